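# CAP and wave V peak picking: zero-phase 500 Hz low-pass smoothing of each
# subject's average response, then the extremum in the component window
# (CAP: minimum in 1-4.5 ms; wave V: maximum in 4-9 ms), at one-sample
# latency resolution.

.peak_windows <- list(CAP = c(1, 4.5), waveV = c(4, 9))

#' Smooth a response waveform for peak picking
#'
#' Zero-phase (forward-backward fourth-order Butterworth, with reflection
#' padding) low-pass at 500 Hz: no group delay, so peak latencies are
#' unaffected, and components an octave or more below the cutoff pass
#' within 1%.
#'
#' @param h a [response_waveform()] (windowed or circular).
#' @param cutoff_hz low-pass cutoff, Hz.
#' @param order Butterworth order of the low-pass design.
#' @return the smoothed `response_waveform`.
#' @export
smooth_for_picking <- function(h, cutoff_hz = 500, order = 4) {
  stopifnot(inherits(h, "response_waveform"))
  if (h$fs < 2 * cutoff_hz) stop("sampling rate too low for this cutoff")
  flt <- signal::butter(order, cutoff_hz / (h$fs / 2), type = "low")
  pad <- ceiling(8 * h$fs / cutoff_hz)
  h$values <- apply(h$values, 2, function(v) zero_phase_filter(flt, v, pad))
  h
}

#' Pick a CAP or wave V peak
#'
#' Smooths the waveform ([smooth_for_picking()]) over a padded region, then
#' takes the window extremum: the minimum in 1--4.5 ms for the CAP, the
#' maximum in 4--9 ms for wave V. Ties go to the earlier latency.
#'
#' @param h a [response_waveform()] (single channel used; circular
#'   responses are windowed internally).
#' @param component_tag "CAP" or "waveV".
#' @param channel channel index.
#' @param smooth apply the 500 Hz zero-phase low-pass first (as done for
#'   each subject's average waveform).
#' @param subject_id,condition carried into the result for bookkeeping.
#' @return a `peak_measurement`: list(component_tag, latency_ms, potential,
#'   subject_id, condition).
#' @export
pick_peak <- function(h, component_tag = c("CAP", "waveV"), channel = 1L,
                      smooth = TRUE, subject_id = NA, condition = NA) {
  component_tag <- match.arg(component_tag)
  win <- .peak_windows[[component_tag]]
  pad <- 5  # ms of context so smoothing has no edge effects in the window
  hw <- if (is.null(h$lags_ms)) {
    extract_lag_window(h, win[1] - pad, win[2] + pad)
  } else h
  if (min(hw$lags_ms) > win[1] || max(hw$lags_ms) < win[2]) {
    stop("response does not cover the ", component_tag, " window")
  }
  if (smooth) hw <- smooth_for_picking(hw)
  inwin <- hw$lags_ms >= win[1] - 1e-9 & hw$lags_ms <= win[2] + 1e-9
  v <- hw$values[inwin, channel]
  lag <- hw$lags_ms[inwin]
  i <- if (component_tag == "CAP") which.min(v) else which.max(v)
  if (sum(v == v[i]) > 1L) message("tied extrema; earliest latency returned")
  structure(list(component_tag = component_tag, latency_ms = lag[i],
                 potential = v[i], subject_id = subject_id,
                 condition = condition),
            class = "peak_measurement")
}

#' Tabulate peak measurements
#'
#' @param peaks list of `peak_measurement` objects.
#' @return data.frame(subject, condition, component, potential, latency_ms).
#' @export
peaks_to_table <- function(peaks) {
  do.call(rbind, lapply(peaks, function(p) {
    data.frame(subject = p$subject_id, condition = p$condition,
               component = p$component_tag, potential = p$potential,
               latency_ms = p$latency_ms)
  }))
}
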