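#' Continuous multichannel recording
#'
#' Container for a continuous voltage recording: a channels x time matrix, a
#' sampling rate, channel labels and trigger events (sample index + code).
#' Triggers mark trial starts and stops and drive epoching and clock-drift
#' correction.
#'
#' @param samples numeric matrix, channels x time (volts).
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per channel.
#' @param triggers data.frame with columns `sample` (1-based index) and
#'   `code` (character), possibly zero rows.
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(samples, fs, channel_labels = NULL,
                                 triggers = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.matrix(samples), fs > 0)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("Ch", seq_len(nrow(samples)))
  }
  if (nrow(samples) != length(channel_labels)) {
    stop("channel count must match label count")
  }
  if (is.null(triggers)) {
    triggers <- data.frame(sample = integer(0), code = character(0))
  }
  if (nrow(triggers) > 0 &&
      (any(triggers$sample < 1) || any(triggers$sample > ncol(samples)))) {
    stop("trigger sample indices must lie within the record")
  }
  structure(list(samples = samples, fs = fs,
                 channel_labels = channel_labels, triggers = triggers),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channel(s) x %d samples @ %g Hz, %d trigger(s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$triggers)))
  invisible(x)
}

#' Epoched EEG data
#'
#' Epochs x channels x samples array with optional per-epoch, per-channel
#' inverse-variance weights (normalized to sum to one over epochs for each
#' channel) and per-epoch condition labels.
#'
#' @param data numeric array, epochs x channels x samples.
#' @param fs sampling rate in Hz.
#' @param weights optional epochs x channels matrix of non-negative weights.
#' @param condition_labels optional character vector, one per epoch.
#' @return An object of class `epoched_data`.
#' @export
epoched_data <- function(data, fs, weights = NULL, condition_labels = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L, fs > 0)
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    stopifnot(nrow(weights) == dim(data)[1], ncol(weights) == dim(data)[2],
              all(weights >= 0))
  }
  if (!is.null(condition_labels)) {
    stopifnot(length(condition_labels) == dim(data)[1])
  }
  structure(list(data = data, fs = fs, weights = weights,
                 condition_labels = condition_labels),
            class = "epoched_data")
}

#' @export
print.epoched_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_data> %d epoch(s) x %d channel(s) x %d samples @ %g Hz%s\n",
              d[1], d[2], d[3], x$fs,
              if (is.null(x$weights)) "" else ", weighted"))
  invisible(x)
}

#' Stimulus-feature regressor
#'
#' Per-epoch stimulus feature waveforms at the EEG sampling rate: the input
#' of the deconvolution. The `latency_offset_ms` records a known model
#' latency (e.g., 2.75 ms for auditory-nerve-model regressors) that is
#' compensated by shifting the estimated response rightward after
#' deconvolution, exactly once.
#'
#' @param data numeric matrix, epochs x samples.
#' @param fs sampling rate in Hz.
#' @param latency_offset_ms non-negative latency compensation in ms.
#' @param kind tag naming the feature ("pulse_train", "rectified_audio",
#'   "anm_surrogate", "external", ...).
#' @return An object of class `regressor`.
#' @export
regressor <- function(data, fs, latency_offset_ms = 0, kind = "generic") {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  stopifnot(is.matrix(data), fs > 0, latency_offset_ms >= 0)
  if (!all(is.finite(data))) stop("regressor values must be finite")
  structure(list(data = data, fs = fs,
                 latency_offset_ms = latency_offset_ms, kind = kind),
            class = "regressor")
}

#' @export
print.regressor <- function(x, ...) {
  cat(sprintf("<regressor:%s> %d epoch(s) x %d samples @ %g Hz, offset %g ms\n",
              x$kind, nrow(x$data), ncol(x$data), x$fs, x$latency_offset_ms))
  invisible(x)
}

#' Response waveform (temporal response function)
#'
#' The kernel h relating a stimulus feature to the EEG, stored either on the
#' full circular lag axis produced by the FFT deconvolution (index 1 = lag 0,
#' tail = negative lags) or on an explicit signed lag window after
#' [extract_lag_window()].
#'
#' @param values numeric matrix, lags x channels.
#' @param fs sampling rate in Hz.
#' @param lags_ms explicit lag axis in ms, or NULL for circular storage.
#' @param n_epochs number of epochs that contributed.
#' @param regressor_kind feature tag carried over from the regressor.
#' @param condition_label optional condition name.
#' @return An object of class `response_waveform`.
#' @export
response_waveform <- function(values, fs, lags_ms = NULL, n_epochs = NA,
                              regressor_kind = "generic",
                              condition_label = NULL) {
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  stopifnot(is.matrix(values), fs > 0)
  if (!is.null(lags_ms)) stopifnot(length(lags_ms) == nrow(values))
  structure(list(values = values, fs = fs, lags_ms = lags_ms,
                 n_epochs = n_epochs, regressor_kind = regressor_kind,
                 condition_label = condition_label),
            class = "response_waveform")
}

#' @export
print.response_waveform <- function(x, ...) {
  cat(sprintf("<response_waveform> %d lag(s) x %d channel(s) @ %g Hz (%s)\n",
              nrow(x$values), ncol(x$values), x$fs,
              if (is.null(x$lags_ms)) "circular" else
                sprintf("%.1f to %.1f ms", min(x$lags_ms), max(x$lags_ms))))
  invisible(x)
}
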