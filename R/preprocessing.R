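# Preprocessing: the causal filter chains, re-referencing, epoching with
# clock-drift correction, silence zeroing, and inverse-variance epoch
# weighting applied before deconvolution.
#
# Subcortical chain: (25 kHz input only) Chebyshev-II anti-alias with
# 3,750/5,000 Hz edges, resample to 10 kHz, then causal first-order
# Butterworth 30-2,000 Hz. Cortical chain: Chebyshev-II 375/500 Hz plus a
# second-order 1,000 Hz Butterworth, every 25th sample to 1 kHz,
# re-reference TP9/TP10, causal first-order Butterworth 1-20 Hz.

#' Causal Butterworth band-pass
#'
#' Single-pass (causal) Butterworth band-pass, first order by default, as
#' used for both the subcortical (30--2,000 Hz) and cortical (1--20 Hz)
#' chains.
#'
#' @param x numeric vector, or channels x time matrix (filtered per row).
#' @param lo,hi band edges in Hz, 0 < lo < hi < fs/2.
#' @param fs sampling rate, Hz.
#' @param order filter order (per edge) of the band-pass design.
#' @return filtered signal, same shape as `x`.
#' @export
causal_butterworth_bandpass <- function(x, lo, hi, fs, order = 1) {
  if (!(lo > 0 && lo < hi && hi < fs / 2)) {
    stop("band edges must satisfy 0 < lo < hi < fs/2")
  }
  flt <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  apply_rows(x, function(v) as.numeric(signal::filter(flt, v)))
}

apply_rows <- function(x, f) {
  if (is.matrix(x)) t(apply(x, 1, f)) else f(x)
}

# Minimum Chebyshev II order meeting passband loss Rp at Wp and stopband
# attenuation Rs at Ws (normalized low-pass edges), closed form.
cheb2_order <- function(Wp, Ws, Rp = 1, Rs = 60) {
  d <- sqrt((10^(Rs / 10) - 1) / (10^(Rp / 10) - 1))
  ceiling(acosh(d) / acosh(Ws / Wp))
}

# The stated anti-aliasing design: Chebyshev II meeting (Wp, Ws, 1 dB,
# 60 dB), plus a second-order Butterworth guard filter.
antialias_chain <- function(x, fs, pass_hz, stop_hz, guard_hz) {
  n <- cheb2_order(pass_hz / (fs / 2), stop_hz / (fs / 2), 1, 60)
  cheb <- signal::cheby2(n, 60, stop_hz / (fs / 2), type = "low")
  but <- signal::butter(2, min(guard_hz / (fs / 2), 0.999), type = "low")
  apply_rows(x, function(v) {
    as.numeric(signal::filter(but, as.numeric(signal::filter(cheb, v))))
  })
}

#' Causal downsample of a 25 kHz recording to 1 kHz (cortical chain)
#'
#' Chebyshev II anti-alias (passband edge 375 Hz, stopband edge 500 Hz,
#' <= 1 dB passband loss, >= 60 dB stopband attenuation) plus a second-order
#' Butterworth at 1,000 Hz, both causal, then every 25th sample.
#'
#' @param x numeric vector or channels x time matrix at exactly 25 kHz.
#' @param fs_in input rate; must be 25000.
#' @return downsampled signal at 1 kHz, length `ceiling(n/25)`.
#' @export
downsample_cortical <- function(x, fs_in = 25000) {
  if (!isTRUE(all.equal(fs_in, 25000))) {
    stop("cortical downsampling expects a 25 kHz input")
  }
  y <- antialias_chain(x, fs_in, 375, 500, 1000)
  pick <- function(v) v[seq(1, length(v), by = 25)]
  apply_rows(y, pick)
}

#' Causal downsample of a 25 kHz recording to 10 kHz (subcortical chain)
#'
#' Same Chebyshev-II design philosophy with edges scaled to 3,750/5,000 Hz,
#' then resampling onto the 10 kHz grid by linear interpolation (the signal
#' is band-limited well below the output Nyquist by the anti-alias filters).
#' A 10 kHz input is passed through unchanged.
#'
#' @param x numeric vector or channels x time matrix.
#' @param fs_in input rate, 25000 or 10000.
#' @return signal at 10 kHz.
#' @export
downsample_subcortical <- function(x, fs_in = 25000) {
  if (isTRUE(all.equal(fs_in, 10000))) return(x)
  if (!isTRUE(all.equal(fs_in, 25000))) {
    stop("subcortical downsampling expects a 25 kHz (or 10 kHz) input")
  }
  y <- antialias_chain(x, fs_in, 3750, 5000, 5000)
  interp <- function(v) {
    n_out <- ceiling(length(v) * 10000 / fs_in)
    t_in <- (seq_along(v) - 1) / fs_in
    t_out <- (seq_len(n_out) - 1) / 10000
    stats::approx(t_in, v, xout = pmin(t_out, max(t_in)))$y
  }
  apply_rows(y, interp)
}

#' Re-reference a recording to the mean of reference channels
#'
#' Subtracts the instantaneous mean of the named reference channels (e.g.,
#' TP9/TP10 for the cortical montage) from every channel.
#'
#' @param rec a [continuous_recording()].
#' @param reference_labels labels of the reference channels.
#' @return a re-referenced `continuous_recording`.
#' @export
rereference <- function(rec, reference_labels) {
  stopifnot(inherits(rec, "continuous_recording"))
  idx <- match(reference_labels, rec$channel_labels)
  if (anyNA(idx)) {
    stop("reference channel(s) not found: ",
         paste(reference_labels[is.na(idx)], collapse = ", "))
  }
  ref <- colMeans(rec$samples[idx, , drop = FALSE])
  rec$samples <- sweep(rec$samples, 2, ref)
  rec
}

# Fourier-domain resampling of x onto exactly n_out samples spanning the
# same interval. Identity when n_out == length(x).
resample_fourier <- function(x, n_out) {
  n_in <- length(x)
  if (n_out == n_in) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  h <- min(n_in, n_out) %/% 2
  Y[1:(h + 1)] <- X[1:(h + 1)]
  if (h > 1) Y[(n_out - h + 2):n_out] <- X[(n_in - h + 2):n_in]
  # split a shared Nyquist bin symmetrically to keep the signal real
  if (min(n_in, n_out) %% 2 == 0) {
    if (n_in > n_out) {
      Y[h + 1] <- X[h + 1] + X[n_in - h + 1]
    } else if (n_out > n_in) {
      Y[h + 1] <- X[h + 1] / 2
      Y[n_out - h + 1] <- Conj(X[h + 1]) / 2
    }
  }
  Re(ifft(Y)) * n_out / n_in
}

#' Epoch a recording with clock-drift correction
#'
#' Slices the recording between each (start, stop) trigger pair and
#' resamples the slice (Fourier method) so that the true trial duration maps
#' to exactly `nominal_duration * fs` samples, correcting any drift between
#' the stimulus and EEG clocks. Pairs exactly `nominal_duration` apart are
#' passed through untouched.
#'
#' @param rec a [continuous_recording()].
#' @param trigger_pairs data.frame/matrix with columns start, stop (1-based
#'   sample indices; stop exclusive), one row per trial. Defaults to
#'   consecutive "start"/"stop" codes in `rec$triggers`.
#' @param nominal_duration nominal trial duration in seconds.
#' @param condition_labels optional per-epoch labels.
#' @return an [epoched_data()] with equal-length epochs.
#' @export
epoch_with_drift_correction <- function(rec, trigger_pairs = NULL,
                                        nominal_duration,
                                        condition_labels = NULL) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (is.null(trigger_pairs)) {
    st <- rec$triggers$sample[rec$triggers$code == "start"]
    sp <- rec$triggers$sample[rec$triggers$code == "stop"] + 1L
    trigger_pairs <- cbind(start = st, stop = sp)
  }
  trigger_pairs <- as.matrix(trigger_pairs)
  starts <- trigger_pairs[, 1]; stops <- trigger_pairs[, 2]
  if (any(stops <= starts)) stop("inverted trigger pair")
  o <- order(starts)
  if (any(utils::head(stops[o], -1) > starts[o][-1])) {
    stop("overlapping trigger pairs")
  }
  L <- round(nominal_duration * rec$fs)
  nep <- nrow(trigger_pairs); nch <- nrow(rec$samples)
  out <- array(0, dim = c(nep, nch, L))
  for (i in seq_len(nep)) {
    seg <- rec$samples[, starts[i]:(stops[i] - 1L), drop = FALSE]
    for (c in seq_len(nch)) out[i, c, ] <- resample_fourier(seg[c, ], L)
  }
  epoched_data(out, rec$fs, condition_labels = condition_labels)
}

#' Zero the EEG during long silences
#'
#' Sets samples inside silence spans longer than 490 ms to exactly zero, to
#' keep attention-dependent onset/offset transients at speech gaps from
#' smearing into the deconvolved responses. Shorter spans are ignored; all
#' other samples are untouched. A logical zero-mask is attached as the
#' `"zero_mask"` attribute (epochs x samples) for downstream variance
#' computation.
#'
#' @param epochs an [epoched_data()].
#' @param silence_spans data.frame(epoch, start_s, stop_s); may be empty.
#' @param min_duration minimum silence duration to act on, seconds.
#' @return the modified `epoched_data`.
#' @export
zero_silent_spans <- function(epochs, silence_spans,
                              min_duration = 0.49) {
  stopifnot(inherits(epochs, "epoched_data"))
  d <- dim(epochs$data); L <- d[3]
  mask <- matrix(FALSE, d[1], L)
  if (!is.null(silence_spans) && nrow(silence_spans) > 0) {
    keep <- (silence_spans$stop_s - silence_spans$start_s) > min_duration
    sp <- silence_spans[keep, , drop = FALSE]
    for (j in seq_len(nrow(sp))) {
      i0 <- max(1L, floor(sp$start_s[j] * epochs$fs) + 1L)
      i1 <- min(L, ceiling(sp$stop_s[j] * epochs$fs))
      if (i1 >= i0) {
        epochs$data[sp$epoch[j], , i0:i1] <- 0
        mask[sp$epoch[j], i0:i1] <- TRUE
      }
    }
  }
  attr(epochs, "zero_mask") <- mask
  epochs
}

#' Detect silent spans in an audio waveform
#'
#' Frames the audio (1 ms frames), flags frames whose RMS falls below
#' `threshold_db` relative to the whole-waveform RMS, and merges consecutive
#' flagged frames into spans.
#'
#' @param audio numeric vector.
#' @param fs sampling rate, Hz.
#' @param frame_ms frame length, ms.
#' @param threshold_db silence threshold relative to overall RMS, dB.
#' @return data.frame(start_s, stop_s) of merged silent spans.
#' @export
detect_silences <- function(audio, fs, frame_ms = 1, threshold_db = -60) {
  flen <- max(1L, round(frame_ms / 1000 * fs))
  nfr <- floor(length(audio) / flen)
  if (nfr == 0) return(data.frame(start_s = numeric(0), stop_s = numeric(0)))
  fr <- matrix(audio[seq_len(nfr * flen)], nrow = flen)
  fr_rms <- sqrt(colMeans(fr^2))
  ref <- rms(audio)
  silent <- fr_rms < ref * 10^(threshold_db / 20)
  r <- rle(silent)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  data.frame(start_s = (starts[sel] - 1L) * flen / fs,
             stop_s = ends[sel] * flen / fs)
}

#' Inverse-variance epoch weights
#'
#' Assigns each epoch (per channel) a weight equal to the inverse of its
#' variance, normalized to sum to one for each channel. Variance is computed
#' over non-zeroed samples only when a zero-mask from
#' [zero_silent_spans()] is present (zeroed spans would bias it downward).
#' A zero-variance epoch gets the largest finite weight observed on that
#' channel before normalization, with a warning.
#'
#' @param epochs an [epoched_data()].
#' @return the `epoched_data` with its `weights` field filled.
#' @export
compute_epoch_weights <- function(epochs) {
  stopifnot(inherits(epochs, "epoched_data"))
  d <- dim(epochs$data)
  if (d[1] < 1) stop("need at least one epoch")
  mask <- attr(epochs, "zero_mask")
  w <- matrix(0, d[1], d[2])
  for (c in seq_len(d[2])) {
    v <- vapply(seq_len(d[1]), function(n) {
      x <- epochs$data[n, c, ]
      if (!is.null(mask)) x <- x[!mask[n, ]]
      stats::var(x)
    }, numeric(1))
    wc <- ifelse(v > 0, 1 / v, NA_real_)
    if (anyNA(wc)) {
      warning("zero-variance epoch(s) assigned the maximum finite weight")
      fill <- if (all(is.na(wc))) 1 else max(wc, na.rm = TRUE)
      wc[is.na(wc)] <- fill
    }
    w[, c] <- wc / sum(wc)
  }
  epochs$weights <- w
  epochs
}
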