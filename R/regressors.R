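# Stimulus-feature regressors for the deconvolution: glottal pulse trains,
# half-wave-rectified audio, an auditory-nerve-style surrogate, externally
# computed firing rates, and the 100-300 Hz fundamental waveform used by the
# complex cross-correlation metric.

#' Pulse-train regressor
#'
#' Unit impulses placed at the sample nearest each pulse time, one epoch per
#' pulse train. Pulses falling outside the epoch are dropped with a warning.
#'
#' @param pulses a `pulse_train` or list of them (one per epoch).
#' @param fs target sampling rate, Hz.
#' @param epoch_duration epoch length in seconds.
#' @return a [regressor()] of kind "pulse_train" with zero latency offset.
#' @export
pulse_train_regressor <- function(pulses, fs, epoch_duration) {
  if (inherits(pulses, "pulse_train")) pulses <- list(pulses)
  L <- round(epoch_duration * fs)
  data <- matrix(0, length(pulses), L)
  dropped <- 0L
  for (n in seq_along(pulses)) {
    idx <- round(pulses[[n]]$pulse_times * fs) + 1L
    bad <- idx < 1L | idx > L
    dropped <- dropped + sum(bad)
    data[n, idx[!bad]] <- 1
  }
  if (dropped > 0) {
    warning(sprintf("%d pulse(s) outside epoch bounds dropped", dropped))
  }
  regressor(data, fs, latency_offset_ms = 0, kind = "pulse_train")
}

#' Half-wave-rectified audio regressor
#'
#' @param audio numeric vector or epochs x samples matrix at the EEG rate.
#' @param fs sampling rate, Hz.
#' @return a [regressor()] of kind "rectified_audio" (non-negative values,
#'   zero latency offset).
#' @export
rectified_audio_regressor <- function(audio, fs) {
  if (is.vector(audio)) audio <- matrix(audio, nrow = 1L)
  regressor(pmax(audio, 0), fs, latency_offset_ms = 0,
            kind = "rectified_audio")
}

# ERB-scale bandwidth (Glasberg & Moore) used for the surrogate filterbank.
erb_hz <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' Auditory-nerve surrogate regressor
#'
#' A documented surrogate for model-based auditory-nerve firing rates — not
#' a physiological nerve model. Processing: causal second-order Butterworth
#' band-pass filterbank on an ERB-spaced grid (gammatone-like bandwidths),
#' half-wave rectification, power-law compression (exponent 0.3), summation
#' over bands, causal anti-alias filtering and resampling to the EEG rate.
#' Carries the 2.75 ms latency offset used for nerve-model regressors so the
#' downstream response is shifted right by that amount after deconvolution.
#' Analyses whose correctness matters (kernel recovery) use the pulse-train
#' regressor instead, so nothing depends on this surrogate's fidelity.
#'
#' @param audio numeric vector or epochs x samples matrix.
#' @param fs_audio audio sampling rate (>= 10 kHz).
#' @param fs_out output (EEG) sampling rate, Hz.
#' @param level_db_spl presentation level; audio is scaled as if its RMS
#'   corresponded to this level, which only scales the compressed output.
#' @param cf_lo,cf_hi,cf_per_octave characteristic-frequency grid.
#' @return a [regressor()] of kind "anm_surrogate",
#'   `latency_offset_ms = 2.75`.
#' @export
anm_surrogate_regressor <- function(audio, fs_audio, fs_out = 10000,
                                    level_db_spl = 65,
                                    cf_lo = 125, cf_hi = 8000,
                                    cf_per_octave = 2) {
  if (fs_audio < 10000) stop("surrogate expects audio sampled at >= 10 kHz")
  if (is.vector(audio)) audio <- matrix(audio, nrow = 1L)
  if (all(audio == 0)) {
    warning("silent audio: surrogate regressor is all zero")
    n_out <- ceiling(ncol(audio) * fs_out / fs_audio)
    return(regressor(matrix(0, nrow(audio), n_out), fs_out,
                     latency_offset_ms = 2.75, kind = "anm_surrogate"))
  }
  scale <- 10^((level_db_spl - 65) / 20)
  n_oct <- log2(cf_hi / cf_lo)
  cfs <- cf_lo * 2^(seq(0, n_oct, by = 1 / cf_per_octave))
  cfs <- cfs[cfs + 1.019 * erb_hz(cfs) < 0.95 * fs_audio / 2]  # below Nyquist
  banks <- lapply(cfs, function(fc) {
    bw <- 1.019 * erb_hz(fc)
    edges <- c(max(fc - bw, 1), fc + bw)
    signal::butter(2, edges / (fs_audio / 2), type = "pass")
  })
  aa <- signal::butter(4, min(0.8 * fs_out / fs_audio, 0.999), type = "low")
  n_out <- ceiling(ncol(audio) * fs_out / fs_audio)
  t_in <- (seq_len(ncol(audio)) - 1) / fs_audio
  t_out <- (seq_len(n_out) - 1) / fs_out
  out <- matrix(0, nrow(audio), n_out)
  for (n in seq_len(nrow(audio))) {
    x <- audio[n, ] * scale
    acc <- numeric(length(x))
    for (b in banks) {
      y <- pmax(as.numeric(signal::filter(b, x)), 0)
      acc <- acc + y^0.3
    }
    if (fs_out < fs_audio) {
      acc <- as.numeric(signal::filter(aa, acc))
      acc <- stats::approx(t_in, acc, xout = pmin(t_out, max(t_in)))$y
    }
    out[n, ] <- acc
  }
  regressor(out, fs_out, latency_offset_ms = 2.75, kind = "anm_surrogate")
}

#' Load an externally computed regressor
#'
#' Reads epochs x samples firing-rate (or other feature) waveforms from CSV
#' (one row per epoch, no header) or RDS, passing values through unchanged
#' and recording the latency offset to be compensated after deconvolution.
#'
#' @param path CSV or RDS file.
#' @param fs sampling rate of the stored waveforms, Hz.
#' @param latency_offset_ms model latency to compensate (2.75 for
#'   nerve-model output).
#' @param n_epochs,n_samples expected shape; checked if given.
#' @return a [regressor()] of kind "external".
#' @export
load_external_regressor <- function(path, fs, latency_offset_ms = 0,
                                    n_epochs = NULL, n_samples = NULL) {
  data <- if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    as.matrix(readRDS(path))
  } else {
    as.matrix(utils::read.csv(path, header = FALSE))
  }
  dimnames(data) <- NULL
  if (!is.null(n_epochs) && nrow(data) != n_epochs) {
    stop(sprintf("regressor has %d epoch(s), expected %d",
                 nrow(data), n_epochs))
  }
  if (!is.null(n_samples) && ncol(data) != n_samples) {
    stop(sprintf("regressor has %d sample(s) per epoch, expected %d",
                 ncol(data), n_samples))
  }
  regressor(data, fs, latency_offset_ms = latency_offset_ms,
            kind = "external")
}

#' Save a regressor to CSV (one row per epoch, no header)
#'
#' @param reg a [regressor()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_regressor_csv <- function(reg, path) {
  utils::write.table(reg$data, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Fundamental waveform (100--300 Hz band of the stimulus)
#'
#' Zero-phase band-pass of the audio tracking the glottal fundamental, used
#' as the reference waveform of the complex cross-correlation metric.
#' Default realization is a forward-backward second-order Butterworth
#' (first order leaves sub-band energy, e.g. a 50 Hz tone, less than 20 dB
#' down); a linear-phase FIR variant (compensated to zero phase) is
#' available to mirror FIR-based replications.
#'
#' @param audio numeric vector or epochs x samples matrix.
#' @param fs sampling rate (>= 2 kHz).
#' @param lo,hi band edges, Hz.
#' @param type "butter" (default) or "fir".
#' @param order Butterworth order of the band-pass design.
#' @param fir_order FIR order when `type = "fir"`.
#' @return filtered waveform, same shape as `audio`.
#' @export
fundamental_waveform <- function(audio, fs, lo = 100, hi = 300,
                                 type = c("butter", "fir"), order = 2,
                                 fir_order = 210) {
  if (fs < 2000) stop("fundamental waveform expects fs >= 2 kHz")
  type <- match.arg(type)
  pad <- ceiling(8 * fs / lo)
  if (type == "butter") {
    flt <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
    apply_rows(audio, function(v) zero_phase_filter(flt, v, pad))
  } else {
    b <- signal::Ma(signal::fir1(fir_order, c(lo, hi) / (fs / 2),
                                 type = "pass"))
    apply_rows(audio, function(v) zero_phase_filter(b, v, pad))
  }
}
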