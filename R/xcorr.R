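# Complex cross-correlation FFR metric: the 100-300 Hz band-passed EEG is
# cross-correlated with the analytic (Hilbert-transformed) fundamental
# waveform per trial, normalized per trial, averaged phase-coherently across
# trials, and the modulus (envelope) peak taken in 0-20 ms.

#' Analytic signal via the FFT
#'
#' @param x real numeric vector.
#' @return complex vector `x + i * H(x)` (one-sided spectrum method).
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[2:(n / 2)] <- 2; w[n / 2 + 1] <- 1
  } else {
    w[1] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  ifft(X * w)
}

#' Complex cross-correlation response
#'
#' Per trial, circularly cross-correlates the analytic fundamental waveform
#' with the EEG (positive lags = EEG later than stimulus), normalizes, and
#' averages the complex responses across trials before taking the modulus.
#' Default normalization puts each trial on a correlation-coefficient scale
#' (divide by trial length x RMS of the analytic fundamental x RMS of the
#' EEG); `"stim_energy"` divides by the analytic fundamental's energy only.
#' Trials with a zero-energy fundamental are dropped with a warning.
#'
#' @param eeg epochs x samples matrix (single channel), or an
#'   [epoched_data()] with one channel; band-pass it 100--300 Hz zero-phase
#'   first (see [fundamental_waveform()] for the same filter).
#' @param fundamental epochs x samples matrix of real fundamental waveforms.
#' @param fs sampling rate, Hz (taken from `eeg` if `epoched_data`).
#' @param normalize "rms" (default), "stim_energy" or "none".
#' @return an `xcorr_envelope`: complex mean response and envelope on the
#'   circular lag axis, `fs`, `n_trials`.
#' @export
complex_xcorr_response <- function(eeg, fundamental, fs = NULL,
                                   normalize = c("rms", "stim_energy",
                                                 "none")) {
  normalize <- match.arg(normalize)
  if (inherits(eeg, "epoched_data")) {
    stopifnot(dim(eeg$data)[2] == 1L)
    fs <- eeg$fs
    eeg <- matrix(eeg$data[, 1L, ], nrow = dim(eeg$data)[1])
  }
  if (is.vector(eeg)) eeg <- matrix(eeg, nrow = 1L)
  if (is.vector(fundamental)) fundamental <- matrix(fundamental, nrow = 1L)
  stopifnot(!is.null(fs), all(dim(eeg) == dim(fundamental)))
  L <- ncol(eeg)
  acc <- complex(L)
  used <- 0L
  for (n in seq_len(nrow(eeg))) {
    f <- fundamental[n, ]
    if (all(f == 0)) next
    a <- analytic_signal(f)
    cc <- ifft(Conj(stats::fft(a)) * stats::fft(eeg[n, ]))
    norm <- switch(normalize,
                   rms = L * sqrt(mean(Mod(a)^2)) * rms(eeg[n, ]),
                   stim_energy = sum(Mod(a)^2),
                   none = 1)
    if (norm == 0) next
    acc <- acc + cc / norm
    used <- used + 1L
  }
  if (used < nrow(eeg)) {
    warning(sprintf("%d trial(s) with zero-energy fundamental dropped",
                    nrow(eeg) - used))
  }
  if (used == 0L) stop("no usable trials")
  mean_cc <- acc / used
  structure(list(complex = mean_cc, envelope = Mod(mean_cc), fs = fs,
                 n_trials = used, normalize = normalize),
            class = "xcorr_envelope")
}

#' Peak of the cross-correlation envelope
#'
#' Argmax of the envelope within the lag window (default 0--20 ms). Ties go
#' to the earlier lag; a peak on either window edge is flagged.
#'
#' @param env an `xcorr_envelope`.
#' @param window_ms lag window, ms.
#' @return list(`size`, `latency_ms`, `edge` flag).
#' @export
xcorr_peak <- function(env, window_ms = c(0, 20)) {
  stopifnot(inherits(env, "xcorr_envelope"))
  ks <- round(window_ms[1] * env$fs / 1000):round(window_ms[2] * env$fs / 1000)
  L <- length(env$envelope)
  idx <- ((ks %% L) + L) %% L + 1L
  e <- env$envelope[idx]
  i <- which.max(e)                      # first maximum = earlier lag on tie
  if (sum(e == e[i]) > 1L) {
    message("tied envelope maxima; earliest lag returned")
  }
  list(size = e[i], latency_ms = ks[i] * 1000 / env$fs,
       edge = i == 1L || i == length(e))
}

#' Response-size ratios between paired conditions
#'
#' Per-pair ratio a/b with mean and standard error; pairs with non-positive
#' denominators are excluded with a warning. Optionally also reports the
#' log-transformed ratios.
#'
#' @param sizes_a,sizes_b equal-length numeric vectors, paired by subject
#'   (and narrator where applicable).
#' @param pair_keys optional identifiers for the pairs.
#' @param use_log also compute mean/SEM of log(ratio).
#' @return list(`ratios`, `mean`, `sem`, `pair_keys`, and when requested
#'   `log_mean`, `log_sem`).
#' @export
response_ratio <- function(sizes_a, sizes_b, pair_keys = NULL,
                           use_log = FALSE) {
  stopifnot(length(sizes_a) == length(sizes_b))
  if (is.null(pair_keys)) pair_keys <- seq_along(sizes_a)
  ok <- sizes_b > 0
  if (!all(ok)) {
    warning(sprintf("%d pair(s) with non-positive denominator excluded",
                    sum(!ok)))
  }
  r <- sizes_a[ok] / sizes_b[ok]
  out <- list(ratios = r, mean = mean(r),
              sem = stats::sd(r) / sqrt(length(r)),
              pair_keys = pair_keys[ok])
  if (use_log) {
    lr <- log(r)
    out$log_mean <- mean(lr)
    out$log_sem <- stats::sd(lr) / sqrt(length(lr))
  }
  out
}
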