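# Weighted frequency-domain deconvolution of epoched EEG against stimulus
# regressors, lag-window extraction, and stimulus-artifact kernel
# estimation/subtraction for dichotic recordings.
#
# The estimator, per channel, over N epochs with per-epoch FFTs x_n, y_n
# and inverse-variance weights b_n (sum 1 per channel):
#
#   h = IFFT[ sum_n b_n conj(x_n) y_n  /  ((1/N) sum_n conj(x_n) x_n) ]
#
# computed elementwise over frequency on the full epoch (circular model, no
# zero-padding); negative lags live in the tail of the circular axis. The
# denominator is the unweighted mean regressor power. Bins whose power falls
# below 1e-12 x the median power are floored at that value (pulse-train
# spectra are near-flat, so this rarely triggers).

#' Weighted FFT deconvolution
#'
#' Estimates the temporal response function per channel, then shifts it
#' right by the regressor's latency offset (e.g., 2.75 ms for
#' auditory-nerve-model regressors), exactly once.
#'
#' @param X a [regressor()] (epochs x samples).
#' @param Y an [epoched_data()] with matching epoch count, length and fs.
#' @param weights optional epochs x channels matrix overriding
#'   `Y$weights`; defaults to uniform 1/N per channel.
#' @param power_floor_rel relative denominator floor.
#' @return a circular [response_waveform()] (index 1 = lag 0); the number
#'   of floored bins is attached as attribute `"n_floored_bins"`.
#' @export
weighted_fft_deconvolution <- function(X, Y, weights = NULL,
                                       power_floor_rel = 1e-12) {
  stopifnot(inherits(X, "regressor"), inherits(Y, "epoched_data"))
  d <- dim(Y$data)
  if (nrow(X$data) != d[1] || ncol(X$data) != d[3] ||
      !isTRUE(all.equal(X$fs, Y$fs))) {
    stop("regressor and EEG must share epoch count, length and fs")
  }
  N <- d[1]; C <- d[2]; L <- d[3]
  if (all(X$data == 0)) {
    stop("regressor power below floor at every frequency")
  }
  w <- weights %||% Y$weights %||% matrix(1 / N, N, C)
  w <- as.matrix(w)
  num <- matrix(0 + 0i, L, C)
  den <- numeric(L)
  rev_idx <- c(1L, L:2L)   # index of -k for the packed real-pair transform
  for (n in seq_len(N)) {
    if (C == 1L) {
      # two real FFTs in one complex transform: z = x + i y
      zf <- stats::fft(complex(real = X$data[n, ],
                               imaginary = Y$data[n, 1L, ]))
      zr <- Conj(zf[rev_idx])
      xf <- (zf + zr) / 2
      yf <- (zf - zr) / (2i)
      cxf <- Conj(xf)
      den <- den + Re(cxf * xf)
      num[, 1L] <- num[, 1L] + w[n, 1L] * cxf * yf
    } else {
      xf <- stats::fft(X$data[n, ])
      cxf <- Conj(xf)
      den <- den + Re(cxf * xf)
      for (c in seq_len(C)) {
        num[, c] <- num[, c] + w[n, c] * cxf * stats::fft(Y$data[n, c, ])
      }
    }
  }
  den <- den / N
  floor_val <- power_floor_rel * stats::median(den)
  if (floor_val <= 0) floor_val <- power_floor_rel * max(den)
  if (floor_val <= 0) {
    stop("regressor power below floor at every frequency")
  }
  low <- den < floor_val
  if (all(low)) stop("regressor power below floor at every frequency")
  den[low] <- floor_val
  h <- matrix(0, L, C)
  for (c in seq_len(C)) h[, c] <- Re(ifft(num[, c] / den))
  shift <- round(X$latency_offset_ms * Y$fs / 1000)
  if (shift != 0) h <- apply(h, 2, roll_right, k = shift)
  out <- response_waveform(h, Y$fs, n_epochs = N, regressor_kind = X$kind)
  attr(out, "n_floored_bins") <- sum(low)
  out
}

#' Extract a signed lag window from a circular response
#'
#' Maps the requested lag interval onto the circular axis (negative lags
#' wrap from the tail) and returns the sub-waveform with an explicit lag
#' axis; both endpoints are included.
#'
#' @param h a [response_waveform()].
#' @param t_min_ms,t_max_ms window edges in ms (t_min <= t_max).
#' @return a windowed `response_waveform` with `lags_ms` set.
#' @export
extract_lag_window <- function(h, t_min_ms, t_max_ms) {
  stopifnot(inherits(h, "response_waveform"))
  if (t_min_ms > t_max_ms) stop("t_min_ms must not exceed t_max_ms")
  L <- nrow(h$values)
  if (!is.null(h$lags_ms)) {                 # already windowed: sub-window
    keep <- h$lags_ms >= t_min_ms - 1e-9 & h$lags_ms <= t_max_ms + 1e-9
    if (!any(keep)) stop("window outside available lags")
    return(response_waveform(h$values[keep, , drop = FALSE], h$fs,
                             lags_ms = h$lags_ms[keep],
                             n_epochs = h$n_epochs,
                             regressor_kind = h$regressor_kind,
                             condition_label = h$condition_label))
  }
  k_min <- round(t_min_ms * h$fs / 1000)
  k_max <- round(t_max_ms * h$fs / 1000)
  if (k_max - k_min + 1L > L || k_max > L %/% 2 || k_min < -(L %/% 2)) {
    stop("window outside available lags")
  }
  ks <- k_min:k_max
  idx <- ((ks %% L) + L) %% L + 1L
  response_waveform(h$values[idx, , drop = FALSE], h$fs,
                    lags_ms = ks * 1000 / h$fs, n_epochs = h$n_epochs,
                    regressor_kind = h$regressor_kind,
                    condition_label = h$condition_label)
}

#' Estimate the stimulus-artifact kernel
#'
#' Deconvolves the EEG against the raw stimulus audio and windows the
#' result to the configured artifact support (default -1 to +5 ms; the
#' transducer artifact is near-instantaneous), zero elsewhere.
#'
#' @param Y an [epoched_data()].
#' @param audio a [regressor()] holding the raw audio per epoch at the EEG
#'   rate (per-epoch polarity already applied).
#' @param support_ms artifact support window (ms, signed).
#' @param weights optional weights passed to the deconvolution.
#' @return an `artifact_kernel`: circular values (lags x channels) zero
#'   outside the support, plus `fs` and `support_ms`.
#' @export
estimate_artifact_kernel <- function(Y, audio, support_ms = c(-1, 5),
                                     weights = NULL) {
  h <- weighted_fft_deconvolution(audio, Y, weights = weights)
  L <- nrow(h$values)
  ks <- c(0:(L %/% 2), -((L - L %/% 2 - 1):1)) # lag of each circular index
  lag_ms <- ks * 1000 / h$fs
  outside <- lag_ms < support_ms[1] | lag_ms > support_ms[2]
  v <- h$values
  v[outside, ] <- 0
  structure(list(values = v, fs = h$fs, support_ms = support_ms),
            class = "artifact_kernel")
}

#' Subtract the estimated stimulus artifact from the EEG
#'
#' Convolves the artifact kernel with each epoch's audio (circular, matching
#' the estimation model) and subtracts the result from every channel.
#'
#' @param Y an [epoched_data()].
#' @param k an `artifact_kernel` from [estimate_artifact_kernel()].
#' @param audio a [regressor()] with the per-epoch audio (signed polarity).
#' @return the cleaned `epoched_data`.
#' @export
subtract_artifact <- function(Y, k, audio) {
  stopifnot(inherits(Y, "epoched_data"), inherits(k, "artifact_kernel"))
  d <- dim(Y$data)
  if (nrow(audio$data) != d[1] || ncol(audio$data) != d[3]) {
    stop("audio shape must match the EEG epochs")
  }
  kf <- apply(k$values, 2, stats::fft)
  for (n in seq_len(d[1])) {
    af <- stats::fft(audio$data[n, ])
    for (c in seq_len(d[2])) {
      est <- Re(ifft(af * kf[, c]))
      Y$data[n, c, ] <- Y$data[n, c, ] - est
    }
  }
  Y
}
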