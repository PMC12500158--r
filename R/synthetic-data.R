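# Synthetic speech-EEG generator: pulse trains standing in for glottal
# pulses, parametric evoked kernels (CAP-like, wave-V-like, cortical), and a
# forward model that convolves regressors with kernels and adds pink+white
# noise, optional transducer artifact and silence-driven offset transients.

# Component support windows (ms): the extremum must lie inside, and the
# kernel is identically zero outside.
.kernel_windows <- list(
  CAP      = c(1, 4.5),
  waveV    = c(4, 9),
  cortical = c(15, 300)
)

#' Generate a glottal-pulse-like train
#'
#' Pulse times with instantaneous rate following a slowly wandering f0
#' trajectory (AR(1) across pulses), emulating the pitch contour of a
#' narrator. Inter-pulse intervals equal 1/f0 at each pulse.
#'
#' @param f0_mean mean fundamental frequency in Hz (50--400).
#' @param f0_sd standard deviation of the f0 trajectory in Hz.
#' @param duration train duration in seconds (> 0).
#' @param seed integer seed; output is a pure function of the arguments.
#' @return A `pulse_train` object with fields `pulse_times` (s, strictly
#'   increasing), `f0_trajectory` (Hz at each pulse), `duration`, `seed`.
#' @export
generate_pulse_train <- function(f0_mean, f0_sd = 0, duration, seed = 1) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be positive")
  }
  if (f0_mean < 50 || f0_mean > 400) stop("f0_mean must lie in [50, 400] Hz")
  with_seed(seed, {
    n_max <- ceiling(duration * (f0_mean + 6 * max(f0_sd, 1)))
    rho <- 0.99  # smooth contour: ~100-pulse correlation length
    innov_sd <- f0_sd * sqrt(1 - rho^2)
    f0 <- numeric(n_max)
    f0[1] <- f0_mean + if (f0_sd > 0) stats::rnorm(1, 0, f0_sd) else 0
    if (n_max > 1 && f0_sd > 0) {
      e <- stats::rnorm(n_max - 1, 0, innov_sd)
      for (i in 2:n_max) f0[i] <- f0_mean + rho * (f0[i - 1] - f0_mean) + e[i - 1]
    } else if (n_max > 1) {
      f0[2:n_max] <- f0_mean
    }
    f0 <- pmin(pmax(f0, 50), 400)
    times <- cumsum(c(0, 1 / f0[-n_max]))
    keep <- times < duration
    structure(list(pulse_times = times[keep], f0_trajectory = f0[keep],
                   duration = duration, seed = seed),
              class = "pulse_train")
  })
}

#' Construct a ground-truth evoked kernel
#'
#' A Gaussian-bump kernel on the sample grid whose extremum sits exactly at
#' (`peak_latency_ms`, `peak_amplitude`), hard-limited to the component's
#' physiological support window (CAP 1--4.5 ms, wave V 4--9 ms, cortical
#' 15--300 ms). The requested latency is snapped to the lag grid so the
#' extremum is exact.
#'
#' @param component_tag one of "CAP", "waveV", "cortical".
#' @param peak_latency_ms extremum latency in ms; must lie in the
#'   component's window.
#' @param peak_amplitude extremum value in volts (negative for CAP).
#' @param width_ms full width at half maximum of the bump, ms.
#' @param fs sampling rate of the lag grid, Hz.
#' @return A `ground_truth_kernel` with fields `lags_ms`, `values`,
#'   `component_tag`, `peak_latency_ms`, `peak_amplitude`, `fs`.
#' @export
make_kernel <- function(component_tag, peak_latency_ms, peak_amplitude,
                        width_ms = 1, fs = 10000) {
  if (!component_tag %in% names(.kernel_windows)) {
    stop("unknown component_tag: ", component_tag)
  }
  win <- .kernel_windows[[component_tag]]
  if (peak_latency_ms < win[1] || peak_latency_ms > win[2]) {
    stop(sprintf("%s peak latency must lie in [%g, %g] ms",
                 component_tag, win[1], win[2]))
  }
  lat <- round(peak_latency_ms * fs / 1000) / fs * 1000  # snap to grid
  lags_ms <- seq(0, win[2] + 2 * width_ms, by = 1000 / fs)
  sigma <- width_ms / (2 * sqrt(2 * log(2)))
  values <- peak_amplitude * exp(-(lags_ms - lat)^2 / (2 * sigma^2))
  values[lags_ms < win[1] | lags_ms > win[2]] <- 0
  structure(list(lags_ms = lags_ms, values = values,
                 component_tag = component_tag, peak_latency_ms = lat,
                 peak_amplitude = peak_amplitude, fs = fs),
            class = "ground_truth_kernel")
}

# Place a kernel's values on a length-n circular lag axis (index 1 = lag 0)
# for FFT convolution.
kernel_to_fir <- function(kernel, n, fs) {
  if (!isTRUE(all.equal(fs, kernel$fs))) stop("kernel fs mismatch")
  v <- numeric(n)
  idx <- round(kernel$lags_ms * fs / 1000) + 1L
  ok <- idx >= 1L & idx <= n
  v[idx[ok]] <- kernel$values[ok]
  v
}

#' Pink (1/f) noise
#'
#' Gaussian noise with 1/f spectral amplitude between `f_lo` and `f_hi`
#' (flat outside that band), synthesized in the frequency domain with
#' Hermitian-symmetric complex Gaussian coefficients and scaled to standard
#' deviation `sd`. An EEG-background approximation.
#'
#' @param n number of samples.
#' @param fs sampling rate, Hz.
#' @param sd target sample standard deviation.
#' @param f_lo,f_hi band over which amplitude follows 1/f, Hz.
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs, sd = 1, f_lo = 0.1, f_hi = 2000) {
  if (sd == 0) return(numeric(n))
  half <- n %/% 2
  # positive-frequency coefficients (k = 1 .. half), Hermitian mirror below
  z <- complex(real = stats::rnorm(half), imaginary = stats::rnorm(half)) /
    sqrt(2)
  if (n %% 2 == 0) z[half] <- complex(real = sqrt(2) * Re(z[half]))
  f <- seq_len(half) * fs / n
  z <- z / pmin(pmax(f, f_lo), f_hi)
  spec <- complex(n)
  spec[2:(half + 1)] <- z
  spec[n:(n - half + 1 + (n %% 2 == 0))] <- Conj(z[seq_len(half - (n %% 2 == 0))])
  x <- Re(ifft(spec)) * n
  x * sd / stats::sd(x)
}

#' Simulation specification
#'
#' Bundles the structural parameters of a simulated recording session.
#' `kernels` is a list of entries `list(stream=, kernel=, condition=)`;
#' `condition = NULL` applies the kernel in every condition. For epochs whose
#' `condition_labels` entry equals `attended_label`, each kernel is scaled by
#' `attention_gain[component_tag]` (default 1 = null effect).
#'
#' @param n_epochs number of epochs.
#' @param fs sampling rate, Hz (1000, 10000 or 25000).
#' @param epoch_duration epoch length in seconds (64 s as presented).
#' @param kernels list of kernel entries (see Details).
#' @param noise_white_sd,noise_pink_sd noise standard deviations, volts.
#' @param artifact_kernel optional `ground_truth_kernel`-like waveform
#'   convolved with the audio to mimic transducer artifact.
#' @param alternate_polarity logical; flip audio (and hence artifact)
#'   polarity on every other epoch, as in stimulus presentation.
#' @param silence_spans data.frame(epoch, start_s, stop_s) of silent gaps.
#' @param offset_response_amplitude amplitude of a slow cortical offset
#'   transient added at each silence onset (default 0 = none).
#' @param condition_labels per-epoch labels (default alternates
#'   "attended"/"unattended").
#' @param attention_gain named multiplicative gain per component tag for
#'   attended epochs (default all 1).
#' @param n_channels number of simulated channels.
#' @param channel_gains per-channel multiplicative gain on the evoked part.
#' @param seed integer seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_epochs, fs = 10000, epoch_duration = 64,
                            kernels = list(), noise_white_sd = 0,
                            noise_pink_sd = 0, artifact_kernel = NULL,
                            alternate_polarity = FALSE,
                            silence_spans = NULL,
                            offset_response_amplitude = 0,
                            condition_labels = NULL,
                            attention_gain = NULL,
                            n_channels = 1, channel_gains = NULL,
                            seed = 1) {
  stopifnot(n_epochs >= 1, fs %in% c(1000, 10000, 25000), epoch_duration > 0)
  if (is.null(condition_labels)) {
    condition_labels <- rep(c("attended", "unattended"),
                            length.out = n_epochs)
  }
  if (!is.null(attention_gain) && any(unlist(attention_gain) <= 0)) {
    stop("attention_gain must be positive")
  }
  if (!is.null(silence_spans)) {
    bad <- silence_spans$start_s < 0 | silence_spans$stop_s > epoch_duration |
      silence_spans$stop_s <= silence_spans$start_s
    if (any(bad)) stop("silence spans must lie within epochs")
  }
  if (is.null(channel_gains)) channel_gains <- rep(1, n_channels)
  structure(list(n_epochs = n_epochs, fs = fs,
                 epoch_duration = epoch_duration, kernels = kernels,
                 noise_white_sd = noise_white_sd,
                 noise_pink_sd = noise_pink_sd,
                 artifact_kernel = artifact_kernel,
                 alternate_polarity = alternate_polarity,
                 silence_spans = silence_spans,
                 offset_response_amplitude = offset_response_amplitude,
                 condition_labels = condition_labels,
                 attention_gain = attention_gain,
                 n_channels = n_channels, channel_gains = channel_gains,
                 seed = seed),
            class = "simulation_spec")
}

#' Simulate a continuous EEG recording with known ground truth
#'
#' Forward model: each epoch of each channel is the sum over streams of the
#' circular convolution of that stream's regressor with its (condition- and
#' gain-resolved) kernels, plus an optional audio-convolved transducer
#' artifact with alternating polarity, plus pink and white noise. Circular
#' convolution matches the frequency-domain deconvolution's model exactly,
#' and the evoked kernels are short relative to the 64 s epochs so wraparound
#' is physically negligible.
#'
#' @param spec a [simulation_spec()].
#' @param regressors list of `regressor` objects, one per stream, each with
#'   `spec$n_epochs` rows at `spec$fs`.
#' @param audio optional list of epochs x samples matrices (one per stream)
#'   used for the artifact path; defaults to the regressor waveforms.
#' @param build_recording assemble the concatenated
#'   [continuous_recording()] (skip to save memory on long simulations).
#' @param keep_noiseless retain the pre-noise epochs array.
#' @return list with `recording` (a [continuous_recording()] with start/stop
#'   triggers per epoch, or NULL), `epochs` (the epochs x channels x samples
#'   array), `noiseless` (same, before noise, or NULL), and `truth`
#'   (kernels, gains, silence spans, condition labels, artifact kernel).
#' @export
simulate_recording <- function(spec, regressors, audio = NULL,
                               build_recording = TRUE,
                               keep_noiseless = TRUE) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.list(regressors) || inherits(regressors, "regressor")) {
    regressors <- list(regressors)
  }
  L <- round(spec$epoch_duration * spec$fs)
  for (r in regressors) {
    if (nrow(r$data) != spec$n_epochs || ncol(r$data) != L ||
        !isTRUE(all.equal(r$fs, spec$fs))) {
      stop("regressor epochs must match the simulation spec (epochs, length, fs)")
    }
  }
  if (is.null(audio)) audio <- lapply(regressors, function(r) r$data)
  nch <- spec$n_channels
  with_seed(spec$seed, {
    firs <- lapply(spec$kernels, function(k) {
      stats::fft(kernel_to_fir(k$kernel, L, spec$fs))
    })
    art_fir <- if (!is.null(spec$artifact_kernel)) {
      stats::fft(kernel_to_fir2(spec$artifact_kernel, L, spec$fs))
    } else NULL
    noiseless <- if (keep_noiseless) {
      array(0, dim = c(spec$n_epochs, nch, L))
    } else NULL
    epochs <- array(0, dim = c(spec$n_epochs, nch, L))
    for (n in seq_len(spec$n_epochs)) {
      cond <- spec$condition_labels[n]
      evoked_f <- complex(L)
      reg_f <- lapply(regressors, function(r) stats::fft(r$data[n, ]))
      for (i in seq_along(spec$kernels)) {
        k <- spec$kernels[[i]]
        if (!is.null(k$condition) && !identical(k$condition, cond)) next
        gain <- 1
        if (!is.null(spec$attention_gain) && identical(cond, "attended")) {
          g <- spec$attention_gain[[k$kernel$component_tag]]
          if (!is.null(g)) gain <- g
        }
        evoked_f <- evoked_f + gain * reg_f[[k$stream %||% 1L]] * firs[[i]]
      }
      evoked <- if (length(spec$kernels)) Re(ifft(evoked_f)) else numeric(L)
      artifact <- numeric(L)
      if (!is.null(art_fir)) {
        pol <- if (spec$alternate_polarity && n %% 2 == 0) -1 else 1
        for (a in audio) {
          artifact <- artifact + pol * Re(ifft(stats::fft(a[n, ]) * art_fir))
        }
      }
      offset <- numeric(L)
      if (!is.null(spec$silence_spans) &&
          spec$offset_response_amplitude != 0) {
        sp <- spec$silence_spans[spec$silence_spans$epoch == n, , drop = FALSE]
        if (nrow(sp) > 0) {
          t_ax <- seq_len(L) / spec$fs
          for (j in seq_len(nrow(sp))) {
            # slow damped transient starting at the silence onset
            rel <- t_ax - sp$start_s[j]
            on <- rel >= 0 & rel < 1
            offset[on] <- offset[on] + spec$offset_response_amplitude *
              rel[on] / 0.15 * exp(1 - rel[on] / 0.15)
          }
        }
      }
      for (c in seq_len(nch)) {
        base <- spec$channel_gains[c] * evoked + artifact + offset
        if (keep_noiseless) noiseless[n, c, ] <- base
        noise <- numeric(L)
        if (spec$noise_pink_sd > 0) {
          noise <- noise + pink_noise(L, spec$fs, spec$noise_pink_sd)
        }
        if (spec$noise_white_sd > 0) {
          noise <- noise + stats::rnorm(L, 0, spec$noise_white_sd)
        }
        epochs[n, c, ] <- base + noise
      }
    }
    rec <- NULL
    if (build_recording) {
      samples <- matrix(aperm(epochs, c(2, 3, 1)), nrow = nch)
      starts <- (seq_len(spec$n_epochs) - 1L) * L + 1L
      triggers <- data.frame(
        sample = as.integer(rbind(starts, starts + L - 1L)),
        code = rep(c("start", "stop"), spec$n_epochs)
      )
      rec <- continuous_recording(samples, spec$fs, triggers = triggers)
    }
    list(recording = rec,
         epochs = epoched_data(epochs, spec$fs,
                               condition_labels = spec$condition_labels),
         noiseless = noiseless,
         truth = list(kernels = spec$kernels,
                      attention_gain = spec$attention_gain,
                      silence_spans = spec$silence_spans,
                      condition_labels = spec$condition_labels,
                      artifact_kernel = spec$artifact_kernel))
  })
}

# Accept either a ground_truth_kernel or a plain list(lags_ms, values, fs)
# for the artifact waveform.
kernel_to_fir2 <- function(k, n, fs) {
  if (inherits(k, "ground_truth_kernel")) return(kernel_to_fir(k, n, fs))
  v <- numeric(n)
  idx <- round(k$lags_ms * fs / 1000)
  idx <- ((idx %% n) + n) %% n + 1L   # negative lags wrap to the tail
  v[idx] <- k$values
  v
}

#' Simulate a cohort of per-subject response waveforms
#'
#' Generates subject-level response estimates directly at the waveform
#' level — a per-subject multiplicative amplitude factor times the
#' ground-truth kernel, plus temporally smoothed measurement noise drawn
#' independently per condition — for studying the inferential battery's
#' operating characteristics (type-I error, power) without simulating and
#' deconvolving full recordings for every cohort.
#'
#' @param n_subjects number of subjects.
#' @param kernel_waveform numeric vector (subcortical: lags) or matrix
#'   (cortical: channels x times) of the true response.
#' @param gain_a,gain_b multiplicative gain in conditions a and b
#'   (equal gains = null effect).
#' @param noise_sd within-subject measurement noise sd (per sample, after
#'   smoothing).
#' @param subject_sd sd of the per-subject amplitude factor about 1.
#' @param smooth_samples width of the moving-average temporal smoothing
#'   applied to the noise (correlated noise, as in filtered EEG).
#' @param seed integer seed.
#' @return list `a`, `b`: arrays subjects x lags (vector kernel) or
#'   subjects x channels x times (matrix kernel).
#' @export
simulate_cohort_responses <- function(n_subjects, kernel_waveform,
                                      gain_a = 1, gain_b = 1,
                                      noise_sd = 0.5, subject_sd = 0.2,
                                      smooth_samples = 5, seed = 1) {
  with_seed(seed, {
    mat <- is.matrix(kernel_waveform)
    kv <- if (mat) kernel_waveform else matrix(kernel_waveform, nrow = 1)
    nc <- nrow(kv); nt <- ncol(kv)
    amp <- 1 + stats::rnorm(n_subjects, 0, subject_sd)
    make <- function(gain) {
      out <- array(0, dim = c(n_subjects, nc, nt))
      for (s in seq_len(n_subjects)) {
        noise <- matrix(stats::rnorm(nc * nt), nc, nt)
        if (smooth_samples > 1) {
          k <- rep(1 / smooth_samples, smooth_samples)
          noise <- t(apply(noise, 1, function(r) {
            as.numeric(stats::filter(r, k, sides = 2, circular = TRUE))
          }))
          noise <- noise * sqrt(smooth_samples)  # restore unit variance scale
        }
        out[s, , ] <- amp[s] * gain * kv + noise_sd * noise
      }
      if (!mat) out <- array(out, dim = c(n_subjects, nt)) else out
      out
    }
    list(a = make(gain_a), b = make(gain_b))
  })
}
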