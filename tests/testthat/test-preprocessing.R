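# Filter chains, re-referencing, drift-corrected epoching, silence zeroing
# and inverse-variance weighting.

test_that("causal band-pass rejects DC and enforces valid edges", {
  fs <- 10000
  x <- rep(1, 5000)
  y <- causal_butterworth_bandpass(x, 30, 2000, fs)
  expect_lt(max(abs(y[3000:5000])), 10^(-20 / 20))  # >= 20 dB down
  expect_error(causal_butterworth_bandpass(x, 30, 6000, fs), "edges")
  expect_error(causal_butterworth_bandpass(x, 0, 100, fs), "edges")
})

test_that("impulse response matches an independently derived biquad", {
  # first-order Butterworth band-pass via bilinear transform, derived by
  # hand: H(s) = B s / (s^2 + B s + w0^2) with prewarped edges
  fs <- 10000; lo <- 30; hi <- 2000
  wl <- 2 * fs * tan(pi * lo / fs)
  wh <- 2 * fs * tan(pi * hi / fs)
  B <- wh - wl; w02 <- wl * wh; K <- 2 * fs
  a0 <- K^2 + B * K + w02
  b <- c(B * K, 0, -B * K) / a0
  a <- c(1, (2 * w02 - 2 * K^2) / a0, (K^2 - B * K + w02) / a0)
  n <- 200
  imp <- c(1, numeric(n - 1))
  ref <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (k in 0:2) if (t - k >= 1) acc <- acc + b[k + 1] * imp[t - k]
    for (k in 1:2) if (t - k >= 1) acc <- acc - a[k + 1] * ref[t - k]
    ref[t] <- acc
  }
  got <- causal_butterworth_bandpass(imp, lo, hi, fs)
  expect_lt(max(abs(got - ref)), 1e-9)
})

test_that("causal filters are causal under input truncation", {
  fs <- 10000
  set.seed(2)
  x <- stats::rnorm(2000)
  y_full <- causal_butterworth_bandpass(x, 30, 2000, fs)
  x2 <- x; x2[1001:2000] <- stats::rnorm(1000)
  y_trunc <- causal_butterworth_bandpass(x2, 30, 2000, fs)
  expect_equal(y_full[1:1000], y_trunc[1:1000], tolerance = 1e-12)
})

test_that("cortical downsampling meets the stated passband/stopband specs", {
  t25 <- (0:149999) / 25000
  amp <- function(f) {
    s <- downsample_cortical(sin(2 * pi * f * t25))
    sqrt(2) * sqrt(mean(s[2001:5500]^2))
  }
  expect_gt(20 * log10(amp(300)), -1)       # passband preserved within 1 dB
  expect_lt(20 * log10(amp(600)), -60)      # stopband
  expect_equal(downsample_cortical(numeric(25000)), numeric(1000))
  expect_length(downsample_cortical(numeric(25001)), 1001)
  expect_error(downsample_cortical(numeric(100), fs_in = 10000), "25 kHz")
})

test_that("subcortical downsampling preserves in-band content at 10 kHz", {
  t25 <- (0:99999) / 25000
  s <- downsample_subcortical(sin(2 * pi * 1000 * t25))
  expect_length(s, 40000)
  a <- sqrt(2) * sqrt(mean(s[5001:35000]^2))
  expect_gt(20 * log10(a), -1)
  s2 <- downsample_subcortical(sin(2 * pi * 6000 * t25))
  expect_lt(20 * log10(sqrt(2) * sqrt(mean(s2[5001:35000]^2))), -60)
  expect_identical(downsample_subcortical(1:5 / 5, fs_in = 10000), 1:5 / 5)
})

test_that("re-referencing subtracts the reference mean", {
  rec <- continuous_recording(rbind(Fz = rnorm(50), TP9 = rep(2, 50),
                                    TP10 = rep(4, 50)), 1000,
                              c("Fz", "TP9", "TP10"))
  out <- rereference(rec, c("TP9", "TP10"))
  expect_equal(out$samples[1, ], rec$samples[1, ] - 3)
  # self-reference zeros the channel
  self <- rereference(rec, "Fz")
  expect_true(all(self$samples[1, ] == 0))
  # zero-mean reference leaves other channels unchanged
  rec2 <- continuous_recording(rbind(rnorm(50), rep(1, 50), rep(-1, 50)),
                               1000, c("A", "P1", "P2"))
  expect_equal(rereference(rec2, c("P1", "P2"))$samples[1, ],
               rec2$samples[1, ])
  # idempotent on second application
  twice <- rereference(rereference(rec, c("TP9", "TP10")), c("TP9", "TP10"))
  expect_equal(twice$samples, out$samples)
  expect_error(rereference(rec, "TP11"), "not found")
})

test_that("drift correction resamples to the nominal grid", {
  fs <- 10000
  # zero drift: exact slice
  x <- stats::rnorm(20000)
  rec <- continuous_recording(matrix(x, 1), fs)
  ep <- epoch_with_drift_correction(rec, cbind(1, 10001),
                                    nominal_duration = 1)
  expect_equal(ep$data[1, 1, ], x[1:10000])
  # true rate 1.0001x nominal: 100 Hz sinusoid stays 100 Hz
  n_true <- 100010
  tt <- (0:(n_true - 1)) / (fs * 1.0001)
  rec2 <- continuous_recording(matrix(sin(2 * pi * 100 * tt), 1), fs)
  ep2 <- epoch_with_drift_correction(rec2, cbind(1, n_true + 1),
                                     nominal_duration = 10)
  expect_equal(dim(ep2$data)[3], 100000)
  sp <- Mod(stats::fft(ep2$data[1, 1, ]))
  f_peak <- (which.max(sp[1:50000]) - 1) / 10
  expect_equal(f_peak, 100, tolerance = 0.01)
  expect_error(epoch_with_drift_correction(rec, cbind(100, 50), 1),
               "inverted")
  expect_error(epoch_with_drift_correction(rec, rbind(c(1, 6000),
                                                      c(5000, 11000)), 0.5),
               "overlap")
})

test_that("silence zeroing applies the 490 ms rule exactly", {
  fs <- 1000
  ep <- epoched_data(array(stats::rnorm(2 * 1 * 2000), c(2, 1, 2000)), fs)
  short_span <- data.frame(epoch = 1, start_s = 0.5, stop_s = 0.9)   # 0.4 s
  out <- zero_silent_spans(ep, short_span)
  expect_identical(out$data, ep$data)
  long_span <- data.frame(epoch = 2, start_s = 0.5, stop_s = 1.1)    # 0.6 s
  out2 <- zero_silent_spans(ep, long_span)
  expect_true(all(out2$data[2, 1, 501:1100] == 0))
  # everything else bit-identical
  expect_identical(out2$data[1, , ], ep$data[1, , ])
  expect_identical(out2$data[2, 1, 1:500], ep$data[2, 1, 1:500])
  expect_identical(out2$data[2, 1, 1101:2000], ep$data[2, 1, 1101:2000])
  # empty list is identity
  expect_identical(zero_silent_spans(ep, NULL)$data, ep$data)
})

test_that("silence zeroing commutes with re-referencing", {
  fs <- 1000
  arr <- array(stats::rnorm(2 * 3 * 1000), c(2, 3, 1000))
  span <- data.frame(epoch = 1, start_s = 0.1, stop_s = 0.7)
  reref_ep <- function(e) {
    ref <- apply(e$data[, 2:3, , drop = FALSE], c(1, 3), mean)
    for (c in 1:3) e$data[, c, ] <- e$data[, c, ] - ref
    e
  }
  a <- zero_silent_spans(reref_ep(epoched_data(arr, fs)), span)
  b <- reref_ep(zero_silent_spans(epoched_data(arr, fs), span))
  expect_equal(a$data, b$data, tolerance = 1e-12)
})

test_that("silence detection finds inserted gaps", {
  fs <- 10000
  x <- stats::rnorm(3 * fs) * 0.3
  x[10001:16000] <- 0   # 0.6 s gap
  sp <- detect_silences(x, fs)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$start_s, 1.0, tolerance = 2e-3)
  expect_equal(sp$stop_s, 1.6, tolerance = 2e-3)
})

test_that("epoch weights are inverse-variance, normalized per channel", {
  fs <- 1000
  arr <- array(0, c(2, 1, 1000))
  set.seed(4)
  a <- stats::rnorm(1000); arr[1, 1, ] <- a / stats::sd(a)        # var 1
  b <- stats::rnorm(1000); arr[2, 1, ] <- 2 * b / stats::sd(b)    # var 4
  w <- compute_epoch_weights(epoched_data(arr, fs))$weights
  expect_equal(as.numeric(w), c(0.8, 0.2), tolerance = 1e-12)
  # uniform variance: 1/N each; single epoch: weight 1
  u <- array(stats::rnorm(3000), c(3, 1, 1000))
  for (i in 1:3) u[i, 1, ] <- u[i, 1, ] / stats::sd(u[i, 1, ])
  wu <- compute_epoch_weights(epoched_data(u, fs))$weights
  expect_equal(as.numeric(wu), rep(1 / 3, 3), tolerance = 1e-9)
  w1 <- compute_epoch_weights(
    epoched_data(array(stats::rnorm(100), c(1, 1, 100)), fs))$weights
  expect_equal(as.numeric(w1), 1)
  # weights sum to one per channel for multichannel data
  m <- array(stats::rnorm(4 * 3 * 500), c(4, 3, 500))
  wm <- compute_epoch_weights(epoched_data(m, fs))$weights
  expect_equal(colSums(wm), rep(1, 3), tolerance = 1e-12)
})

test_that("zero-variance epochs get the maximum finite weight", {
  fs <- 1000
  arr <- array(stats::rnorm(3 * 1000), c(3, 1, 1000))
  arr[2, 1, ] <- 5  # constant: zero variance
  expect_warning(ep <- compute_epoch_weights(epoched_data(arr, fs)),
                 "zero-variance")
  w <- ep$weights[, 1]
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w[2], max(w))
})

test_that("weighting ignores zeroed spans when computing variance", {
  fs <- 1000
  arr <- array(stats::rnorm(2 * 1 * 2000), c(2, 1, 2000))
  ep <- epoched_data(arr, fs)
  span <- data.frame(epoch = 1, start_s = 0, stop_s = 1.0)
  zeroed <- zero_silent_spans(ep, span)
  w <- compute_epoch_weights(zeroed)$weights
  # variance of epoch 1 computed over the unzeroed half only, so weights
  # stay near 1/2 rather than inflating toward epoch 1
  expect_lt(abs(w[1, 1] - 0.5), 0.1)
})
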