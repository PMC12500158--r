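# Weighted FFT deconvolution, lag windows, artifact estimation/subtraction.

test_that("identity system yields a unit impulse at lag 0", {
  set.seed(1)
  x <- stats::rnorm(2048)
  h <- weighted_fft_deconvolution(
    regressor(x, 10000), epoched_data(array(x, c(1, 1, 2048)), 10000))
  expect_equal(h$values[1, 1], 1, tolerance = 1e-9)
  expect_lt(max(abs(h$values[-1, 1])), 1e-9)
})

test_that("a known circularly convolved kernel is recovered", {
  set.seed(2)
  fs <- 10000; L <- 4096
  x <- stats::rnorm(L)
  g <- numeric(L); g[c(31, 57, 100)] <- c(-0.5, 1, 0.2)
  y <- Re(stats::fft(stats::fft(x) * stats::fft(g), inverse = TRUE)) / L
  h <- weighted_fft_deconvolution(
    regressor(x, fs), epoched_data(array(y, c(1, 1, L)), fs))
  expect_lt(sqrt(mean((h$values[, 1] - g)^2)) / sqrt(mean(g^2)), 1e-8)
})

test_that("the estimator is linear in the EEG", {
  set.seed(3)
  fs <- 1000; L <- 1024
  x <- stats::rnorm(L); y <- stats::rnorm(L)
  h1 <- weighted_fft_deconvolution(
    regressor(x, fs), epoched_data(array(y, c(1, 1, L)), fs))
  h3 <- weighted_fft_deconvolution(
    regressor(x, fs), epoched_data(array(3 * y, c(1, 1, L)), fs))
  expect_equal(h3$values, 3 * h1$values, tolerance = 1e-12)
})

test_that("uniform-weight estimate equals the circular least-squares solution", {
  # normal-equations oracle on a small instance: build the circulant design
  # matrix explicitly and solve X'X h = X'y
  set.seed(4)
  fs <- 1000; L <- 256
  x <- stats::rnorm(L)
  g <- numeric(L); g[c(3, 10)] <- c(1, -0.4)
  y <- Re(stats::fft(stats::fft(x) * stats::fft(g), inverse = TRUE)) / L +
    stats::rnorm(L, 0, 0.1)
  Xm <- sapply(seq_len(L), function(k) x[((seq_len(L) - k) %% L) + 1])
  h_ls <- solve(crossprod(Xm), crossprod(Xm, y))
  h <- weighted_fft_deconvolution(
    regressor(x, fs), epoched_data(array(y, c(1, 1, L)), fs))
  expect_lt(sqrt(mean((h$values[, 1] - h_ls)^2)) / sqrt(mean(h_ls^2)), 1e-8)
})

test_that("weighted average across epochs matches direct computation", {
  set.seed(5)
  fs <- 1000; L <- 512
  x <- rbind(stats::rnorm(L), stats::rnorm(L))
  y <- x * 2  # per-epoch identity times 2
  w <- matrix(c(0.3, 0.7), 2, 1)
  h <- weighted_fft_deconvolution(
    regressor(x, fs), epoched_data(array(y, c(2, 1, L)), fs), weights = w)
  # with y_n = 2 x_n: numerator = 2 sum w_n |x_n|^2, denominator =
  # mean |x_n|^2; lag-0 value is not 2 unless powers match, so compute the
  # expected spectrum directly
  x1 <- stats::fft(x[1, ]); x2 <- stats::fft(x[2, ])
  expected <- Re(stats::fft((0.3 * Conj(x1) * 2 * x1 +
                             0.7 * Conj(x2) * 2 * x2) /
                            ((Mod(x1)^2 + Mod(x2)^2) / 2),
                            inverse = TRUE)) / L
  expect_equal(h$values[, 1], expected, tolerance = 1e-10)
})

test_that("lag windows include both endpoints and reject bad input", {
  set.seed(6)
  h <- weighted_fft_deconvolution(
    regressor(stats::rnorm(2048), 10000),
    epoched_data(array(stats::rnorm(2048), c(1, 1, 2048)), 10000))
  hw <- extract_lag_window(h, 0, 15)
  expect_equal(nrow(hw$values), 151)
  expect_equal(hw$lags_ms[1], 0)
  expect_equal(hw$lags_ms[151], 15)
  neg <- extract_lag_window(h, -5, 5)
  expect_equal(neg$values[51, 1], h$values[1, 1])   # lag 0
  expect_equal(neg$values[50, 1], h$values[2048, 1])  # lag -0.1 ms = tail
  expect_error(extract_lag_window(h, 10, 5), "t_min")
  expect_error(extract_lag_window(h, 0, 5000), "outside")
})

test_that("kernel recovery error shrinks with epoch count", {
  fs <- 10000; dur <- 2
  ks <- test_kernels(fs)
  err_for <- function(nep, seed) {
    pulses <- lapply(seq_len(nep), function(i) {
      generate_pulse_train(115, 10, dur, seed = seed * 1000 + i)
    })
    # a final pulse occasionally rounds past the epoch edge and is dropped
    reg <- suppressWarnings(pulse_train_regressor(pulses, fs, dur))
    spec <- simulation_spec(nep, fs, dur,
                            kernels = list(list(stream = 1, kernel = ks$cap),
                                           list(stream = 1,
                                                kernel = ks$wavev)),
                            noise_white_sd = 1, seed = seed)
    sim <- simulate_recording(spec, list(reg), build_recording = FALSE,
                              keep_noiseless = FALSE)
    h <- weighted_fft_deconvolution(reg, compute_epoch_weights(sim$epochs))
    hw <- extract_lag_window(h, 0, 12)
    truth <- truth_on_lags(ks, hw$lags_ms)
    sqrt(mean((hw$values[, 1] - truth)^2))
  }
  seeds <- 1:20
  e5 <- mean(vapply(seeds, function(s) err_for(5, s), numeric(1)))
  e20 <- mean(vapply(seeds, function(s) err_for(20, s), numeric(1)))
  e60 <- mean(vapply(seeds, function(s) err_for(60, s), numeric(1)))
  expect_gt(e5, e20)
  expect_gt(e20, e60)
})

test_that("artifact kernel is recovered from forward-constructed data", {
  set.seed(8)
  fs <- 10000; L <- 20000; nep <- 6
  audio <- matrix(stats::rnorm(nep * L), nep)
  k_true <- numeric(L); k_true[1:3] <- c(0.8, 0.4, 0.1)
  y <- t(apply(audio, 1, function(a) {
    Re(stats::fft(stats::fft(a) * stats::fft(k_true), inverse = TRUE)) / L
  }))
  ep <- epoched_data(array(y, c(nep, 1, L)), fs)
  k_hat <- estimate_artifact_kernel(ep, regressor(audio, fs))
  expect_lt(sqrt(mean((k_hat$values[, 1] - k_true)^2)) /
              sqrt(mean(k_true^2)), 1e-6)
  # support is enforced: zero outside (-1, 5) ms
  lag_idx_10ms <- 101
  expect_true(all(k_hat$values[lag_idx_10ms:(L - 11), 1] == 0))
  # uncorrelated noise gives a kernel under the noise floor
  noise_ep <- epoched_data(array(stats::rnorm(nep * L, 0, 1),
                                 c(nep, 1, L)), fs)
  k_noise <- estimate_artifact_kernel(noise_ep, regressor(audio, fs))
  expect_lt(sqrt(mean(k_noise$values^2)), 0.01)
  expect_error(estimate_artifact_kernel(ep, regressor(matrix(0, nep, L), fs)),
               "floor")
})

test_that("artifact subtraction removes a pure artifact; zero kernel is identity", {
  set.seed(9)
  fs <- 10000; L <- 10000; nep <- 4
  audio <- matrix(stats::rnorm(nep * L), nep)
  k_true <- numeric(L); k_true[1:2] <- c(1, 0.5)
  y <- t(apply(audio, 1, function(a) {
    Re(stats::fft(stats::fft(a) * stats::fft(k_true), inverse = TRUE)) / L
  }))
  ep <- epoched_data(array(y, c(nep, 1, L)), fs)
  areg <- regressor(audio, fs)
  k_hat <- estimate_artifact_kernel(ep, areg)
  clean <- subtract_artifact(ep, k_hat, areg)
  expect_lt(sqrt(mean(clean$data^2)), 1e-6 * sqrt(mean(y^2)))
  zero_k <- structure(list(values = matrix(0, L, 1), fs = fs,
                           support_ms = c(-1, 5)), class = "artifact_kernel")
  expect_equal(subtract_artifact(ep, zero_k, areg)$data, ep$data)
})

test_that("alternating-polarity artifact is reduced in every epoch", {
  set.seed(10)
  fs <- 10000; L <- 10000; nep <- 6
  base_audio <- matrix(stats::rnorm(nep * L), nep)
  pol <- rep(c(1, -1), 3)
  audio <- base_audio * pol
  k_true <- numeric(L); k_true[1:2] <- c(1, 0.3)
  art <- t(sapply(seq_len(nep), function(n) {
    Re(stats::fft(stats::fft(audio[n, ]) * stats::fft(k_true),
                  inverse = TRUE)) / L
  }))
  y <- art + matrix(stats::rnorm(nep * L, 0, 0.05), nep)
  ep <- epoched_data(array(y, c(nep, 1, L)), fs)
  areg <- regressor(audio, fs)
  clean <- subtract_artifact(ep, estimate_artifact_kernel(ep, areg), areg)
  for (n in seq_len(nep)) {
    expect_lt(sqrt(mean((clean$data[n, 1, ] - (y[n, ] - art[n, ]))^2)),
              sqrt(mean(art[n, ]^2)))
  }
})
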