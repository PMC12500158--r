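# Shared fixtures, all built in code at test time.

# Default CAP + wave V kernel pair at 10 kHz.
test_kernels <- function(fs = 10000) {
  list(cap = make_kernel("CAP", 3.0, -0.5, 0.5, fs),
       wavev = make_kernel("waveV", 5.6, 1.0, 1.0, fs))
}

# A short single-channel simulated session with pulse-train regressor.
tiny_sim <- function(n_epochs = 4, dur = 2, fs = 10000, seed = 1,
                     noise_white_sd = 0, noise_pink_sd = 0, ...) {
  pulses <- lapply(seq_len(n_epochs), function(i) {
    generate_pulse_train(115, 10, dur, seed = seed * 100 + i)
  })
  reg <- pulse_train_regressor(pulses, fs, dur)
  ks <- test_kernels(fs)
  spec <- simulation_spec(n_epochs, fs, dur,
                          kernels = list(list(stream = 1, kernel = ks$cap),
                                         list(stream = 1, kernel = ks$wavev)),
                          noise_white_sd = noise_white_sd,
                          noise_pink_sd = noise_pink_sd, seed = seed, ...)
  sim <- simulate_recording(spec, list(reg))
  list(reg = reg, spec = spec, sim = sim, kernels = ks)
}

# Ground-truth summed kernel waveform sampled on a lag axis (ms).
truth_on_lags <- function(kernels, lags_ms) {
  Reduce(`+`, lapply(kernels, function(k) {
    stats::approx(c(k$lags_ms, max(lags_ms) + 1), c(k$values, 0),
                  xout = lags_ms, rule = 2)$y
  }))
}
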