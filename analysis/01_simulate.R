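#!/usr/bin/env Rscript
# Simulate a small diotic-style recording session with known CAP and wave V
# kernels and write it out as BrainVision files plus sidecar tables, so the
# rest of the analysis chain can be run from files on disk exactly as it
# would be on a real recording.

suppressPackageStartupMessages(library(speechABR))

out_dir <- "results/simulated"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

fs <- 10000
n_epochs <- 6
epoch_duration <- 8   # desk-scale epochs; the forward model is length-free
seed <- 20260920

pulses <- lapply(seq_len(n_epochs), function(i) {
  generate_pulse_train(115, 10, epoch_duration, seed = seed %% 1e6 + i)
})
reg <- pulse_train_regressor(pulses, fs, epoch_duration)

kernels <- list(
  list(stream = 1, kernel = make_kernel("CAP", 3.0, -0.5, 0.5, fs)),
  list(stream = 1, kernel = make_kernel("waveV", 5.6, 1.0, 1.0, fs)))

spec <- simulation_spec(n_epochs, fs, epoch_duration, kernels = kernels,
                        noise_white_sd = 0.4, noise_pink_sd = 0.4,
                        seed = seed %% 1e6)
sim <- simulate_recording(spec, list(reg))

write_brainvision(sim$recording, file.path(out_dir, "session"))
save_regressor_csv(reg, file.path(out_dir, "regressor.csv"))
truth <- do.call(rbind, lapply(kernels, function(k) {
  data.frame(component = k$kernel$component_tag, stream = k$stream,
             condition = "all", latency_ms = k$kernel$peak_latency_ms,
             amplitude = k$kernel$peak_amplitude)
}))
write.csv(truth, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)

cat(sprintf("Simulated %d epochs of %g s at %g Hz (%d glottal-like pulses/epoch on average).\n",
            n_epochs, epoch_duration, fs,
            round(mean(vapply(pulses, function(p) length(p$pulse_times),
                              numeric(1))))))
cat(sprintf("Wrote BrainVision triplet, regressor and ground truth to %s/.\n",
            out_dir))
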