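#!/usr/bin/env Rscript
# Read the simulated session back from disk, run the subcortical analysis
# chain (epoching from triggers, inverse-variance weighting, weighted FFT
# deconvolution), and compare the recovered temporal response function with
# the simulated ground truth.

suppressPackageStartupMessages(library(speechABR))

in_dir <- "results/simulated"
out_dir <- "results/trf"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

rec <- read_brainvision(file.path(in_dir, "session.vhdr"))
epoch_duration <- 8
epochs <- epoch_with_drift_correction(rec, nominal_duration = epoch_duration)
epochs <- compute_epoch_weights(epochs)

reg <- load_external_regressor(file.path(in_dir, "regressor.csv"), rec$fs,
                               n_epochs = dim(epochs$data)[1])

h <- weighted_fft_deconvolution(reg, epochs)
hw <- extract_lag_window(h, -5, 15)
write_response_csv(hw, file.path(out_dir, "trf.csv"))

truth <- read.csv(file.path(in_dir, "ground_truth.csv"))
pk_cap <- pick_peak(h, "CAP")
pk_v <- pick_peak(h, "waveV")
picked <- data.frame(component = c("CAP", "waveV"),
                     latency_ms = c(pk_cap$latency_ms, pk_v$latency_ms),
                     potential = c(pk_cap$potential, pk_v$potential))
write.csv(picked, file.path(out_dir, "picked_peaks.csv"), row.names = FALSE)

cat("Recovered TRF written to", file.path(out_dir, "trf.csv"), "\n")
for (i in seq_len(nrow(picked))) {
  tr <- truth[truth$component == picked$component[i], ]
  cat(sprintf("%-6s picked at %.1f ms (truth %.1f ms), potential %+.3f (truth %+.1f)\n",
              picked$component[i], picked$latency_ms[i], tr$latency_ms,
              picked$potential[i], tr$amplitude))
}
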