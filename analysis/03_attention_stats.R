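#!/usr/bin/env Rscript
# Simulate a cohort under a null attention effect (identical subcortical
# kernels in both conditions), run the full peak battery — directional t
# tests, BH-FDR over the four-comparison family, JZS Bayes factors — plus
# the pointwise FDR analysis over 0-15 ms, and tabulate the results.

suppressPackageStartupMessages(library(speechABR))

out_dir <- "results/attention"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- run_config(experiment_kind = "diotic", n_subjects = 6, n_epochs = 6,
                  fs = 10000, epoch_duration = 4,
                  noise_white_sd = 0.5, noise_pink_sd = 0.3, seed = 314)
out <- run_pipeline(cfg, out_dir = out_dir)

cat("Peak battery on a null-effect cohort (attended vs unattended):\n")
print(out$stats, digits = 3)
cat(sprintf("\nPointwise FDR over 0-15 ms: %d of %d lags significant.\n",
            sum(out$pointwise$significant), nrow(out$pointwise)))
cat("Large BF01 values and an empty significant-lag set are the expected\n")
cat("outcome here: the generator injected no attention effect.\n")
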