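#!/usr/bin/env Rscript
# The complex cross-correlation FFR metric: band-limited fundamental
# waveforms cross-correlated with simulated EEG carrying a known 8 ms
# response, per-subject envelope peaks in 0-20 ms, response-size ratios,
# and the binomial / ratio-versus-unity tests used to compare conditions.

suppressPackageStartupMessages(library(speechABR))

out_dir <- "results/xcorr"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

fs <- 10000
n <- 8 * fs
n_subjects <- 14
delay_samples <- 80   # 8 ms response latency
gain_target <- 1.3    # "target" stimuli evoke larger responses
gain_distractor <- 1.0

set.seed(271)
rows <- lapply(seq_len(n_subjects), function(s) {
  f <- fundamental_waveform(rnorm(n), fs)
  resp <- c(tail(f, delay_samples), head(f, -delay_samples))
  one <- function(gain, label) {
    eeg <- gain * resp + rnorm(n, 0, 2 * sd(f))
    pk <- xcorr_peak(complex_xcorr_response(matrix(eeg, 1), matrix(f, 1),
                                            fs = fs))
    data.frame(subject = s, condition = label, peak_size = pk$size,
               peak_latency_ms = pk$latency_ms, edge_flag = pk$edge)
  }
  rbind(one(gain_target, "target"), one(gain_distractor, "distractor"))
})
peaks <- do.call(rbind, rows)
write.csv(peaks, file.path(out_dir, "xcorr_peaks.csv"), row.names = FALSE)

tg <- peaks$peak_size[peaks$condition == "target"]
ds <- peaks$peak_size[peaks$condition == "distractor"]
rr <- response_ratio(tg, ds)
k <- sum(tg > ds)
p_binom <- binomial_two_sided(k, n_subjects)
rt <- ratio_gt_one_t(rr$ratios)

cat(sprintf("Mean envelope peak latency: %.1f ms (true 8.0 ms).\n",
            mean(peaks$peak_latency_ms)))
cat(sprintf("%d of %d subjects show target > distractor (binomial p = %.3g).\n",
            k, n_subjects, p_binom))
cat(sprintf("Mean ratio %.2f +/- %.2f; one-tailed t(%d) = %.2f, p = %.3g.\n",
            rr$mean, rr$sem, rt$dof, rt$statistic, rt$p_raw))
write.csv(data.frame(k = k, n = n_subjects, p_binomial = p_binom,
                     mean_ratio = rr$mean, sem_ratio = rr$sem,
                     t = rt$statistic, dof = rt$dof, p_ratio = rt$p_raw),
          file.path(out_dir, "summary.csv"), row.names = FALSE)
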