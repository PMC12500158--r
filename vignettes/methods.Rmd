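---
title: "Deconvolution of subcortical and cortical responses to continuous speech: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolution of subcortical and cortical responses to continuous speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechABR)
```

## The problem

Selective attention has large, well-replicated effects on cortical speech
encoding. Whether it also modulates the auditory periphery (the
auditory-nerve compound action potential, CAP) and brainstem (the ABR and
its wave V) is contested. Answering the question with continuous, natural
speech requires three things this package provides: an estimator that
extracts millisecond-scale subcortical responses from hours of EEG recorded
during ongoing speech; measurement of the single numbers those responses
support (peak potentials and latencies, cross-correlation envelope peaks);
and an inferential battery able to quantify evidence *for* a null effect as
well as against it.

## The deconvolution model

The EEG in each 64 s epoch is modelled as the convolution of a
stimulus-feature regressor with an unknown kernel (the temporal response
function, TRF), plus noise. With per-epoch FFTs $X_n$ (regressor) and $Y_n$
(EEG), and per-epoch, per-channel weights $b_n$,

$$ h \;=\; \mathcal{F}^{-1}\!\left[ \frac{\sum_n b_n X_n^* Y_n}
   {\tfrac1N \sum_n X_n^* X_n} \right]. $$

Assumptions worth making explicit:

* **Linearity and time-invariance** within an epoch. The synthetic forward
  model is exactly this, so recovery tests are exact up to noise; real
  neural responses are only approximately LTI.
* **Circularity.** The FFT is taken over the whole epoch with no
  zero-padding; lags wrap, and negative lags are read from the tail of the
  lag axis. Evoked kernels (tens of ms) are vastly shorter than the 64 s
  epochs, so wraparound is physically negligible, and the circular model
  makes the estimator exactly the circular least-squares solution (verified
  against an explicit circulant normal-equations solve at $n = 2048$, and
  exact for noiseless data under uniform weights).
* **Weighting.** $b_n$ is the inverse of the epoch's variance per channel,
  normalized to sum to one per channel — noisy epochs are down-weighted.
  The denominator uses the *unweighted* mean regressor power, as the
  estimator is written; with unequal weights and unequal per-epoch
  regressor power the estimator is therefore not exactly unbiased, which is
  the cost of the published form and is invisible at realistic SNR.
* **Denominator floor.** The estimator has no explicit regularization.
  Bins whose mean regressor power falls below $10^{-12}\times$ its median
  are floored at that value and counted. Pulse-train spectra are nearly
  flat, so this virtually never triggers; an all-zero regressor is an
  error.
* **Latency compensation.** A regressor computed by a model with its own
  latency (2.75 ms for auditory-nerve-model output) shifts the TRF left;
  the TRF is rolled right by exactly that amount after estimation, once.

## Preprocessing chains

*Subcortical*: 25 kHz recordings are anti-aliased with a Chebyshev II
design (edges scaled to 3,750/5,000 Hz, 1 dB passband loss, 60 dB stopband)
plus a second-order Butterworth guard filter, resampled to 10 kHz, then
band-passed 30–2,000 Hz with a causal first-order Butterworth. The
anti-aliasing design for this branch is not prescribed anywhere, so the
package reuses the cortical branch's design philosophy with scaled edges.

*Cortical*: Chebyshev II (375/500 Hz edges, 1/60 dB) plus a second-order
1,000 Hz Butterworth, every 25th sample to 1 kHz, re-referencing to
TP9/TP10, then 1–20 Hz causal first-order Butterworth. All filters in both
chains are single-pass (causal); causality is tested by input truncation.

*Epoching and clock drift*: trial start/stop triggers define each epoch;
the enclosed samples are resampled by the Fourier method so the true trial
duration maps onto exactly `nominal_duration * fs` samples. Fourier
resampling is appropriate because epochs are long and band-limited; a
sinusoid's frequency is preserved to well under 0.01 Hz at the drift
magnitudes clocks actually show (~1e-4).

*Silence zeroing*: speech pauses longer than 490 ms evoke strong,
attention-dependent onset/offset transients that smear into the TRF as slow
acausal components. The EEG inside such spans is set to exactly zero; spans
of 490 ms or less are left untouched. Epoch variance for weighting is then
computed over non-zeroed samples only, since the zeros would otherwise bias
variance (and hence weights) upward for epochs with long silences. The
synthetic generator can inject a configurable offset transient at silence
onsets (default amplitude 0) to reproduce this contamination scenario.

## Regressors

* **Pulse trains** — unit impulses at the sample nearest each glottal-pulse
  time; zero latency offset. These carry all correctness-critical tests.
* **Rectified audio** — half-wave rectified stimulus, a baseline feature.
* **Auditory-nerve surrogate** — an ERB-spaced band-pass filterbank
  (causal second-order Butterworth, gammatone-like bandwidths), half-wave
  rectification, power-law compression with exponent 0.3, summation across
  bands, and resampling to the EEG rate, with the 2.75 ms latency offset.
  This is a *documented surrogate*, not a physiological nerve model: it has
  the right qualitative properties (causal onset, compressive growth
  $2^{0.3}$ per doubling, broadband drive) and the correct interface, so a
  genuine nerve-model output can replace it via
  `load_external_regressor()` without touching anything downstream. No
  acceptance-level result depends on the surrogate's fidelity.
* **Fundamental waveform** — zero-phase 100–300 Hz band-pass of the
  stimulus, the reference signal of the cross-correlation metric. The
  band-pass is a forward-backward second-order Butterworth: a first-order
  design leaves a 50 Hz tone under 20 dB attenuated even after the
  backward pass, which is too leaky for a waveform meant to isolate the
  fundamental; order 2 gives ~28 dB there while leaving the 100–300 Hz
  band within 1 dB. An FIR variant is available by argument for
  replications that used FIR filters.

## The complex cross-correlation FFR metric

Per trial, the analytic (Hilbert-transformed) fundamental waveform is
circularly cross-correlated with the EEG, normalized, and the *complex*
responses are averaged across trials before the envelope (modulus) is
taken; phase-coherent averaging preserves SNR growth with trial count,
and averaging moduli instead can only be larger (triangle inequality —
asserted elementwise in the tests). The envelope peak is taken over lags
0–20 ms; edge-maximal responses are flagged, and ties break to the earlier
lag for determinism. The normalization constant of the original metric is
not published; the default here divides by trial length × RMS of the
analytic fundamental × RMS of the trial's EEG, i.e. a
correlation-coefficient scale that makes sizes comparable across trials.
A stimulus-energy-only normalization is available by argument, and the
choice is recorded in the returned object. Peak latency is invariant to
either choice.

## Peak picking

Each subject's average response is smoothed with a zero-phase 500 Hz
low-pass before picking the CAP minimum in 1–4.5 ms or the wave V maximum
in 4–9 ms, at one-sample (0.1 ms at 10 kHz) latency resolution. The
smoother is a fourth-order Butterworth run forward-backward with
odd-reflection padding: reflection padding keeps edge transients out of
the measurement windows (the plain forward-backward filter without padding
distorts short windows badly), zero phase preserves latencies exactly, and
order 4 passes a 100 Hz component within 1% where a first-order design
would clip it by ~4%. Smoothing attenuates the *amplitude* of very narrow
peaks (a 0.5 ms-wide CAP keeps ~50% of its height); since the same filter
is applied to both conditions of a comparison, paired statistics are
unaffected, and latencies are preserved to the sample.

## Statistics

* **Pointwise tests**: two-tailed paired *t* at every lag in the window of
  interest (0–7 ms CAP, 0–15 ms ABR), BH-FDR corrected across the window at
  0.05. Lags with identically zero difference get $t = 0$, $p = 1$.
* **Peak battery**: directional paired *t* per comparison — lower-tailed
  for CAP size (an enhanced CAP is more negative), upper-tailed for wave V
  size, two-tailed for latencies (no prior direction) — with BH-FDR across
  the four comparisons as one family. The family choice reproduces the
  published adjusted-p pattern from the published *t* values, which is how
  the family was inferred; the package treats those four comparisons
  jointly as its default battery.
* **JZS Bayes factors**: $\mathrm{BF}_{01} = m_0/m_1$ with $m_0$ the
  central-*t* density at the observed *t* and $m_1$ the noncentral-*t*
  density marginalized over a Cauchy(0, 0.707) prior on the standardized
  effect size (noncentrality $\delta\sqrt n$), by adaptive quadrature at
  relative tolerance $10^{-6}$. One-sided variants truncate and renormalize
  the prior on the half-line; the two-sided marginal equals the mean of the
  two one-sided marginals, an identity the tests assert. Published values
  are matched at their printed one-decimal precision; different tail
  conventions in other implementations could differ below that.
* **Exact binomial**: two-sided, summing all outcome probabilities no more
  likely than the observed count (via `stats::binom.test`).
* **Ratios versus unity**: one-tailed upper *t* on (ratio − 1), with a
  log-ratio variant; ratios are kept unlogged by default to mirror the
  analysis convention being replicated, and both are reported where it
  matters.
* **Spatiotemporal cluster permutation**: paired comparison over subjects ×
  channels × times. Cluster-forming threshold = the two-tailed *t* critical
  value at 0.05 with $n-1$ dof; clusters are sign-consistent connected
  components across channel adjacency and temporal contiguity (no
  diagonal); cluster mass = sum of *t*; the null is random sign flips of
  subject difference maps — exhaustive over all $2^n$ assignments when
  $n \le 12$, 10,000 random flips otherwise, with the add-one p-value
  convention for sampled nulls. Fewer than 5 subjects is an error (at
  $n=4$ the exhaustive null has only 16 points). Channel adjacency is
  user-supplied; `chain_adjacency()` and `grid_adjacency()` cover
  synthetic montages, since the algorithm is geometry-agnostic.

## The synthetic generator

`simulate_recording()` implements exactly the linear forward model the
estimator assumes: regressor ⊛ kernel per stream (circular), plus optional
audio-convolved transducer artifact with polarity alternating across
epochs, plus pink and white noise, with every kernel, gain, and silence
span returned as ground truth. Specific choices:

* **Kernels** are Gaussian bumps snapped to the lag grid, hard-limited to
  physiological support windows (CAP 1–4.5 ms, wave V 4–9 ms, cortical
  15–300 ms). Defaults — CAP at 3.0 ms and −0.5, wave V at 5.6 ms and
  +1.0 (arbitrary voltage units), widths 0.5 and 1 ms — sit at the typical
  latencies of speech-evoked responses.
* **Pulse trains** follow an AR(1) f0 contour (correlation 0.99 per pulse)
  around a narrator-like mean of 115 Hz with 10 Hz dispersion, clamped to
  50–400 Hz.
* **Pink noise** is synthesized in the frequency domain with 1/f amplitude
  between 0.1 and 2,000 Hz; EEG background is approximately 1/f and
  nothing more specific is established for this paradigm, so the two noise
  levels (pink, white) are free parameters.
* **Attention effects** enter as multiplicative per-component gains on
  attended epochs; the default gain of 1 makes the null scenario the
  baseline, so type-I error studies need no special casing.
* **Cohort-level simulation** (`simulate_cohort_responses()`) generates
  per-subject response *waveforms* directly — per-subject amplitude factor
  (sd 0.2 around 1) times the true kernel plus temporally smoothed
  measurement noise (sd 0.5 per sample after smoothing, 5-sample moving
  average), drawn independently per condition. This emulates the
  between-subject and between-condition variability of subject-average
  TRFs at the SNR typical of about an hour of EEG, and makes 200-cohort
  operating-characteristic studies affordable. It does not model
  waveform-shape variability across subjects, channel-correlated noise, or
  latency jitter; conclusions from it concern the *statistics*, not the
  estimator.

What the generator does **not** emulate: acoustic realism of speech (the
audio stand-ins are broadband noise or pulse trains), eye blinks and other
ICA-grade artifacts, nonstationary noise within an epoch, and nonlinear
cochlear processing. Passing tests therefore demonstrate that the chain
recovers what the linear model puts in at realistic SNR — not that real
EEG satisfies the model.

## Study conditions used by the verification suite

The deep end-to-end checks run at the sizes the conclusions need: kernel
recovery uses 60 epochs of 64 s at 10 kHz (the full session size) with
pink+white noise at −10 dB per-sample kernel-to-noise, across 20 seeds;
operating characteristics use 200 null cohorts of 20 subjects for the
pointwise FDR analysis and 20 cohorts with a 1.5× cortical gain for
cluster-test power (1,000 permutations each); unit-level properties run on
2–8 s epochs, where the circular model makes size irrelevant. The
artifact-subtraction check uses a broadband artifact 5–10× the neural
response, as in recordings without polarity inversion, with stimulus audio
statistically independent of the pulse regressor so artifact-kernel
estimation is identifiable at desk scale.

## Numerical choices and degenerate inputs

* Zero-variance epochs receive the largest finite weight on their channel
  (with a warning) rather than an infinite one; weights always renormalize
  to sum to one per channel.
* Zero-variance differences make a *t* statistic undefined: `paired_t()`
  and `ratio_gt_one_t()` raise an error rather than report 0/0; the
  pipeline drops such comparisons (this actually occurs — simulated wave V
  latencies are often identical across conditions, as real ones nearly
  are).
* Ties at any extremum (envelope peak, CAP/wave V pick) break to the
  earlier latency and are reported.
* Fourier resampling is skipped entirely when input and output lengths
  match, so the zero-drift path is bit-exact.
* All simulation functions take explicit integer seeds and restore the
  caller's RNG state; derived seeds are kept below 2³¹.

## Known limitations

* The estimator inherits the published form's unweighted denominator (see
  above); a fully weighted generalized-least-squares variant is out of
  scope.
* Single-feature deconvolution only; no ridge/Tikhonov regularization and
  no multivariate TRFs.
* The auditory-nerve surrogate is qualitative; quantitative regressor
  comparisons require genuine nerve-model output via the external
  regressor interface.
* BrainVision support covers the subset the package writes (binary
  multiplexed/vectorized float32 and int16 with stimulus markers).
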