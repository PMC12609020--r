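---
title: "Methods: dual-scaling DFA and EEMD analysis of vibroarthrographic signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-scaling DFA and EEMD analysis of vibroarthrographic signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Vibroarthrography (VAG) records the vibrations and sounds a moving knee
joint transmits to the skin. Cartilage degeneration (chondromalacia,
osteoarthritis) changes the contact mechanics of the articular surfaces and
leaves traces in these signals: more high-frequency friction content,
alterations of the energy distribution across frequency bands, and changed
temporal correlation structure of the fluctuations. `vagdfa` implements a
dual-path analysis of such recordings:

1. **Feature path** — decompose each recording with ensemble empirical mode
   decomposition (EEMD), characterise every intrinsic mode function (IMF)
   by centroid frequency, mean instantaneous frequency, energy and a
   dual-scaling detrended fluctuation analysis (DFA) fit, aggregate into a
   12-dimensional band-level feature vector, screen by Mann-Whitney tests,
   weight by neighbourhood component analysis (NCA) and classify with an
   RBF-kernel support vector machine under stratified 5-fold
   cross-validation.
2. **Image path** — recombine the IMFs that show persistent, well-fitted
   correlation structure into short-scale (`x_alpha1`) and long-scale
   (`x_alpha2`) reconstructions, render raw and reconstructed signals as
   continuous-wavelet-transform (CWT) scalogram images, and classify the
   images with a compact convolutional network.

Clinical VAG recordings are not publicly distributable, so the package
ships a synthetic cohort generator that reproduces the statistical
structure the pipeline measures. Every stage is exercised and validated on
that generator.

## Preprocessing

Recordings cover ten flexion-extension cycles. Preprocessing is
trim → filter → normalize:

* **Cycle segmentation.** "Slope change" segmentation is operationalised as
  envelope-minimum detection: rectify the signal, smooth with a 0.25 s
  moving average, find envelope peaks at least 0.5 s apart, and place cycle
  boundaries at the envelope minima between consecutive peaks. Envelope
  minima are robust to the high-frequency content that dominates raw VAG
  signals. When fewer than the expected number of cycles is found, the
  intervals found are returned together with a warning flag.
* **Low-frequency noise removal.** A fourth-order Butterworth high-pass at
  10 Hz removes motion and environmental drift. The default is a causal
  single pass, matching the literal order of the stated filter; a
  zero-phase forward-backward variant is available (`zero_phase = TRUE`)
  because phase distortion can shift burst timing, at the cost of squaring
  the magnitude response.
* **Normalization** to `[0, 1]` by the min-max map. A constant (dead)
  channel maps to 0.5 everywhere and is flagged rather than erroring, so
  batch runs survive.

The trim → filter → normalize order is a package choice; the relative order
of trimming and filtering is immaterial for the downstream statistics as
long as normalization comes last.

## EEMD

Classical EMD extracts IMFs by iterated envelope-mean subtraction. The
sifting loop uses cubic splines through the maxima and minima with mirror
extension of the two outermost extrema at each boundary (suppresses end
swings), and stops on Huang's criterion `SD < 0.2` or after 50 iterations.
Plain EMD is complete by construction: the IMFs plus residue reproduce the
input to machine precision, and the test suite asserts a relative residual
below 1e-9.

EEMD decomposes `ensemble` noise-perturbed copies `x + r * sd(x) * w_e`
and averages the IMFs element-wise, which mitigates mode mixing. Defaults
are the reference settings of the pipeline: noise ratio `r = 0.01`,
`ensemble = 100`, and 10 components. Realizations can produce different
IMF counts, so each realization's list is zero-padded to 10 components
before averaging; trailing all-zero mean components are dropped. With
`noise_ratio = 0, ensemble = 1` EEMD reduces exactly to EMD. The residue is
excluded from all downstream features.

## Dual-scaling DFA with breakpoint detection

For a series `x`, the profile is `Y(k) = sum_{i<=k}(x_i - mean(x))`. For a
window size `n` the profile is split into `floor(N/n)` non-overlapping
segments from the start (the tail remainder is discarded — the simplest
faithful reading of non-overlapping segmentation, and exactly what the
brute-force oracle in the tests implements), a least-squares line is
removed from each segment (DFA-1, linear detrending only), and `F(n)` is
the root mean square residual. `F(n) ~ n^alpha` defines the scaling
exponent.

Because movement tempo varies between subjects, the window grid is
cycle-relative: 30 window lengths logarithmically spaced between 0.1 of a
cycle and two full cycles, rounded, deduplicated, and clamped to at least
4 samples. Zero, non-finite and invalid points are removed from the
log-log cloud before fitting; at least 6 points must survive.

The two-segment fit reviews every admissible breakpoint (at least 3 points
per side), fits ordinary least squares lines to both sides, and selects
the split with the lowest total residual sum of squares. Exact ties break
toward the smallest index, for determinism. The short-scale slope is
`alpha1`, the long-scale slope `alpha2`, each with its own R²; the
breakpoint is reported both as a window size in samples and as
`bp_ratio = bp_scale / signal length`, the convention used when quoting
the breakpoint as a fraction of total signal duration. The fit object also
carries `alpha_overall`, the single-line slope, which is the natural
estimate when a series has one scaling regime.

Natural logarithms are used throughout; slopes are base-invariant.

## Reconstruction criteria

An IMF joins the short-scale reconstruction when `alpha1 > 0.5` (positive
temporal correlations, persistence) **and** `r2_1 > 0.9` (reliable fit);
the long-scale reconstruction applies the same rule to `alpha2`/`r2_2`.
Both inequalities are strict, so an exponent of exactly 0.5 is excluded.
Recordings where no component qualifies keep a zero signal with a flag
rather than being dropped, so cohort sizes and class balance survive to
cross-validation; the scalogram of a zero signal is a uniform image.

## Features and screening

Per IMF: centroid frequency (Welch power spectral density with a Hann
window, segments of `min(1024, n)` samples, 50% overlap — the estimator is
a package choice), mean instantaneous frequency (derivative of the
unwrapped analytic-signal phase, excluding 5% of samples at each edge and
clipping negative instantaneous values to zero, both guarding against the
known unreliability of the analytic phase at edges and near-zero
amplitudes), and energy (sum of squares).

IMFs are grouped by index alone — high (IMF 1–3), mid (IMF 4–6), low
(IMF 7–10) — and each band contributes the mean of CF, MIF, energy and
DFA breakpoint ratio: 12 features in a fixed order. The breakpoint ratio
is computed per band (three features), consistent with the
3-bands-by-4-parameters layout.

Screening: normality of each feature per group is assessed with a
Lilliefors test whose p-value comes from a seeded Monte-Carlo null (2000
standard-normal samples of the same `n`, add-one correction) — exact in
`n` and fully reproducible. Normality results are reported but gate
nothing; the selection gate is the two-sided Mann-Whitney U test at
`p < 0.05`, computed with midrank ties, exact enumeration for combined
sizes up to 12 and a tie-corrected normal approximation with continuity
correction otherwise. No multiple-testing correction is applied by design.

## NCA weighting and SVM

NCA maximises the regularised leave-one-out soft-nearest-neighbour
objective `mean_i p_i - lambda * sum(w^2)` with
`p_ij ∝ exp(-sum_k w_k^2 |x_ik - x_jk|)` on standardised features and
`lambda = 1/n`. Three numerical choices matter and were validated by
simulation:

* **Initialisation** at `w = 1/sqrt(p)` gives unit initial length scale
  (starting pairwise distances are O(1) regardless of dimension), keeping
  the softmax smooth at the start of the ascent.
* **Convergence tolerance**: the backtracking gradient ascent stops when
  an accepted step improves the objective by less than 1e-3. Informative
  features produce large early gains and are found immediately; running
  the ascent to full stationarity instead lets the leave-one-out objective
  chase sample-specific optima on uninformative designs (in-sample
  overfitting), which simulation shows concentrates weight on noise
  features in a substantial fraction of seeds.
* **Reporting**: weights are `(w^2 + 1e-3) / sum(w^2 + 1e-3)`. The ridge
  makes the all-irrelevant fixed point — every raw weight shrunk to
  numerical zero — report near-uniform weights instead of amplifying
  noise in the normalisation.

Weights are normalised to sum 1, so the 0.05 exclusion cutoff sits below
the uniform weight 1/12 ≈ 0.083 of a 12-feature set. An empty selection
falls back to the top three weights with a warning.

The SVM uses an RBF kernel with cost 1 and the `1/(p * var)` bandwidth
convention, standardisation fitted inside each training fold (no
leakage), and signed decision values for the ROC — sufficient for
ranking, so no probability calibration is attempted. Screening and NCA
run on the full data set before cross-validation, mirroring the
pipeline's stated sequence; the optimistic bias this implies affects both
classes equally and is documented here deliberately.

Stratified fold assignment, fold metrics (accuracy, sensitivity = recall,
specificity, precision, F1), trapezoidal AUC (equal to the pairwise
concordance estimator with ties counted 1/2) and per-fold confusion
counts are reported as tibbles with `tidy()`/`glance()`/`autoplot()`
methods. The positive class is OA throughout: sensitivity is the rate of
detecting disease.

## Scalograms and the CNN

Scalograms use an analytic Morlet wavelet (centre-frequency parameter 6)
over 64 logarithmically spaced scales spanning pseudo-frequencies from
5 Hz to `fs/2.5`; the identical grid object is reused for every signal in
a run and its hash is stamped into each image. The magnitude matrix is
min-max normalised per image, mapped through a numerically pinned
256-entry jet table (classic blue→cyan→yellow→red breakpoints, generated
from closed-form expressions so images are bit-exact across platforms),
and bilinearly resized to 128² or 256². A constant matrix maps to the
mid-colormap colour with a flag. Resizing one CWT (rather than
regenerating CWTs per target size) is the package's choice.

The CNN is three Conv(3×3, same padding)–BatchNorm–ReLU–MaxPool(2×2)
blocks with 16/32/64 filters, dropout 0.4, a single dense layer and a
softmax over {HC, OA}; training uses Adam (step size 1e-3) for 30 epochs,
batch size 32, and an L2 penalty of 0.01 on convolutional and dense
weights. Filter counts, dense width and step size are declared defaults
(only the pattern of increasing filters is fixed by the architecture
description). Augmentation — rotations ±10°, scaling 0.9–1.1,
translations ±5 px, horizontal flips — applies to training folds only.
The decision rule is asymmetric: predict HC only when `P(HC) >= 0.7`,
otherwise OA (cases *below* the threshold go to OA, so the boundary value
0.7 itself is HC). AUC uses the raw OA probability.

The network is implemented in R with im2col gathers and BLAS matrix
products; the hand-derived backward pass is verified against finite
differences in the test suite to 1e-4 relative. Because smoke-test runs
use few optimisation steps, batch-norm running statistics are
recalibrated with full forward passes over the training fold after
training — a standard recalibration that makes evaluation-mode statistics
meaningful regardless of epoch count.

## The synthetic cohort generator

Each recording is `envelope × (band noise + clicks) + fluctuation`:

* envelope `(1 - m) + m * |sin(pi t / cycle_s)|` with modulation depth
  `m = 0.8` — ten cycles of 3 s at 4 kHz by default, so the 300/150 Hz
  band edges sit far inside Nyquist;
* three Gaussian noise bands (relative powers and centres from the group
  profile; half-octave bandwidths, FFT band-pass with raised-cosine
  edges);
* Poisson-timed damped sinusoidal bursts at 600–900 Hz (5 ms decay),
  emulating friction clicks;
* an additive fluctuation component with a planted scaling crossover: an
  fGn(`H_short`) component plus a low-pass-filtered fGn(`H_long`)
  component, amplitude-balanced so their detrended fluctuations are equal
  exactly at the planted crossover scale. Spectral mixing (not
  concatenation) keeps both regimes present at all times, which is how
  DFA sees real signals.

Fractional Gaussian noise comes from exact circulant embedding of the fGn
autocovariance (spectral synthesis as fallback); power-law noise for the
DFA calibration tests comes from two-sided spectral shaping. Default
group profiles give the osteoarthritis group stronger high-band energy,
slightly higher band centres, frequent clicks and stronger short-scale
persistence (`H_short` 0.85 vs 0.60) than the healthy profile — the
direction of effects the pipeline is designed to detect. Per-recording
seeds are derived by hashing `(group, subject, channel)` with the master
seed, so cohorts are extensible without reshuffling existing subjects.

What the generator does **not** emulate: biomechanically realistic joint
acoustics, inter-subject variability structure, sensor coupling and
artefacts, or any correlation between channels. Passing tests therefore
demonstrate that the pipeline recovers planted statistical structure of
the stated kind — not clinical performance on real recordings.

## Problem sizes used in validation

The validation suite chooses sizes where each property is statistically
decisive yet quick: DFA exponent recovery uses series of 2^14 samples
averaged over 20 seeds; breakpoint-oracle equivalence uses 100 random
log-log clouds; crossover recovery uses 20 seeds of 2^15 samples;
screening calibration uses 100 Mann-Whitney runs, 50 NCA runs and 500
Lilliefors replicates; the end-to-end feature path uses a cohort of 40
recordings per group (2 kHz, ten 1 s cycles, EEMD ensemble 8); the CNN
smoke test uses 40 scalograms per class at 128² with 3 epochs. Full
reference settings (4 kHz, 3 s cycles, ensemble 100, 30 epochs) remain
the defaults of `default_config()`.

## Known limitations

* The screening/NCA-before-CV sequence leaks label information into
  feature selection; reported CV metrics are optimistic for small
  cohorts.
* DFA-1 with a forward-only partition discards up to one window of
  samples per scale; higher-order detrending and bidirectional averaging
  are out of scope.
* The Lilliefors Monte-Carlo p is exact only up to simulation error
  (~1/sqrt(mc_reps)).
* The CNN is a faithful but compact reference implementation; it trains
  on CPU at small image counts and is not intended for large-scale image
  corpora.
* Empty reconstructions (no IMF passing the criteria) enter
  classification as uniform images; with many such recordings the image
  path degrades gracefully but uninformatively.
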