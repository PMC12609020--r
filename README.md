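# vagdfa

Dual-path analysis of vibroarthrographic (VAG) signals — the vibrations a
moving knee joint transmits to the skin — for discriminating
osteoarthritic (OA) from healthy (HC) knees.

Cartilage degeneration changes the joint's contact mechanics and leaves
traces in VAG recordings: more high-frequency friction content, shifted
band energies, and altered temporal correlation structure. `vagdfa`
implements a complete pipeline around two complementary representations:

1. **Feature path.** Each preprocessed recording (cycle segmentation,
   4th-order Butterworth high-pass at 10 Hz, min-max normalization) is
   decomposed by ensemble empirical mode decomposition (EEMD; noise ratio
   0.01, 100 realizations, 10 IMFs). Every intrinsic mode function is
   characterised by its centroid frequency `CF = Σ f·P(f) / Σ P(f)`, mean
   instantaneous frequency (Hilbert phase derivative), energy `Σ x²`, and
   a dual-scaling detrended fluctuation analysis fit: the log–log
   fluctuation function `F(n) ~ n^α` is fitted with two segments, the
   breakpoint chosen by exhaustive minimum-RSS search, giving short- and
   long-scale exponents α₁, α₂ and the breakpoint position. Band means
   over IMFs 1–3 / 4–6 / 7–10 yield 12 features, screened by Mann–Whitney
   U tests (p < 0.05), weighted by neighbourhood component analysis
   (cutoff 0.05), and classified by an RBF-SVM under stratified 5-fold CV.
2. **Image path.** IMFs with persistent, well-fitted correlations
   (α > 0.5 and R² > 0.9, per scale range) are summed into α₁-/α₂-based
   reconstructions; raw and reconstructed signals become Morlet CWT
   scalograms (jet colormap, 128² or 256²) classified by a compact
   three-block CNN with an asymmetric HC-probability threshold of 0.7.

Clinical VAG data are not publicly available, so the package includes a
synthetic cohort generator (`generate_cohort()`) with planted group
effects — band energies, click bursts, scaling crossovers — that makes
every stage testable end to end.

## Worked example

```r
library(vagdfa)

# A small synthetic cohort: 10 recordings per group, planted OA effects
spec <- cohort_spec(n_per_group = 10, fs_hz = 2000, cycle_s = 1,
                    n_cycles = 10, seed = 1)
cohort <- generate_cohort(spec)

# Preprocess + EEMD + per-IMF features + per-IMF dual-scaling DFA
features <- cohort_features(cohort, seed = 1, ensemble = 10)
screening <- screen_features(features, seed = 1)
dplyr::filter(screening, kept)
#> # A tibble: 7 × 6
#>   feature     lilliefors_p_hc lilliefors_p_oa  mw_u     mw_p kept
#>   <chr>                 <dbl>           <dbl> <dbl>    <dbl> <lgl>
#> 1 high_cf               0.152          0.175      0 0.000183 TRUE
#> 2 high_mif              0.286          0.423      0 0.000183 TRUE
#> 3 high_energy           0.694          0.815     93 0.00131  TRUE
#> 4 mid_cf                0.411          0.193     22 0.0376   TRUE
#> 5 mid_mif               0.583          0.0905     0 0.000183 TRUE
#> 6 mid_energy            0.544          0.897     98 0.000330 TRUE
#> 7 low_energy            0.696          0.866     93 0.00131  TRUE

# NCA weighting, selection at the 0.05 cutoff, RBF-SVM with 5-fold CV
keep <- screening$feature[screening$kept]
X <- scale(as.matrix(features[, keep]))
w <- nca_weights(X, features$group)
sel <- select_by_weight(w)
report <- svm_rbf_cv(X[, sel, drop = FALSE], features$group, k = 5, seed = 1)
report
#> <vag_cv_report> 5-fold CV: accuracy 1.000 +/- 0.000, AUC 1.000 +/- 0.000 (positive: OA)
glance(report)      # one row of mean/sd per metric
autoplot(report)    # per-fold ROC curves
```

The screening table shows the planted group effects where they were
planted: the OA profile has stronger and faster high-band content, so the
high-band centroid frequency, instantaneous frequency and energy separate
the groups (Mann–Whitney p ≪ 0.05), while the breakpoint-ratio features
on this small cohort do not pass the gate. On the clearly
separated synthetic cohort the cross-validated SVM is at ceiling; the
permutation null (`svm_rbf_cv` on shuffled labels) falls back to chance.

A single dual-scaling DFA fit is just as accessible:

```r
x <- generate_crossover_series(H_short = 0.5, H_long = 0.9, crossover_s = 0.5,
                               fs_hz = 1000, n = 2^15, seed = 1,
                               integrate_long = TRUE)
fit <- dfa_dual(x, windows = round(exp(seq(log(16), log(4096), length.out = 30))))
fit
#> <vag_dual_fit> alpha1 = 0.537 (R2 0.992), alpha2 = 1.622 (R2 0.992), breakpoint 413 samples (0.013 of signal)
autoplot(fit)   # log-log cloud, two fitted segments, detected breakpoint
```

The planted crossover at 0.5 s × 1000 Hz = 500 samples is detected at 413
samples — within the factor-of-two band the recovery tests require — with
the short scales at the white-noise exponent and the long scales
reflecting the integrated persistent component.

The whole pipeline (simulate → preprocess → decompose → DFA → features →
reconstruct → SVM / scalograms → CNN → report) runs from one config and
one seed:

```r
cfg <- default_config(out_dir = "vag_run", seed = 1)
run_pipeline(cfg)                       # all stages, plain-file outputs
run_pipeline(cfg, stages = c("simulate", "preprocess"))  # stage gating
```

or from the shell via the thin CLI wrapper:

```sh
Rscript inst/cli/vagdfa.R run --out vag_run --seed 1
```

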