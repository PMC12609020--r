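test_that("fGn matches its analytic lag-1 autocovariance and is deterministic", {
  n <- 2^14
  # white-noise limit
  r1_white <- mean(sapply(1:5, function(s) {
    x <- generate_fgn(0.5, n, s)
    sum(x[-1] * x[-n]) / sum(x^2)
  }))
  expect_lt(abs(r1_white), 0.05)
  # persistent case: r1 = 2^(2H-1) - 1 = 0.741 for H = 0.9 (zero-mean process,
  # so the raw, non-demeaned estimator is the right oracle)
  r1_pers <- mean(sapply(1:10, function(s) {
    x <- generate_fgn(0.9, n, s)
    sum(x[-1] * x[-n]) / sum(x^2)
  }))
  expect_lt(abs(r1_pers - (2^(2 * 0.9 - 1) - 1)), 0.05)
  expect_identical(generate_fgn(0.7, 1024, 42), generate_fgn(0.7, 1024, 42))
})

test_that("colored noise has the DFA exponent implied by its spectral slope", {
  a_pink <- mean(sapply(1:5, function(s) {
    dfa_dual(generate_colored_noise(1, 2^13, s))$alpha_overall
  }))
  expect_lt(abs(a_pink - 1), 0.15)
})

test_that("crossover series plant two regimes; equal-H input stays single-regime", {
  x <- generate_crossover_series(0.5, 0.9, 0.5, 1000, 2^14, 7,
                                 integrate_long = TRUE)
  f <- dfa_dual(x, windows = sort(unique(round(exp(seq(log(16), log(2^14 / 8),
                                                       length.out = 30))))))
  expect_lt(abs(f$alpha1 - 0.5), 0.15)
  expect_gt(f$alpha2, 1.0)
  # no planted crossover: two-segment slopes nearly equal
  x1 <- generate_crossover_series(0.6, 0.6, 0.5, 1000, 2^13, 8)
  f1 <- dfa_dual(x1)
  expect_lt(abs(f1$alpha1 - f1$alpha2), 0.15)
  expect_identical(generate_crossover_series(0.5, 0.8, 0.3, 1000, 2^12, 3),
                   generate_crossover_series(0.5, 0.8, 0.3, 1000, 2^12, 3))
  expect_error(generate_crossover_series(0.5, 0.9, 10, 1000, 2^12, 1),
               "representable")
})

test_that("low-band-only recordings put >90% of Welch power below 150 Hz", {
  spec <- small_spec()
  prof <- group_profile(band_energy = c(0, 0, 1), click_rate_hz = 0)
  rec <- generate_recording(prof, spec, "s01", 3)
  p <- welch_psd(rec$samples, spec$fs_hz)
  expect_gt(sum(p$psd[p$freq < 150]) / sum(p$psd), 0.9)
})

test_that("the cyclic envelope leaves variance minima at cycle boundaries", {
  spec <- small_spec()
  prof <- group_profile(mod_depth = 1)
  rec <- generate_recording(prof, spec, "s01", 9)
  fs <- spec$fs_hz
  w <- round(0.02 * fs)
  var_at <- function(center) {
    idx <- max(1, center - w):min(length(rec$samples), center + w)
    var(rec$samples[idx])
  }
  bounds <- round(seq(1, spec$n_cycles) * spec$cycle_s * fs)
  mids <- round((seq(1, spec$n_cycles) - 0.5) * spec$cycle_s * fs)
  expect_true(mean(sapply(bounds[-length(bounds)], var_at)) <
                0.5 * mean(sapply(mids, var_at)))
})

test_that("click-rich profiles raise high-band EEMD energy over click-free ones", {
  spec <- cohort_spec(n_per_group = 2, fs_hz = 2000, cycle_s = 1,
                      n_cycles = 3, seed = 1)
  prof_oa <- group_profile(band_energy = c(1.5, 1, 1.4), click_rate_hz = 8,
                           H_short = 0.85)
  prof_hc <- group_profile(band_energy = c(0.6, 1, 2), click_rate_hz = 0,
                           H_short = 0.6)
  wins <- 0
  n_pairs <- 10
  for (s in seq_len(n_pairs)) {
    hi_energy <- function(prof, sd) {
      rec <- generate_recording(prof, spec, "s", sd)
      d <- eemd(rec$samples, noise_ratio = 0.01, ensemble = 2, seed = sd)
      sum(sapply(d$imfs[1:min(3, length(d$imfs))], signal_energy))
    }
    if (hi_energy(prof_oa, 100 + s) > hi_energy(prof_hc, 200 + s)) wins <- wins + 1
  }
  expect_gte(wins / n_pairs, 0.8)
})

test_that("cohorts are balanced, reproducible and mutually uncorrelated", {
  spec <- cohort_spec(n_per_group = 5, fs_hz = 2000, cycle_s = 1,
                      n_cycles = 3, seed = 21)
  coh <- generate_cohort(spec)
  expect_equal(length(coh$recordings), 10)
  expect_equal(sum(coh$manifest$group == "HC"), 5)
  coh2 <- generate_cohort(spec)
  expect_identical(coh$recordings[[1]]$samples, coh2$recordings[[1]]$samples)
  expect_identical(coh$manifest, coh2$manifest)
  # pairwise correlations of distinct subjects are near zero
  cors <- combn(6, 2, function(ij) {
    cor(coh$recordings[[ij[1]]]$samples, coh$recordings[[ij[2]]]$samples)
  })
  expect_lt(max(abs(cors)), 0.1)
})

test_that("cohorts round-trip through disk in the manifest dialect", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_per_group = 2, fs_hz = 2000, cycle_s = 1,
                      n_cycles = 3, seed = 2)
  coh <- generate_cohort(spec)
  man_path <- write_cohort(coh, dir)
  man <- read_manifest(man_path)
  expect_equal(nrow(man), 4)
  rec <- read_recording(file.path(dir, man$path[1]), manifest_row = man[1, ])
  expect_equal(rec$samples, coh$recordings[[man$path[1]]]$samples,
               tolerance = 1e-10)
})
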