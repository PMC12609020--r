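test_that("centroid frequency matches spectral-line and flat-spectrum oracles", {
  fs <- 1000
  expect_equal(centroid_frequency(tone(100, fs, 4096), fs), 100, tolerance = 2)
  x2 <- tone(100, fs, 4096) + tone(300, fs, 4096)
  expect_equal(centroid_frequency(x2, fs), 200, tolerance = 5)
  cf_white <- mean(sapply(1:20, function(s) {
    set.seed(s)
    centroid_frequency(rnorm(4096), fs)
  }))
  expect_equal(cf_white, 250, tolerance = 10)
  expect_true(is.nan(centroid_frequency(numeric(128), fs)))
})

test_that("mean instantaneous frequency follows the analytic-signal phase", {
  fs <- 1000
  expect_equal(mean_instantaneous_frequency(tone(50, fs, 4096), fs), 50,
               tolerance = 1)
  # linear chirp 10 -> 110 Hz: mean instantaneous frequency is the midpoint
  n <- 8192
  t <- (0:(n - 1)) / fs
  T_end <- max(t)
  chirp <- sin(2 * pi * (10 * t + (100 / (2 * T_end)) * t^2))
  expect_equal(mean_instantaneous_frequency(chirp, fs), 60, tolerance = 3)
  # amplitude modulation does not move the carrier estimate
  am <- (1 + 0.1 * sin(2 * pi * 3 * t)) * sin(2 * pi * 80 * t)
  expect_equal(mean_instantaneous_frequency(am, fs), 80, tolerance = 3)
  expect_true(is.nan(mean_instantaneous_frequency(numeric(128), fs)))
})

test_that("energy is the exact sum of squares and is additive", {
  expect_identical(signal_energy(c(1, 2, 3)), 14)
  expect_identical(signal_energy(numeric(10)), 0)
  set.seed(1)
  for (i in 1:10) {
    x <- rnorm(50); y <- rnorm(30)
    expect_equal(signal_energy(c(x, y)), signal_energy(x) + signal_energy(y),
                 tolerance = 1e-12)
  }
  expect_error(signal_energy(c(1, Inf)), "[Nn]on-finite")
})

test_that("band membership depends on the IMF index only", {
  expect_equal(imf_band(1:10),
               c(rep("high", 3), rep("mid", 3), rep("low", 4)))
  expect_error(imf_band(11))
})

test_that("band aggregation averages per band in fixed order", {
  rows <- tibble::tibble(
    imf_index = 1:10,
    cf_hz = c(500, 500, 500, 200, 210, 190, 50, 60, 40, 50),
    mif_hz = cf_hz,
    energy = c(1, 2, 3, rep(4, 3), rep(8, 4)),
    band = imf_band(1:10)
  )
  fits <- tibble::tibble(imf_index = 1:10, bp_ratio = seq(0.1, 1, by = 0.1))
  v <- aggregate_band_features(rows, fits)
  expect_equal(names(v), vagdfa:::FEATURE_NAMES)
  expect_equal(unname(v["high_energy"]), 2)
  expect_equal(unname(v["high_cf"]), 500)
  expect_equal(unname(v["mid_bp_ratio"]), 0.5)
  expect_equal(unname(v["low_energy"]), 8)

  # permuting IMFs within a band leaves the vector unchanged
  perm <- c(3, 1, 2, 6, 4, 5, 9, 10, 7, 8)
  v2 <- aggregate_band_features(rows[perm, ], fits[perm, ])
  expect_equal(v2, v)

  # all-missing band is flagged non-finite
  rows$energy[7:10] <- NaN
  v3 <- aggregate_band_features(rows, fits)
  expect_true(is.nan(v3[["low_energy"]]))
})

test_that("recording-level features carry metadata and all 12 columns", {
  spec <- small_spec()
  rec <- generate_recording(default_profiles()$OA, spec, "s01", 4, group = "OA")
  pre <- preprocess_recording(rec, n_cycles = 6)
  ft <- recording_features(pre, ensemble = 2, seed = 1)
  expect_equal(nrow(ft), 1)
  expect_equal(ft$group, "OA")
  expect_true(all(vagdfa:::FEATURE_NAMES %in% names(ft)))
  expect_true(all(is.finite(unlist(ft[, vagdfa:::FEATURE_NAMES]))))
})
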