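test_that("cycle detection recovers the known period of envelope-modulated noise", {
  fs <- 1000
  T_cyc <- 1.0
  ok_count <- 0
  for (s in 1:20) {
    set.seed(s)
    t <- (0:(10 * T_cyc * fs - 1)) / fs
    x <- abs(sin(pi * t / T_cyc)) * rnorm(length(t))
    cyc <- suppressWarnings(detect_cycles(x, fs, n_cycles = 10))
    lens <- cyc$end - cyc$start + 1
    if (nrow(cyc) == 10 && all(abs(lens - T_cyc * fs) <= 0.1 * T_cyc * fs)) {
      ok_count <- ok_count + 1
    }
  }
  expect_gte(ok_count, 18)
})

test_that("degenerate inputs yield zero or fewer cycles with a warning flag", {
  cyc <- suppressWarnings(detect_cycles(rep(1, 2000), 1000))
  expect_equal(nrow(cyc), 0)
  expect_true(attr(cyc, "warning_flag"))

  fs <- 1000
  t <- (0:(3 * fs - 1)) / fs
  set.seed(1)
  x3 <- abs(sin(pi * t / 1.0)) * rnorm(length(t))
  expect_warning(cyc3 <- detect_cycles(x3, fs, n_cycles = 10), "Found")
  expect_lte(nrow(cyc3), 3 + 1)
  expect_true(attr(cyc3, "warning_flag"))
})

test_that("high-pass filter removes DC and matches the analytic Butterworth response", {
  fs <- 2000
  n <- 10 * fs
  # DC in the stopband
  y <- remove_low_frequency(rep(2, n), fs)
  expect_lt(max(abs(tail(y, n / 2))), 1e-3 * 2)
  # passband tone preserved within 5%
  x100 <- tone(100, fs, n)
  y100 <- remove_low_frequency(x100, fs)
  amp <- max(abs(tail(y100, n / 2)))
  expect_lt(abs(amp - 1), 0.05)
  # deep-stopband tone attenuated per the 4th-order magnitude |H| ~ (f/fc)^4
  y1 <- remove_low_frequency(tone(1, fs, n), fs)
  meas <- max(abs(tail(y1, n / 2)))
  pred <- (1 / 10)^4 / sqrt(1 + (1 / 10)^8)
  expect_lt(abs(log10(meas / pred)), 0.35)
  # zero-phase variant also suppresses DC
  yz <- remove_low_frequency(rep(2, n), fs, zero_phase = TRUE)
  expect_lt(max(abs(yz[(n / 4):(3 * n / 4)])), 1e-3 * 2)
  expect_error(remove_low_frequency(rnorm(100), 15, cutoff_hz = 10), "Nyquist")
})

test_that("unit-interval normalization maps extremes to 0/1 and is idempotent", {
  expect_equal(as.numeric(normalize_unit_interval(c(2, 4, 6))), c(0, 0.5, 1))
  expect_equal(as.numeric(normalize_unit_interval(c(-1, 1))), c(0, 1))
  z <- normalize_unit_interval(c(5, 5, 5))
  expect_equal(as.numeric(z), rep(0.5, 3))
  expect_true(attr(z, "degenerate_flag"))
  set.seed(3)
  x <- rnorm(100)
  once <- normalize_unit_interval(x)
  twice <- normalize_unit_interval(as.numeric(once))
  expect_equal(as.numeric(once), as.numeric(twice))
  expect_error(normalize_unit_interval(c(1, NA, 3)), "[Nn]on-finite")
})

test_that("preprocessing preserves sample count through filter and normalization", {
  spec <- small_spec()
  rec <- generate_recording(default_profiles()$HC, spec, "s01", 5)
  pre <- preprocess_recording(rec, n_cycles = 6)
  trimmed_len <- pre$cycle_bounds$end[nrow(pre$cycle_bounds)]
  expect_equal(length(pre$samples), trimmed_len)
  expect_equal(range(pre$samples), c(0, 1))
  expect_equal(nrow(pre$cycle_bounds), 6)
  expect_equal(pre$cycle_len, 1 * 2000, tolerance = 0.1)
})
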