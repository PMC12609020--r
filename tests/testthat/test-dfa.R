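test_that("the DFA profile is the centred cumulative sum", {
  expect_equal(dfa_profile(c(1, 2, 3)), c(-1, -1, 0))
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(100)
    y <- dfa_profile(x)
    expect_equal(y[length(y)], 0, tolerance = 1e-12)
  }
  expect_equal(dfa_profile(rep(3, 50)), rep(0, 50))
})

test_that("the fluctuation function matches a naive brute-force implementation", {
  set.seed(2)
  y <- dfa_profile(rnorm(2^12))
  for (n in c(16, 37, 128, 500)) {
    expect_equal(dfa_fluctuation(y, n), fluct_naive(y, n), tolerance = 1e-12)
  }
  # exactly linear profile detrends to zero
  expect_equal(dfa_fluctuation(2 + 0.3 * seq_len(1000), 25), 0, tolerance = 1e-10)
  expect_error(dfa_fluctuation(y, 2), "Window size")
  expect_error(dfa_fluctuation(y, length(y)), "Window size")
})

test_that("the window grid is log-spaced between 0.1 and 2 cycles", {
  g <- dfa_window_grid(1000, 40000)
  expect_equal(min(g), 100)
  expect_equal(max(g), 2000)
  expect_equal(length(g), 30)
  ratios <- exp(diff(log(g)))
  expect_equal(mean(ratios), 20^(1 / 29), tolerance = 0.01)

  g2 <- dfa_window_grid(100, 4000)
  expect_equal(min(g2), 10)
  expect_equal(max(g2), 200)
  expect_equal(g2, sort(unique(g2)))
  g2b <- dfa_window_grid(50, 4000)  # small windows collide after rounding
  expect_lt(length(g2b), 30)
  expect_equal(g2b, sort(unique(g2b)))

  g3 <- dfa_window_grid(40.4, 4000)   # 0.1 cycle rounds to 4
  expect_equal(min(g3), 4)
  expect_error(dfa_window_grid(1000, 3000), "exceed")
})

test_that("log-log cleaning drops degenerate points and enforces the minimum", {
  w <- c(4, 8, 16, 32, 64, 128, 256, 512)
  f <- c(1, 2, 0, 4, NaN, 16, 32, 64)
  cl <- clean_loglog(w, f)
  expect_equal(length(cl$log_n), 6)
  expect_equal(cl$log_f, log(c(1, 2, 4, 16, 32, 64)))
  f_ok <- 2^(seq_along(w))
  cl2 <- clean_loglog(w, f_ok)
  expect_equal(cl2$log_n, log(w))
  expect_error(clean_loglog(w[1:6], c(1, 2, 0, 4, 5, 6)), "6 usable")
})

test_that("dual_fit recovers exact piecewise-linear structure and tie-breaks low", {
  log_n <- log(seq(4, 400, length.out = 30))
  i_true <- 12
  # two lines crossing strictly between points 12 and 13, so the zero-RSS
  # split is unique (a crossing exactly at a grid point would tie)
  x_cross <- (log_n[i_true] + log_n[i_true + 1]) / 2
  log_f <- ifelse(seq_along(log_n) <= i_true,
                  0.5 * log_n,
                  1.2 * log_n + (0.5 - 1.2) * x_cross)
  fit <- dual_fit(log_n, log_f)
  expect_equal(fit$bp_index, i_true)
  expect_equal(fit$alpha1, 0.5, tolerance = 1e-10)
  expect_equal(fit$alpha2, 1.2, tolerance = 1e-10)
  expect_equal(fit$rss_total, 0, tolerance = 1e-18)
  expect_equal(fit$r2_1, 1)
  expect_equal(fit$r2_2, 1)

  # single line: slopes equal, split falls to the smallest admissible index
  log_f1 <- 0.8 * log_n + 1
  fit1 <- dual_fit(log_n, log_f1)
  expect_equal(fit1$alpha1, 0.8, tolerance = 1e-10)
  expect_equal(fit1$alpha2, 0.8, tolerance = 1e-10)
  expect_equal(fit1$bp_index, 3)
  expect_error(dual_fit(rep(1, 10), rnorm(10)), "increasing")
})

test_that("dual_fit equals the exhaustive brute-force search on random clouds", {
  set.seed(3)
  for (r in 1:100) {
    p <- sample(8:30, 1)
    log_n <- sort(log(sample(4:3000, p)))
    if (any(diff(log_n) == 0)) next
    log_f <- 0.7 * log_n + rnorm(p, sd = 0.3)
    fit <- dual_fit(log_n, log_f)
    oracle <- dual_fit_naive(log_n, log_f)
    expect_equal(fit$bp_index, oracle$i)
    expect_equal(fit$alpha1, oracle$a1, tolerance = 1e-10)
    expect_equal(fit$alpha2, oracle$a2, tolerance = 1e-10)
  }
})

test_that("two segments never fit worse than one line", {
  set.seed(4)
  for (r in 1:100) {
    log_n <- sort(log(sample(4:2000, 20)))
    log_f <- rnorm(20)
    fit <- dual_fit(log_n, log_f)
    one <- sum(residuals(lm(log_f ~ log_n))^2)
    expect_lte(fit$rss_total, one + 1e-12)
  }
})

test_that("F(n) grows monotonically with scale for persistent signals", {
  rhos <- sapply(1:5, function(s) {
    x <- generate_fgn(0.7, 2^12, s)
    y <- dfa_profile(x)
    w <- sort(unique(round(exp(seq(log(4), log(2^12 / 4), length.out = 25)))))
    f <- sapply(w, function(n) dfa_fluctuation(y, n))
    cor(rank(w), rank(f), method = "spearman")
  })
  expect_true(all(rhos > 0.9))
})

test_that("per-IMF fits share the cycle grid and flag failures as missing", {
  n <- 2^14
  # mean exponents over seeds: injected fGn(0.5) yields alpha1 = alpha2 = 0.5
  fits_all <- lapply(1:20, function(s) {
    decomp <- vagdfa:::new_imf_decomposition(
      list(generate_fgn(0.5, n, s)), numeric(n), list(ensemble = 1L))
    dfa_dual_imfs(decomp, cycle_len = n / 10)
  })
  a1 <- sapply(fits_all, function(f) f$alpha1[1])
  a2 <- sapply(fits_all, function(f) f$alpha2[1])
  expect_lt(abs(mean(a1) - 0.5), 0.1)
  expect_lt(abs(mean(a2) - 0.5), 0.1)

  imfs <- lapply(1:3, function(i) generate_fgn(0.5, 4096, i))
  fits <- dfa_dual_imfs(
    vagdfa:::new_imf_decomposition(imfs, numeric(4096), list(ensemble = 1L)),
    cycle_len = 410)
  expect_equal(nrow(fits), 3)
  expect_equal(fits$bp_ratio, fits$bp_scale / 4096)

  # a constant IMF produces F(n) = 0 everywhere -> flagged missing fit
  decomp2 <- vagdfa:::new_imf_decomposition(
    c(imfs, list(numeric(4096))), numeric(4096), list(ensemble = 1L))
  fits2 <- dfa_dual_imfs(decomp2, cycle_len = 410)
  expect_true(is.na(fits2$alpha1[4]))
})

test_that("tidiers and autoplot work on a dual fit", {
  f <- dfa_dual(generate_fgn(0.5, 4096, 1))
  td <- tidy(f)
  expect_equal(td$segment, c("short", "long"))
  gl <- glance(f)
  expect_equal(gl$alpha1, f$alpha1)
  p <- autoplot(f)
  expect_s3_class(p, "ggplot")
})
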