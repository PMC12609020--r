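# Detrended fluctuation analysis with an adaptive, cycle-relative window
# grid and an automatic two-segment (alpha1/alpha2) piecewise log-log fit
# with breakpoint detection.

#' DFA profile (cumulative sum of centred values)
#'
#' `Y(k) = sum_{i<=k} (x_i - mean(x))`.
#'
#' @param x Numeric vector, length >= 16.
#' @return Numeric vector of the same length.
#' @export
dfa_profile <- function(x) {
  stopifnot(length(x) >= 3)
  cumsum(x - mean(x))
}

#' Fluctuation function at one window size
#'
#' Partitions the profile into `floor(N/n)` non-overlapping segments from the
#' start (tail remainder discarded), removes a least-squares line from each
#' segment, and returns the root mean square residual over all covered
#' samples.
#'
#' @param y DFA profile (from [dfa_profile()]).
#' @param n Window size in samples, `4 <= n <= length(y)/2`.
#' @return Scalar `F(n)`.
#' @export
dfa_fluctuation <- function(y, n) {
  N <- length(y)
  n <- as.integer(n)
  if (n < 4 || n > N / 2) abort("Window size `n` must satisfy 4 <= n <= length(y)/2.")
  m <- N %/% n
  ymat <- matrix(y[seq_len(n * m)], nrow = n)
  tt <- seq_len(n)
  qrX <- qr(cbind(1, tt))
  res <- qr.resid(qrX, ymat)
  sqrt(mean(res^2))
}

#' Cycle-relative logarithmic window grid
#'
#' 30 window lengths logarithmically spaced between 0.1 of a cycle and two
#' full cycles, rounded to integers, deduplicated, clamped to >= 4 samples.
#'
#' @param cycle_len Mean cycle length in samples.
#' @param signal_len Signal length in samples.
#' @param n_windows Number of grid points before deduplication.
#' @return Increasing integer vector of window sizes.
#' @export
dfa_window_grid <- function(cycle_len, signal_len, n_windows = 30L) {
  stopifnot(cycle_len > 0, signal_len > 0)
  lo <- 0.1 * cycle_len
  hi <- 2 * cycle_len
  if (hi > signal_len / 2) abort("Two full cycles exceed half the signal length.")
  g <- exp(seq(log(lo), log(hi), length.out = n_windows))
  g <- sort(unique(pmax(4L, as.integer(round(g)))))
  if (length(g) < 8) abort("Fewer than 8 unique window sizes after rounding; grid too coarse.")
  g
}

#' Clean log-log pairs before the piecewise fit
#'
#' Drops pairs where `F(n)` is zero, non-finite or `n` is invalid; returns
#' natural-log coordinates.
#'
#' @param windows Integer window sizes.
#' @param f_n Fluctuation values, same length.
#' @return A list with `log_n`, `log_f`, and `kept` (logical index).
#' @export
clean_loglog <- function(windows, f_n) {
  stopifnot(length(windows) == length(f_n))
  keep <- is.finite(f_n) & f_n > 0 & is.finite(windows) & windows >= 4
  if (sum(keep) < 6) abort("Fewer than 6 usable log-log points; cannot fit two 3-point segments.")
  list(log_n = log(as.numeric(windows[keep])), log_f = log(f_n[keep]), kept = keep)
}

# Slope/intercept/RSS/R2 of an OLS line (closed form; used by dual_fit).
ols_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) abort("Degenerate abscissa (repeated log_n) in segment fit.")
  slope <- sum((x - mx) * (y - my)) / sxx
  fit <- my + slope * (x - mx)
  rss <- sum((y - fit)^2)
  tss <- sum((y - my)^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  list(slope = slope, intercept = my - slope * mx, rss = rss, r2 = r2)
}

#' Two-segment piecewise-linear fit with automatic breakpoint
#'
#' Fits ordinary least-squares lines to `[1..i]` and `[i+1..end]` for every
#' admissible split (at least 3 points per segment) and keeps the split with
#' the lowest total residual sum of squares; exact ties break toward the
#' smallest split index. Slopes are the short-scale (`alpha1`) and long-scale
#' (`alpha2`) DFA exponents.
#'
#' @param log_n,log_f Natural-log coordinates (from [clean_loglog()]),
#'   `log_n` strictly increasing, at least 6 points.
#' @param signal_len Optional signal length in samples; when given,
#'   `bp_ratio = bp_scale / signal_len` is reported.
#' @return A list of class `vag_dual_fit`: `alpha1`, `alpha2`, `r2_1`,
#'   `r2_2`, `bp_index`, `bp_scale` (samples), `bp_ratio`, `rss_total`,
#'   `alpha_overall` (single-line slope) and the input points.
#' @export
dual_fit <- function(log_n, log_f, signal_len = NULL) {
  p <- length(log_n)
  stopifnot(p == length(log_f), p >= 6)
  if (any(diff(log_n) <= 0)) abort("`log_n` must be strictly increasing.")
  best <- NULL
  for (i in 3:(p - 3)) {
    f1 <- ols_line(log_n[1:i], log_f[1:i])
    f2 <- ols_line(log_n[(i + 1):p], log_f[(i + 1):p])
    tot <- f1$rss + f2$rss
    if (is.null(best) || tot < best$rss_total) {
      best <- list(i = i, f1 = f1, f2 = f2, rss_total = tot)
    }
  }
  overall <- ols_line(log_n, log_f)
  bp_scale <- exp(log_n[best$i])
  structure(
    list(alpha1 = best$f1$slope, alpha2 = best$f2$slope,
         r2_1 = best$f1$r2, r2_2 = best$f2$r2,
         bp_index = best$i, bp_scale = bp_scale,
         bp_ratio = if (!is.null(signal_len)) bp_scale / signal_len else NA_real_,
         rss_total = best$rss_total,
         alpha_overall = overall$slope, r2_overall = overall$r2,
         intercept1 = best$f1$intercept, intercept2 = best$f2$intercept,
         log_n = log_n, log_f = log_f),
    class = "vag_dual_fit"
  )
}

#' @export
print.vag_dual_fit <- function(x, ...) {
  cat(sprintf("<vag_dual_fit> alpha1 = %.3f (R2 %.3f), alpha2 = %.3f (R2 %.3f), breakpoint %.0f samples%s\n",
              x$alpha1, x$r2_1, x$alpha2, x$r2_2, x$bp_scale,
              if (is.finite(x$bp_ratio)) sprintf(" (%.3f of signal)", x$bp_ratio) else ""))
  invisible(x)
}

#' Dual-scaling DFA of one series
#'
#' Computes the profile, evaluates the fluctuation function on a window grid
#' (the cycle-relative grid when `cycle_len` is given, otherwise a
#' logarithmic default spanning `[4, length(x)/4]`), cleans the log-log
#' points and runs the two-segment fit.
#'
#' @param x Numeric series.
#' @param cycle_len Mean movement-cycle length in samples (optional).
#' @param windows Explicit window sizes (overrides `cycle_len`).
#' @param n_windows Number of grid points.
#' @return A `vag_dual_fit` (see [dual_fit()]).
#' @export
dfa_dual <- function(x, cycle_len = NULL, windows = NULL, n_windows = 30L) {
  N <- length(x)
  if (is.null(windows)) {
    windows <- if (!is.null(cycle_len)) {
      dfa_window_grid(cycle_len, N, n_windows)
    } else {
      sort(unique(pmax(4L, as.integer(round(exp(seq(log(4), log(N / 4), length.out = n_windows)))))))
    }
  }
  y <- dfa_profile(x)
  f_n <- vapply(windows, function(n) dfa_fluctuation(y, n), numeric(1))
  ll <- clean_loglog(windows, f_n)
  dual_fit(ll$log_n, ll$log_f, signal_len = N)
}

#' Dual-scaling DFA per IMF
#'
#' Applies [dfa_dual()] to every IMF of a decomposition with a shared,
#' cycle-relative window grid. Per-IMF grid or cleaning failures are
#' propagated as missing fits rather than errors.
#'
#' @param decomp A `vag_imf_decomposition` (see [emd()] / [eemd()]).
#' @param cycle_len Mean cycle length in samples.
#' @param n_windows Number of grid points.
#' @return A tibble with one row per IMF: `imf_index`, `alpha1`, `alpha2`,
#'   `r2_1`, `r2_2`, `bp_scale`, `bp_ratio`, `rss_total`, and a list-column
#'   `fit` with the full `vag_dual_fit` (or `NULL` when the fit failed).
#' @export
dfa_dual_imfs <- function(decomp, cycle_len, n_windows = 30L) {
  stopifnot(inherits(decomp, "vag_imf_decomposition"))
  N <- length(decomp$imfs[[1]])
  windows <- dfa_window_grid(cycle_len, N, n_windows)
  rows <- purrr::map(seq_along(decomp$imfs), function(i) {
    fit <- tryCatch(dfa_dual(decomp$imfs[[i]], windows = windows), error = function(e) NULL)
    if (is.null(fit)) {
      tibble::tibble(imf_index = i, alpha1 = NA_real_, alpha2 = NA_real_,
                     r2_1 = NA_real_, r2_2 = NA_real_, bp_scale = NA_real_,
                     bp_ratio = NA_real_, rss_total = NA_real_, fit = list(NULL))
    } else {
      tibble::tibble(imf_index = i, alpha1 = fit$alpha1, alpha2 = fit$alpha2,
                     r2_1 = fit$r2_1, r2_2 = fit$r2_2, bp_scale = fit$bp_scale,
                     bp_ratio = fit$bp_ratio, rss_total = fit$rss_total,
                     fit = list(fit))
    }
  })
  dplyr::bind_rows(rows)
}

#' @export
tidy.vag_dual_fit <- function(x, ...) {
  tibble::tibble(
    segment = c("short", "long"),
    alpha = c(x$alpha1, x$alpha2),
    r_squared = c(x$r2_1, x$r2_2),
    intercept = c(x$intercept1, x$intercept2)
  )
}

#' @export
glance.vag_dual_fit <- function(x, ...) {
  tibble::tibble(alpha1 = x$alpha1, alpha2 = x$alpha2, r2_1 = x$r2_1,
                 r2_2 = x$r2_2, bp_index = x$bp_index, bp_scale = x$bp_scale,
                 bp_ratio = x$bp_ratio, rss_total = x$rss_total,
                 alpha_overall = x$alpha_overall)
}

#' Plot a dual-scaling DFA fit
#'
#' Log-log fluctuation points with the two fitted segments and the detected
#' breakpoint.
#'
#' @param object A `vag_dual_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vag_dual_fit <- function(object, ...) {
  pts <- tibble::tibble(log_n = object$log_n, log_f = object$log_f)
  i <- object$bp_index
  seg <- dplyr::bind_rows(
    tibble::tibble(segment = "short", log_n = object$log_n[1:i],
                   fit = object$intercept1 + object$alpha1 * object$log_n[1:i]),
    tibble::tibble(segment = "long", log_n = object$log_n[(i + 1):length(object$log_n)],
                   fit = object$intercept2 + object$alpha2 * object$log_n[(i + 1):length(object$log_n)])
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$log_n, y = .data$log_f)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_line(data = seg,
                       ggplot2::aes(y = .data$fit, colour = .data$segment),
                       linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = log(object$bp_scale), linetype = "dashed") +
    ggplot2::labs(x = "log window size (samples)", y = "log F(n)",
                  colour = "scaling range",
                  title = sprintf("alpha1 = %.2f, alpha2 = %.2f, breakpoint = %.0f samples",
                                  object$alpha1, object$alpha2, object$bp_scale)) +
    ggplot2::theme_minimal()
}
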