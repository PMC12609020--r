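# Statistical screening of the 12 aggregated features: Lilliefors normality
# check per group (reported, not gating) and the Mann-Whitney U gate at
# p < 0.05.

# Null distributions are deterministic given (n, mc_reps, seed), so they are
# cached per session.
.lilliefors_cache <- new.env(parent = emptyenv())

# Lilliefors/KS distance of a sample to the normal with estimated moments.
lilliefors_distance <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  i <- seq_len(n)
  max(pmax(i / n - p, p - (i - 1) / n))
}

#' Lilliefors test for normality with a Monte-Carlo null
#'
#' Kolmogorov-Smirnov distance to the normal distribution with estimated
#' mean and standard deviation; the p-value comes from a seeded Monte-Carlo
#' null of `mc_reps` standard-normal samples of the same size (add-one
#' correction), so it is exact in `n` and reproducible.
#'
#' @param sample Numeric sample, `n >= 4`.
#' @param mc_reps Monte-Carlo replicates for the null distribution.
#' @param seed Integer seed.
#' @return A list with `statistic` (the KS distance), `p_value`, `n`.
#' @export
lilliefors_test <- function(sample, mc_reps = 2000L, seed = 1L) {
  n <- length(sample)
  if (n < 4) abort("Lilliefors test needs n >= 4.")
  if (stats::sd(sample) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, n = n,
                flag = "zero variance"))
  }
  d_obs <- lilliefors_distance(sample)
  key <- paste(n, mc_reps, seed, sep = "|")
  d_null <- .lilliefors_cache[[key]]
  if (is.null(d_null)) {
    d_null <- with_seed(seed, {
      m <- matrix(rnorm(n * mc_reps), nrow = n)
      apply(m, 2, lilliefors_distance)
    })
    .lilliefors_cache[[key]] <- d_null
  }
  p <- (1 + sum(d_null >= d_obs)) / (mc_reps + 1)
  list(statistic = d_obs, p_value = p, n = n, flag = NULL)
}

#' Mann-Whitney U test
#'
#' U from rank sums with midrank ties. Two-sided p-value by exact
#' enumeration of all group assignments when `n_a + n_b <= exact_max`,
#' otherwise by normal approximation with tie-corrected variance and
#' continuity correction.
#'
#' @param a,b Numeric samples (each `n >= 3`).
#' @param exact_max Total size at or below which the exact enumeration runs.
#' @return A list with `u` (for sample `a`), `p_value`, and `method`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 12L) {
  n_a <- length(a); n_b <- length(b)
  stopifnot(n_a >= 3, n_b >= 3)
  comb <- c(a, b)
  r <- rank(comb)  # midranks
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  n <- n_a + n_b
  if (length(unique(comb)) == 1) {
    return(list(u = u_a, p_value = 1, method = "degenerate"))
  }
  if (n <= exact_max) {
    idx <- utils::combn(n, n_a)
    u_all <- apply(idx, 2, function(ii) sum(r[ii]) - n_a * (n_a + 1) / 2)
    p <- min(1, 2 * min(mean(u_all <= u_a), mean(u_all >= u_a)))
    return(list(u = u_a, p_value = p, method = "exact"))
  }
  mu <- n_a * n_b / 2
  ties <- table(comb)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n_a * n_b / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(list(u = u_a, p_value = 1, method = "degenerate"))
  z <- (abs(u_a - mu) - 0.5) / sqrt(v)
  p <- min(1, 2 * stats::pnorm(-z))
  list(u = u_a, p_value = p, method = "normal")
}

#' Screen features by between-group Mann-Whitney tests
#'
#' For each feature column: Lilliefors normality p per group (reported only)
#' and the Mann-Whitney U test between groups; a feature is kept iff its
#' Mann-Whitney p-value is below `alpha`.
#'
#' @param features Feature table (tibble) with a `group` column (`HC`/`OA`)
#'   and numeric feature columns.
#' @param feature_cols Character vector of feature columns; defaults to all
#'   numeric columns except metadata.
#' @param alpha Significance gate (0.05).
#' @param mc_reps,seed Lilliefors Monte-Carlo controls.
#' @return A tibble of class `vag_screening`: one row per feature with
#'   `lilliefors_p_hc`, `lilliefors_p_oa`, `mw_u`, `mw_p`, `kept`.
#' @export
screen_features <- function(features, feature_cols = NULL, alpha = 0.05,
                            mc_reps = 2000L, seed = 1L) {
  stopifnot("group" %in% names(features))
  if (is.null(feature_cols)) {
    meta <- c("subject_id", "group", "chain", "channel", "fs_hz", "path")
    feature_cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))], meta)
  }
  g <- features$group
  out <- purrr::map_dfr(feature_cols, function(fc) {
    v <- features[[fc]]
    ok <- is.finite(v)
    a <- v[ok & g == "HC"]; b <- v[ok & g == "OA"]
    lil <- function(x, tag) {
      if (length(x) < 4 || stats::sd(x) == 0) return(list(p_value = NA_real_))
      lilliefors_test(x, mc_reps, derive_seed(seed, paste0(tag, fc)))
    }
    lil_a <- lil(a, "lil-hc-")
    lil_b <- lil(b, "lil-oa-")
    mw <- if (length(a) >= 3 && length(b) >= 3) {
      mann_whitney_u(a, b)
    } else {
      list(u = NA_real_, p_value = NA_real_)  # group too small to test
    }
    tibble::tibble(feature = fc,
                   lilliefors_p_hc = lil_a$p_value,
                   lilliefors_p_oa = lil_b$p_value,
                   mw_u = mw$u, mw_p = mw$p_value,
                   kept = !is.na(mw$p_value) & mw$p_value < alpha)
  })
  class(out) <- c("vag_screening", class(out))
  out
}
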