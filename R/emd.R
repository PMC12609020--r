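# Empirical mode decomposition by envelope-mean sifting, and its ensemble
# variant (EEMD): noise-perturbed decompositions averaged element-wise.

# Indices of local maxima and minima; plateaus carry the previous slope sign.
find_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  nz <- s != 0
  if (!any(nz)) return(list(maxima = integer(0), minima = integer(0)))
  # carry last non-zero sign over plateaus
  s_f <- s
  last <- 0
  for (i in seq_along(s_f)) {
    if (s_f[i] == 0) s_f[i] <- last else last <- s_f[i]
  }
  ch <- diff(s_f)
  maxima <- which(ch < 0) + 1L
  minima <- which(ch > 0) + 1L
  list(maxima = maxima, minima = minima)
}

# Cubic envelope through extrema with mirror extension at the boundaries.
envelope_spline <- function(t_ext, v_ext, n) {
  ord <- order(t_ext)
  t_ext <- t_ext[ord]; v_ext <- v_ext[ord]
  keep <- !duplicated(t_ext)
  stats::splinefun(t_ext[keep], v_ext[keep], method = "fmm")(seq_len(n))
}

mirror_extend <- function(t, v, n, n_mirror = 2L) {
  k <- min(n_mirror, length(t))
  left_t <- 2 - t[seq_len(k)]          # reflect about sample 1
  left_v <- v[seq_len(k)]
  right_t <- 2 * n - t[length(t) - seq_len(k) + 1]  # reflect about sample n
  right_v <- v[length(v) - seq_len(k) + 1]
  list(t = c(left_t, t, right_t), v = c(left_v, v, right_v))
}

#' Extract one intrinsic mode function by sifting
#'
#' Iterated envelope-mean subtraction: cubic splines through the maxima and
#' minima (mirror-extended at the boundaries) define the local mean, which is
#' subtracted until the standard-deviation criterion
#' `SD = sum((h_prev - h)^2) / sum(h_prev^2) < sd_stop` or the iteration cap
#' is reached.
#'
#' @param x Numeric signal with at least 2 maxima and 2 minima; otherwise it
#'   is returned unchanged as a monotone remainder.
#' @param sd_stop Sifting stop threshold (Huang's criterion, 0.2).
#' @param max_iter Iteration cap.
#' @return A list with `imf` (or `NULL` when `x` has too few extrema),
#'   `remainder`, and `monotone` (logical).
#' @export
sift_imf <- function(x, sd_stop = 0.2, max_iter = 50L) {
  n <- length(x)
  h <- x
  for (it in seq_len(max_iter)) {
    ex <- find_extrema(h)
    if (length(ex$maxima) < 2 || length(ex$minima) < 2) {
      if (it == 1) return(list(imf = NULL, remainder = x, monotone = TRUE))
      break
    }
    up_ext <- mirror_extend(ex$maxima, h[ex$maxima], n)
    lo_ext <- mirror_extend(ex$minima, h[ex$minima], n)
    upper <- envelope_spline(up_ext$t, up_ext$v, n)
    lower <- envelope_spline(lo_ext$t, lo_ext$v, n)
    m <- (upper + lower) / 2
    h_new <- h - m
    sd_crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.xmin)
    h <- h_new
    if (sd_crit < sd_stop) break
  }
  list(imf = h, remainder = x - h, monotone = FALSE)
}

new_imf_decomposition <- function(imfs, residue, params) {
  structure(list(imfs = imfs, residue = residue, params = params),
            class = "vag_imf_decomposition")
}

#' @export
print.vag_imf_decomposition <- function(x, ...) {
  cat(sprintf("<vag_imf_decomposition> %d IMF(s) of length %d (%s)\n",
              length(x$imfs), length(x$residue),
              if (isTRUE(x$params$ensemble > 1)) sprintf("EEMD, ensemble %d, noise %.3g",
                                                         x$params$ensemble, x$params$noise_ratio)
              else "EMD"))
  invisible(x)
}

#' Empirical mode decomposition
#'
#' Repeated sifting on successive remainders until `max_imf` IMFs are
#' extracted or the remainder is monotone. The decomposition is complete:
#' `sum(imfs) + residue` reproduces the input to numerical precision.
#'
#' @param x Numeric signal (length >= 64).
#' @param max_imf Maximum number of IMFs (10 in the analysis pipeline).
#' @param sd_stop,max_iter Sifting controls, see [sift_imf()].
#' @return A `vag_imf_decomposition`: `imfs` (list), `residue`, `params`.
#' @export
emd <- function(x, max_imf = 10L, sd_stop = 0.2, max_iter = 50L) {
  stopifnot(length(x) >= 64)
  imfs <- list()
  rem <- x
  for (k in seq_len(max_imf)) {
    s <- sift_imf(rem, sd_stop = sd_stop, max_iter = max_iter)
    if (s$monotone || is.null(s$imf)) break
    imfs[[k]] <- s$imf
    rem <- s$remainder
  }
  new_imf_decomposition(imfs, rem,
                        list(noise_ratio = 0, ensemble = 1L,
                             max_imf = as.integer(max_imf), seed = NA_integer_))
}

#' Ensemble empirical mode decomposition
#'
#' Decomposes `ensemble` noise-perturbed copies
#' `x + noise_ratio * sd(x) * w_e` (`w_e` standard Gaussian, seeded) with
#' [emd()], zero-pads each realization's IMF list to `max_imf`, and averages
#' element-wise. The defaults are the pipeline settings: noise ratio 0.01
#' and 100 realizations.
#'
#' @param x Numeric, non-constant signal.
#' @param noise_ratio Added-noise standard deviation relative to `sd(x)`.
#' @param ensemble Number of noise realizations (>= 1).
#' @param max_imf Number of components realizations are aligned to.
#' @param seed Integer seed for the noise stream.
#' @param sd_stop,max_iter Sifting controls.
#' @return A `vag_imf_decomposition` with trailing all-zero mean IMFs
#'   removed.
#' @export
eemd <- function(x, noise_ratio = 0.01, ensemble = 100L, max_imf = 10L,
                 seed = 1L, sd_stop = 0.2, max_iter = 50L) {
  if (ensemble < 1) abort("`ensemble` must be >= 1.")
  if (stats::sd(x) == 0) abort("`x` must be non-constant.")
  n <- length(x)
  sd_x <- stats::sd(x)
  acc <- matrix(0, nrow = max_imf, ncol = n)
  acc_res <- numeric(n)
  for (e in seq_len(ensemble)) {
    noise <- if (noise_ratio > 0) {
      with_seed(derive_seed(seed, paste0("eemd", e)), rnorm(n))
    } else numeric(n)
    d <- emd(x + noise_ratio * sd_x * noise, max_imf = max_imf,
             sd_stop = sd_stop, max_iter = max_iter)
    for (k in seq_along(d$imfs)) acc[k, ] <- acc[k, ] + d$imfs[[k]]
    acc_res <- acc_res + d$residue
  }
  acc <- acc / ensemble
  acc_res <- acc_res / ensemble
  nonzero <- which(apply(acc != 0, 1, any))
  n_keep <- if (length(nonzero)) max(nonzero) else 0L
  imfs <- if (n_keep > 0) lapply(seq_len(n_keep), function(k) acc[k, ]) else list()
  new_imf_decomposition(imfs, acc_res,
                        list(noise_ratio = noise_ratio,
                             ensemble = as.integer(ensemble),
                             max_imf = as.integer(max_imf),
                             seed = as.integer(seed)))
}

#' Write an IMF decomposition as a delimited-text matrix
#'
#' Rows are IMFs, the final row is the residue; a JSON sidecar stores the
#' decomposition parameters.
#'
#' @param decomp A `vag_imf_decomposition`.
#' @param path Output path for the matrix (tab-separated).
#' @return `path`, invisibly.
#' @export
write_imf_matrix <- function(decomp, path) {
  stopifnot(inherits(decomp, "vag_imf_decomposition"))
  m <- do.call(rbind, c(decomp$imfs, list(decomp$residue)))
  utils::write.table(format(m, digits = 10), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(decomp$params, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
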