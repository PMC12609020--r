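# Criterion-gated reconstruction: sum only the IMFs whose dual-scaling DFA
# fit shows persistence (alpha > 0.5) with a reliable fit (R^2 > 0.9), on
# the short (alpha1) or long (alpha2) scaling range.

#' Select IMFs passing the persistence and fit-quality criteria
#'
#' Local scale: `alpha1 > alpha_min` and `r2_1 > r2_min`; global scale: the
#' same with `alpha2`, `r2_2`. Both inequalities are strict; missing fits
#' are excluded.
#'
#' @param fits Tibble from [dfa_dual_imfs()].
#' @param scale `"local"` (alpha1) or `"global"` (alpha2).
#' @param alpha_min Persistence threshold (0.5).
#' @param r2_min Fit-quality threshold (0.9).
#' @return Integer vector of selected IMF indices.
#' @export
select_components <- function(fits, scale = c("local", "global"),
                              alpha_min = 0.5, r2_min = 0.9) {
  scale <- match.arg(scale)
  a <- if (scale == "local") fits$alpha1 else fits$alpha2
  r2 <- if (scale == "local") fits$r2_1 else fits$r2_2
  ok <- !is.na(a) & !is.na(r2) & a > alpha_min & r2 > r2_min
  as.integer(fits$imf_index[ok])
}

#' Sum selected IMFs into a reconstructed signal
#'
#' @param decomp A `vag_imf_decomposition`.
#' @param idx Integer set of IMF indices; the empty set yields a zero signal
#'   with attribute `empty_flag = TRUE`.
#' @return Numeric vector, same length as the input signal.
#' @export
reconstruct_signal <- function(decomp, idx) {
  stopifnot(inherits(decomp, "vag_imf_decomposition"))
  n <- length(decomp$residue)
  if (length(idx) == 0) {
    out <- numeric(n)
    attr(out, "empty_flag") <- TRUE
    return(out)
  }
  if (any(idx < 1 | idx > length(decomp$imfs))) abort("IMF index out of range.")
  out <- Reduce(`+`, decomp$imfs[idx])
  attr(out, "empty_flag") <- FALSE
  out
}

#' Short- and long-scale reconstructions of one decomposition
#'
#' @param decomp A `vag_imf_decomposition`.
#' @param fits Tibble from [dfa_dual_imfs()].
#' @param alpha_min,r2_min Selection thresholds, see [select_components()].
#' @return A list of class `vag_reconstruction`: `x_alpha1`, `x_alpha2`,
#'   `included_local`, `included_global`, `empty_flags`.
#' @export
reconstruct_pair <- function(decomp, fits, alpha_min = 0.5, r2_min = 0.9) {
  loc <- select_components(fits, "local", alpha_min, r2_min)
  glo <- select_components(fits, "global", alpha_min, r2_min)
  x1 <- reconstruct_signal(decomp, loc)
  x2 <- reconstruct_signal(decomp, glo)
  structure(
    list(x_alpha1 = as.numeric(x1), x_alpha2 = as.numeric(x2),
         included_local = loc, included_global = glo,
         empty_flags = c(local = isTRUE(attr(x1, "empty_flag")),
                         global = isTRUE(attr(x2, "empty_flag")))),
    class = "vag_reconstruction"
  )
}

#' @export
print.vag_reconstruction <- function(x, ...) {
  cat(sprintf("<vag_reconstruction> local IMFs {%s}%s, global IMFs {%s}%s\n",
              paste(x$included_local, collapse = ","),
              if (x$empty_flags["local"]) " [empty]" else "",
              paste(x$included_global, collapse = ","),
              if (x$empty_flags["global"]) " [empty]" else ""))
  invisible(x)
}
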