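# Continuous-wavelet-transform scalograms: analytic Morlet CWT magnitude,
# per-image min-max normalisation, jet colormap, fixed-size RGB images.

#' Element-wise sum of the three sensor channels
#'
#' @param k1,k2,k3 Numeric signals; unequal lengths are truncated to the
#'   shortest with a warning.
#' @return Numeric vector.
#' @export
combine_channels <- function(k1, k2, k3) {
  n <- min(length(k1), length(k2), length(k3))
  if (any(c(length(k1), length(k2), length(k3)) != n)) {
    warn("Channel lengths differ; truncating to the shortest.")
  }
  k1[seq_len(n)] + k2[seq_len(n)] + k3[seq_len(n)]
}

#' Shared CWT scale grid
#'
#' 64 logarithmically spaced scales for an analytic Morlet wavelet (centre
#' frequency parameter `omega0 = 6`), spanning pseudo-frequencies from
#' `f_min` to `fs/2.5`. The same grid object is reused for every signal in
#' a run; its hash is recorded into each image's metadata.
#'
#' @param fs_hz Sampling rate (Hz).
#' @param n_scales Number of scales.
#' @param f_min,f_max Pseudo-frequency span (Hz).
#' @param omega0 Morlet centre-frequency parameter.
#' @return A list of class `vag_scale_grid` with `scales` (seconds),
#'   `freqs` (Hz), `omega0`, `fs_hz`, `wavelet_id`, `hash`.
#' @export
scale_grid <- function(fs_hz, n_scales = 64L, f_min = 5, f_max = fs_hz / 2.5,
                       omega0 = 6) {
  stopifnot(fs_hz > 0, f_min > 0, f_max > f_min, f_max <= fs_hz / 2)
  freqs <- exp(seq(log(f_max), log(f_min), length.out = n_scales))
  scales <- omega0 / (2 * pi * freqs)
  hash <- derive_seed(0, paste(c("grid", format(scales, digits = 10)), collapse = "|"))
  structure(list(scales = scales, freqs = freqs, omega0 = omega0,
                 fs_hz = fs_hz, wavelet_id = sprintf("morlet-%g", omega0),
                 hash = hash),
            class = "vag_scale_grid")
}

#' CWT magnitude matrix
#'
#' Analytic Morlet continuous wavelet transform computed in the frequency
#' domain; rows are scales (ordered by the grid, high to low frequency),
#' columns are time samples.
#'
#' @param x Numeric signal (length >= 256).
#' @param grid A [scale_grid()].
#' @return Numeric matrix `length(grid$scales) x length(x)` of `|CWT|`.
#' @export
cwt_magnitude <- function(x, grid) {
  stopifnot(inherits(grid, "vag_scale_grid"), length(x) >= 256)
  n <- length(x)
  X <- stats::fft(x)
  # angular frequencies of the DFT bins (positive half only; analytic wavelet)
  omega <- 2 * pi * grid$fs_hz * c(0:(n %/% 2), -(((n + 1) %/% 2 - 1):1)) / n
  pos <- omega > 0
  out <- matrix(0, nrow = length(grid$scales), ncol = n)
  for (si in seq_along(grid$scales)) {
    s <- grid$scales[si]
    psi_hat <- numeric(n)
    psi_hat[pos] <- pi^(-0.25) * exp(-0.5 * (s * omega[pos] - grid$omega0)^2)
    w <- stats::fft(X * sqrt(s) * psi_hat, inverse = TRUE) / n
    out[si, ] <- Mod(w)
  }
  out
}

#' Classic jet colormap lookup table
#'
#' The 256-entry blue-cyan-yellow-red table used for every scalogram image,
#' generated from the classic piecewise-linear breakpoints so images are
#' bit-exact across platforms.
#'
#' @param n Number of entries.
#' @return An `n x 3` matrix of RGB values in `[0, 1]`.
#' @export
jet_colors <- function(n = 256L) {
  v <- (seq_len(n) - 1) / (n - 1)
  clamp <- function(z) pmin(1, pmax(0, z))
  cbind(r = clamp(1.5 - abs(4 * v - 3)),
        g = clamp(1.5 - abs(4 * v - 2)),
        b = clamp(1.5 - abs(4 * v - 1)))
}

# Bilinear resize of a matrix to nr x nc (centre-aligned sampling).
bilinear_resize <- function(m, nr, nc) {
  h <- nrow(m); w <- ncol(m)
  ry <- (seq_len(nr) - 0.5) * h / nr + 0.5
  rx <- (seq_len(nc) - 0.5) * w / nc + 0.5
  y0 <- pmin(pmax(floor(ry), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(rx), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(ry - y0, 0), 1); fx <- pmin(pmax(rx - x0, 0), 1)
  top <- m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    m[y0, x1, drop = FALSE] * outer(1 - fy, fx)
  bot <- m[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
    m[y1, x1, drop = FALSE] * outer(fy, fx)
  top + bot
}

#' Convert a CWT magnitude matrix to a fixed-size jet RGB image
#'
#' Min-max normalises the full matrix to `[0, 1]` (a constant matrix maps to
#' 0.5 with a degenerate flag), maps through the pinned 256-entry jet table,
#' and bilinearly resizes to `resolution x resolution`.
#'
#' @param m Numeric matrix (finite entries).
#' @param resolution Output size, 128 or 256.
#' @param source_id Identifier carried in the result.
#' @param grid_hash Optional [scale_grid()] hash recorded for provenance.
#' @return A list of class `vag_scalogram_image`: `pixels`
#'   (`resolution x resolution x 3` integer array, 0-255), `source_id`,
#'   `resolution`, `degenerate`, `grid_hash`.
#' @export
to_rgb_image <- function(m, resolution = 128L, source_id = "", grid_hash = NA_integer_) {
  if (!all(is.finite(m))) abort("Non-finite entries in scalogram matrix.")
  if (!resolution %in% c(128L, 256L)) abort("`resolution` must be 128 or 256.")
  rng <- range(m)
  degenerate <- rng[1] == rng[2]
  norm <- if (degenerate) matrix(0.5, nrow(m), ncol(m)) else (m - rng[1]) / (rng[2] - rng[1])
  small <- bilinear_resize(norm, resolution, resolution)
  small <- pmin(pmax(small, 0), 1)
  lut <- jet_colors(256L)
  idx <- pmin(255L, as.integer(floor(small * 256))) + 1L
  px <- array(0L, dim = c(resolution, resolution, 3))
  for (ch in 1:3) px[, , ch] <- as.integer(round(255 * lut[idx, ch]))
  structure(list(pixels = px, source_id = source_id,
                 resolution = as.integer(resolution),
                 degenerate = degenerate, grid_hash = grid_hash),
            class = "vag_scalogram_image")
}

#' Scalogram image straight from a signal
#'
#' Convenience wrapper: [cwt_magnitude()] then [to_rgb_image()].
#'
#' @param x Numeric signal.
#' @param grid A [scale_grid()].
#' @param resolution Output size, 128 or 256.
#' @param source_id Identifier carried in the result.
#' @return A `vag_scalogram_image`.
#' @export
signal_scalogram <- function(x, grid, resolution = 128L, source_id = "") {
  m <- cwt_magnitude(x, grid)
  to_rgb_image(m, resolution, source_id = source_id, grid_hash = grid$hash)
}

#' Write a scalogram image as PNG
#'
#' @param img A `vag_scalogram_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scalogram_png <- function(img, path) {
  stopifnot(inherits(img, "vag_scalogram_image"))
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}

#' @export
print.vag_scalogram_image <- function(x, ...) {
  cat(sprintf("<vag_scalogram_image> %dx%dx3 '%s'%s\n", x$resolution,
              x$resolution, x$source_id,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Plot a scalogram image
#'
#' @param object A `vag_scalogram_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vag_scalogram_image <- function(object, ...) {
  px <- object$pixels
  df <- tidyr::expand_grid(row = seq_len(dim(px)[1]), col = seq_len(dim(px)[2]))
  df$colour <- grDevices::rgb(px[cbind(df$row, df$col, 1)],
                              px[cbind(df$row, df$col, 2)],
                              px[cbind(df$row, df$col, 3)], maxColorValue = 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$colour)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "time", y = "scale", title = object$source_id) +
    ggplot2::theme_void()
}
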