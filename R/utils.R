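# Shared signal-processing primitives used across modules.

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the complex analytic signal `x + i*H(x)` obtained by zeroing the
#' negative-frequency half of the spectrum and doubling the positive half.
#'
#' @param x Numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2)
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with a Hann window and 50% segment overlap.
#' Used as the spectral estimator behind [centroid_frequency()].
#'
#' @param x Numeric vector.
#' @param fs_hz Sampling rate in Hz.
#' @param nperseg Segment length; defaults to `min(1024, length(x))`.
#' @return A tibble with columns `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs_hz, nperseg = min(1024L, length(x))) {
  stopifnot(is.numeric(x), length(x) >= 8, fs_hz > 0)
  n <- length(x)
  nperseg <- min(as.integer(nperseg), n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nperseg) - 1) / nperseg)  # periodic Hann
  u <- sum(w^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- stats::fft(seg)[seq_len(nfreq)]
    p <- (Mod(sp)^2) / (fs_hz * u)
    # one-sided: double all bins except DC (and Nyquist when nperseg even)
    scale2 <- rep(2, nfreq)
    scale2[1] <- 1
    if (nperseg %% 2 == 0) scale2[nfreq] <- 1
    acc <- acc + p * scale2
  }
  psd <- acc / length(starts)
  tibble::tibble(freq = (seq_len(nfreq) - 1) * fs_hz / nperseg, psd = psd)
}

# Deterministic 32-bit seed derived from a base seed and a string tag, so
# per-subject / per-stage streams are independent and extensible.
derive_seed <- function(seed, tag) {
  codes <- utf8ToInt(paste0(tag, ":", seed))
  h <- 5381
  for (cc in codes) h <- (h * 33 + cc) %% 2147483647
  as.integer(h)
}

# Evaluate with a local RNG state (restores .Random.seed afterwards).
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Moving average with a centred window (used by the cycle detector).
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  k <- rep(1 / width, width)
  as.numeric(stats::filter(x, k, sides = 2)) |>
    (\(y) {
      # fill edge NAs by nearest valid value
      idx <- which(!is.na(y))
      if (length(idx) == 0) return(rep(mean(x), length(x)))
      y[seq_len(idx[1] - 1)] <- y[idx[1]]
      y[seq((tail(idx, 1) + 1), length.out = length(y) - tail(idx, 1))] <- y[tail(idx, 1)]
      y
    })()
}
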