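# Per-IMF frequency/energy features, band grouping by IMF index, and
# aggregation into the 12-dimensional feature vector
# (3 bands x {CF, MIF, E, breakpoint ratio}).

#' Band membership of an IMF index
#'
#' Band grouping is a function of IMF index only: 1-3 high, 4-6 mid,
#' 7-10 low.
#'
#' @param imf_index Integer vector of IMF indices (1-10).
#' @return Character vector: `"high"`, `"mid"` or `"low"`.
#' @export
imf_band <- function(imf_index) {
  stopifnot(all(imf_index >= 1), all(imf_index <= 10))
  dplyr::case_when(imf_index <= 3 ~ "high",
                   imf_index <= 6 ~ "mid",
                   TRUE ~ "low")
}

#' Spectral centroid frequency
#'
#' PSD-weighted mean frequency `sum(f * P(f)) / sum(P(f))` with `P` the
#' Welch estimate (Hann window, segment length `min(1024, n)`, 50% overlap).
#'
#' @param x Numeric signal (length >= 64).
#' @param fs_hz Sampling rate (Hz).
#' @return Centroid frequency in Hz, or `NaN` for an all-zero signal.
#' @export
centroid_frequency <- function(x, fs_hz) {
  stopifnot(length(x) >= 64)
  if (all(x == 0)) return(NaN)
  p <- welch_psd(x, fs_hz)
  tot <- sum(p$psd)
  if (tot <= 0) return(NaN)
  sum(p$freq * p$psd) / tot
}

#' Mean instantaneous frequency
#'
#' Mean of `fs/(2*pi) * d/dt arg(x_a)` where `x_a` is the analytic signal.
#' The outer 5% of samples at each edge are excluded (the analytic phase is
#' unreliable there) and negative instantaneous values are clipped to zero
#' before averaging.
#'
#' @param x Numeric signal (length >= 64).
#' @param fs_hz Sampling rate (Hz).
#' @param edge_frac Fraction excluded at each edge.
#' @return Mean instantaneous frequency in Hz, or `NaN` for an all-zero
#'   signal.
#' @export
mean_instantaneous_frequency <- function(x, fs_hz, edge_frac = 0.05) {
  stopifnot(length(x) >= 64)
  if (all(x == 0)) return(NaN)
  xa <- analytic_signal(x)
  ph <- unwrap_phase(Arg(xa))
  f_inst <- diff(ph) * fs_hz / (2 * pi)
  n <- length(f_inst)
  lo <- max(1L, ceiling(edge_frac * n))
  hi <- min(n, floor((1 - edge_frac) * n))
  mean(pmax(f_inst[lo:hi], 0))
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp_adj <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp_adj))
}

#' Signal energy
#'
#' Sum of squares, `sum(x^2)`.
#'
#' @param x Numeric vector with finite values.
#' @return Scalar energy (squared signal units).
#' @export
signal_energy <- function(x) {
  if (!all(is.finite(x))) abort("Non-finite values in input.")
  sum(x^2)
}

#' Per-IMF feature rows
#'
#' Centroid frequency, mean instantaneous frequency and energy for every IMF
#' of a decomposition, with band membership by index.
#'
#' @param decomp A `vag_imf_decomposition`.
#' @param fs_hz Sampling rate (Hz).
#' @return A tibble with columns `imf_index`, `cf_hz`, `mif_hz`, `energy`,
#'   `band`.
#' @export
imf_features <- function(decomp, fs_hz) {
  stopifnot(inherits(decomp, "vag_imf_decomposition"))
  purrr::map_dfr(seq_along(decomp$imfs), function(i) {
    im <- decomp$imfs[[i]]
    tibble::tibble(
      imf_index = i,
      cf_hz = centroid_frequency(im, fs_hz),
      mif_hz = mean_instantaneous_frequency(im, fs_hz),
      energy = signal_energy(im),
      band = imf_band(i)
    )
  })
}

# Canonical order of the 12 aggregated features.
FEATURE_NAMES <- as.vector(outer(c("cf", "mif", "energy", "bp_ratio"),
                                 c("high", "mid", "low"),
                                 function(p, b) paste(b, p, sep = "_")))

#' Aggregate per-IMF features into the 12-dimensional band vector
#'
#' Per band (high = IMF 1-3, mid = 4-6, low = 7-10), the arithmetic mean of
#' CF, MIF, energy and of the DFA breakpoint ratio over the band's IMFs, in
#' fixed (high, mid, low) x (CF, MIF, E, BR) order. A band whose members are
#' all missing yields `NaN` for that feature.
#'
#' @param feature_rows Tibble from [imf_features()].
#' @param dfa_fits Tibble from [dfa_dual_imfs()] (needs `imf_index`,
#'   `bp_ratio`).
#' @return A named numeric vector of length 12 (see `vagdfa:::FEATURE_NAMES`).
#' @export
aggregate_band_features <- function(feature_rows, dfa_fits) {
  joined <- dplyr::left_join(feature_rows,
                             dplyr::select(dfa_fits, "imf_index", "bp_ratio"),
                             by = "imf_index")
  band_means <- joined |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(dplyr::across(c("cf_hz", "mif_hz", "energy", "bp_ratio"),
                                   \(v) mean(v[is.finite(v)])),
                     .groups = "drop")
  out <- stats::setNames(rep(NaN, 12), FEATURE_NAMES)
  for (b in c("high", "mid", "low")) {
    row <- band_means[band_means$band == b, ]
    if (nrow(row) == 1) {
      out[paste0(b, "_cf")] <- row$cf_hz
      out[paste0(b, "_mif")] <- row$mif_hz
      out[paste0(b, "_energy")] <- row$energy
      out[paste0(b, "_bp_ratio")] <- row$bp_ratio
    }
  }
  out
}

#' Full feature vector for one preprocessed recording
#'
#' Runs EEMD, per-IMF features and per-IMF dual-scaling DFA, then aggregates
#' into the 12-feature band vector.
#'
#' @param pre A `vag_preprocessed` (see [preprocess_recording()]).
#' @param noise_ratio,ensemble,max_imf,seed EEMD settings (see [eemd()]).
#' @param n_windows DFA grid size.
#' @return One-row tibble: metadata columns + the 12 features.
#' @export
recording_features <- function(pre, noise_ratio = 0.01, ensemble = 100L,
                               max_imf = 10L, seed = 1L, n_windows = 30L) {
  stopifnot(inherits(pre, "vag_preprocessed"))
  decomp <- eemd(pre$samples, noise_ratio = noise_ratio, ensemble = ensemble,
                 max_imf = max_imf, seed = seed)
  feats <- imf_features(decomp, pre$meta$fs_hz)
  fits <- dfa_dual_imfs(decomp, pre$cycle_len, n_windows = n_windows)
  vec <- aggregate_band_features(feats, fits)
  dplyr::bind_cols(
    tibble::tibble(subject_id = pre$meta$subject_id, group = pre$meta$group,
                   chain = pre$meta$chain, channel = pre$meta$channel),
    tibble::as_tibble_row(as.list(vec))
  )
}

#' Feature table for a whole cohort
#'
#' @param cohort A `vag_cohort` (see [generate_cohort()]), or a list of
#'   `vag_recording`s.
#' @param seed Base seed; per-recording EEMD seeds are derived from it.
#' @param ... Passed to [recording_features()] (EEMD/DFA settings).
#' @param n_cycles,cutoff_hz Preprocessing settings.
#' @return A tibble, one row per recording: metadata + 12 features.
#' @export
cohort_features <- function(cohort, seed = 1L, n_cycles = 10L, cutoff_hz = 10, ...) {
  recs <- if (inherits(cohort, "vag_cohort")) cohort$recordings else cohort
  purrr::imap_dfr(recs, function(rec, nm) {
    pre <- preprocess_recording(rec, n_cycles = n_cycles, cutoff_hz = cutoff_hz)
    recording_features(pre, seed = derive_seed(seed, paste0("feat:", nm)), ...)
  })
}
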