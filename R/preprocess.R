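# Preprocessing: movement-cycle segmentation from the signal envelope,
# low-frequency noise removal, and unit-interval normalization.

#' Detect flexion-extension movement cycles
#'
#' Operationalises slope-change segmentation as envelope-minimum detection:
#' rectify, smooth with a 0.25 s moving-average envelope, find envelope peaks
#' separated by at least 0.5 s, and place cycle boundaries at the envelope
#' minima between consecutive peaks.
#'
#' @param x Numeric signal.
#' @param fs_hz Sampling rate (Hz).
#' @param n_cycles Number of cycles expected (10 in the acquisition protocol).
#' @return A tibble with columns `start`, `end` (sample indices, inclusive)
#'   and attribute `warning_flag` set to `TRUE` when fewer than `n_cycles`
#'   cycles were found.
#' @export
detect_cycles <- function(x, fs_hz, n_cycles = 10L) {
  stopifnot(length(x) >= fs_hz, n_cycles >= 1)
  env <- moving_average(abs(x - mean(x)), round(0.25 * fs_hz))
  min_sep <- round(0.5 * fs_hz)
  peaks <- find_peaks(env, min_sep)
  empty <- tibble::tibble(start = integer(0), end = integer(0))
  if (length(peaks) == 0) {
    attr(empty, "warning_flag") <- TRUE
    return(empty)
  }
  # Boundaries: envelope minima between consecutive peaks, plus the envelope
  # minima running out from the first/last peak to the signal edges.
  bounds <- integer(length(peaks) + 1)
  bounds[1] <- which.min(env[1:peaks[1]])
  if (length(peaks) > 1) {
    for (j in seq_len(length(peaks) - 1)) {
      seg <- peaks[j]:peaks[j + 1]
      bounds[j + 1] <- seg[which.min(env[seg])]
    }
  }
  bounds[length(bounds)] <- peaks[length(peaks)] - 1 +
    which.min(env[peaks[length(peaks)]:length(x)])
  # the moving-average edge fill flattens the envelope near the signal end;
  # a "minimum" inside that zone means the cycle really runs to the edge
  if (length(x) - bounds[length(bounds)] < round(0.25 * fs_hz)) {
    bounds[length(bounds)] <- length(x)
  }
  starts <- bounds[-length(bounds)]
  ends <- pmax(starts, bounds[-1] - 1L)
  keep <- (ends - starts) >= 1L
  out <- tibble::tibble(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
  if (nrow(out) > n_cycles) {
    # keep the n_cycles most energetic intervals, preserving order
    en <- purrr::map_dbl(seq_len(nrow(out)), \(i) sum(env[out$start[i]:out$end[i]]))
    out <- out[sort(order(en, decreasing = TRUE)[seq_len(n_cycles)]), ]
  }
  attr(out, "warning_flag") <- nrow(out) < n_cycles
  if (nrow(out) < n_cycles) {
    warn(sprintf("Found %d cycle(s); expected %d.", nrow(out), n_cycles))
  }
  out
}

# Local maxima with a minimum separation, largest-first greedy selection.
find_peaks <- function(env, min_sep) {
  n <- length(env)
  if (n < 3) return(integer(0))
  d <- diff(env)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(cand) == 0) return(integer(0))
  # drop flat/degenerate candidates on near-constant envelopes
  if (stats::sd(env) < 1e-12 * (abs(mean(env)) + 1e-300)) return(integer(0))
  prom <- env[cand] - stats::median(env)
  cand <- cand[prom > 0.05 * (max(env) - stats::median(env))]
  if (length(cand) == 0) return(integer(0))
  ord <- cand[order(env[cand], decreasing = TRUE)]
  sel <- integer(0)
  for (p in ord) {
    if (all(abs(p - sel) >= min_sep)) sel <- c(sel, p)
  }
  sort(sel)
}

#' Remove low-frequency noise with a Butterworth high-pass filter
#'
#' Fourth-order Butterworth high-pass, 10 Hz cutoff by default. The default is
#' a causal single pass; `zero_phase = TRUE` applies forward-backward
#' filtering (zero phase, squared magnitude response).
#'
#' @param x Numeric signal.
#' @param fs_hz Sampling rate (Hz).
#' @param order Filter order.
#' @param cutoff_hz High-pass cutoff (Hz); must be below Nyquist.
#' @param zero_phase Use `signal::filtfilt` instead of a single causal pass.
#' @return Filtered signal, same length as `x`.
#' @export
remove_low_frequency <- function(x, fs_hz, order = 4L, cutoff_hz = 10,
                                 zero_phase = FALSE) {
  if (cutoff_hz >= fs_hz / 2) abort("`cutoff_hz` must be below the Nyquist frequency.")
  bf <- signal::butter(order, cutoff_hz / (fs_hz / 2), type = "high")
  if (zero_phase) {
    as.numeric(signal::filtfilt(bf, x))
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Normalize a signal to the unit interval
#'
#' Maps `x` to `(x - min) / (max - min)`. A constant signal maps to 0.5
#' everywhere, with attribute `degenerate_flag = TRUE` so dead channels
#' survive batch runs.
#'
#' @param x Numeric vector, length >= 2, all finite.
#' @return Numeric vector in `[0, 1]` with attribute `degenerate_flag`.
#' @export
normalize_unit_interval <- function(x) {
  stopifnot(length(x) >= 2)
  if (!all(is.finite(x))) abort("Non-finite values in input.")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    out <- rep(0.5, length(x))
    attr(out, "degenerate_flag") <- TRUE
    return(out)
  }
  out <- (x - rng[1]) / (rng[2] - rng[1])
  attr(out, "degenerate_flag") <- FALSE
  out
}

#' Preprocess a raw recording
#'
#' Trims to the detected movement cycles, removes low-frequency noise with the
#' Butterworth high-pass, and normalizes to `[0, 1]` (in that order).
#'
#' @param rec A `vag_recording`.
#' @param n_cycles Expected number of movement cycles.
#' @param cutoff_hz High-pass cutoff (Hz).
#' @param zero_phase Zero-phase filtering option, see [remove_low_frequency()].
#' @return A list of class `vag_preprocessed` with elements `samples` (in
#'   `[0,1]`), `cycle_bounds` (tibble, indices into `samples`), `cycle_len`
#'   (mean samples per cycle), `meta`, and `flags`.
#' @export
preprocess_recording <- function(rec, n_cycles = 10L, cutoff_hz = 10,
                                 zero_phase = FALSE) {
  stopifnot(inherits(rec, "vag_recording"))
  fs <- rec$meta$fs_hz
  cyc <- detect_cycles(rec$samples, fs, n_cycles)
  too_few <- isTRUE(attr(cyc, "warning_flag"))
  if (nrow(cyc) >= 1) {
    lo <- cyc$start[1]
    hi <- cyc$end[nrow(cyc)]
    x <- rec$samples[lo:hi]
    bounds <- dplyr::mutate(cyc, start = .data$start - lo + 1L, end = .data$end - lo + 1L)
    cycle_len <- mean(bounds$end - bounds$start + 1)
  } else {
    x <- rec$samples
    bounds <- cyc
    cycle_len <- length(x) / n_cycles
  }
  x <- remove_low_frequency(x, fs, cutoff_hz = cutoff_hz, zero_phase = zero_phase)
  x <- normalize_unit_interval(x)
  structure(
    list(samples = as.numeric(x), cycle_bounds = bounds, cycle_len = cycle_len,
         meta = rec$meta,
         flags = list(too_few_cycles = too_few,
                      degenerate = isTRUE(attr(x, "degenerate_flag")))),
    class = "vag_preprocessed"
  )
}
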