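# Synthetic VAG cohort generator. Emulates the statistical structure the
# pipeline measures: a cyclic flexion-extension envelope, three frequency
# bands with group-dependent energies and centres, high-frequency click
# bursts, and an additive fluctuation component with two scaling regimes.

#' Fractional Gaussian noise by circulant embedding
#'
#' Exact (Davies-Harte) synthesis of stationary fGn with Hurst exponent `H`
#' and unit variance. Falls back to spectral synthesis with a warning when
#' the circulant embedding is not positive semi-definite.
#'
#' @param H Hurst exponent in (0, 1).
#' @param n Length (>= 16; powers of two are fastest).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
generate_fgn <- function(H, n, seed) {
  stopifnot(H > 0, H < 1, n >= 16)
  k <- 0:n
  gamma_k <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  m <- 2L * n
  cvec <- c(gamma_k, rev(gamma_k[2:n]))
  lambda <- Re(stats::fft(cvec))
  if (min(lambda) < -1e-8 * max(lambda)) {
    warn("Circulant embedding not positive semi-definite; using spectral synthesis.")
    return(generate_colored_noise(2 * H - 1, n, seed))
  }
  lambda <- pmax(lambda, 0)
  with_seed(seed, {
    z <- complex(real = rnorm(m), imaginary = rnorm(m))
    y <- stats::fft(sqrt(lambda / (2 * m)) * z)
    as.numeric(Re(y)[seq_len(n)])
  })
}

#' Colored (power-law) Gaussian noise by spectral synthesis
#'
#' Draws noise with spectrum `S(f) ~ f^-beta`, normalized to unit variance.
#' `beta = 0` is white, `beta = 1` is 1/f ("pink") noise with DFA exponent
#' `alpha = (beta + 1) / 2 = 1`.
#'
#' @param beta Spectral exponent.
#' @param n Length.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
generate_colored_noise <- function(beta, n, seed) {
  stopifnot(n >= 16)
  with_seed(seed, {
    w <- rnorm(n)
    W <- stats::fft(w)
    k <- 0:(n - 1)
    f <- pmin(k, n - k) / n          # two-sided frequency magnitude
    f[1] <- 1 / n                    # avoid division by zero at DC
    shaped <- W * f^(-beta / 2)
    shaped[1] <- 0
    x <- Re(stats::fft(shaped, inverse = TRUE)) / n
    as.numeric((x - mean(x)) / stats::sd(x))
  })
}

# Zero-phase FFT low-pass (brick wall with a raised-cosine rolloff edge).
fft_lowpass <- function(x, fs_hz, cutoff_hz) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (0:(n - 1)) / n * fs_hz
  f <- pmin(f, fs_hz - f)  # two-sided frequency magnitude
  roll <- cutoff_hz * 0.2
  gain <- ifelse(f <= cutoff_hz, 1,
                 ifelse(f >= cutoff_hz + roll, 0,
                        0.5 * (1 + cos(pi * (f - cutoff_hz) / roll))))
  Re(stats::fft(X * gain, inverse = TRUE)) / n
}

# Fluctuation of the DFA profile at a single window size (used to balance
# the two components of the crossover construction at the planted scale).
fluct_at <- function(x, n_win) {
  y <- dfa_profile(x)
  dfa_fluctuation(y, n_win)
}

#' Series with a planted scaling crossover
#'
#' Sum of an fGn(`H_short`) component and a low-pass-filtered (cutoff
#' `1/crossover_s` Hz) fGn(`H_long`) component, amplitude-balanced so their
#' detrended fluctuations are equal at the planted crossover scale: short
#' scales are then dominated by the first regime and long scales by the
#' second. With `integrate_long = TRUE` the long component is cumulatively
#' summed before balancing, planting a nonstationary (alpha > 1) long-scale
#' regime and a sharp slope change.
#'
#' @param H_short,H_long Hurst exponents of the two regimes (must differ).
#' @param crossover_s Planted crossover scale in seconds.
#' @param fs_hz Sampling rate (Hz).
#' @param n Length in samples.
#' @param seed Integer seed.
#' @param integrate_long Integrate the long-scale component (default FALSE).
#' @return Numeric vector of length `n`, unit variance.
#' @export
generate_crossover_series <- function(H_short, H_long, crossover_s, fs_hz, n,
                                      seed, integrate_long = FALSE) {
  if (H_short == H_long && !integrate_long) {
    # single-regime series: no planted crossover
    return(generate_fgn(H_short, n, seed))
  }
  n_star <- round(crossover_s * fs_hz)
  if (n_star < 8 || n_star > n / 4) {
    abort("`crossover_s` is outside the representable window range for this length.")
  }
  short <- generate_fgn(H_short, n, derive_seed(seed, "short"))
  long <- generate_fgn(H_long, n, derive_seed(seed, "long"))
  long <- fft_lowpass(long, fs_hz, 1 / crossover_s)
  if (integrate_long) long <- cumsum(long)
  long <- long - mean(long)
  ratio <- fluct_at(short, n_star) / fluct_at(long, n_star)
  x <- short + long * ratio
  as.numeric(x / stats::sd(x))
}

#' Group profile for the synthetic generator
#'
#' @param band_energy Relative power of the (high, mid, low) bands.
#' @param band_centers_hz Band centre frequencies in Hz, ordered high > mid > low.
#' @param H_short,H_long Hurst exponents of the short-/long-scale fluctuation
#'   regimes of the additive noise component, each in (0, 1).
#' @param crossover_s Planted crossover scale (seconds).
#' @param click_rate_hz Mean rate of damped high-frequency bursts (events/s).
#' @param mod_depth Depth of the flexion-extension amplitude modulation, in
#'   `[0, 1]`.
#' @return A list of class `vag_profile`.
#' @export
group_profile <- function(band_energy = c(1, 1, 2),
                          band_centers_hz = c(600, 200, 50),
                          H_short = 0.6, H_long = 0.8, crossover_s = 0.5,
                          click_rate_hz = 0, mod_depth = 0.8) {
  stopifnot(length(band_energy) == 3, all(band_energy >= 0),
            length(band_centers_hz) == 3,
            band_centers_hz[1] > band_centers_hz[2],
            band_centers_hz[2] > band_centers_hz[3],
            H_short > 0, H_short < 1, H_long > 0, H_long < 1,
            crossover_s > 0, click_rate_hz >= 0,
            mod_depth >= 0, mod_depth <= 1)
  structure(list(band_energy = band_energy, band_centers_hz = band_centers_hz,
                 H_short = H_short, H_long = H_long, crossover_s = crossover_s,
                 click_rate_hz = click_rate_hz, mod_depth = mod_depth),
            class = "vag_profile")
}

#' Default group profiles
#'
#' The osteoarthritis profile has stronger high-band energy, slightly higher
#' band centres, frequent click bursts and stronger short-scale persistence
#' than the healthy-control profile, mirroring increased friction and surface
#' irregularity of degenerated cartilage.
#'
#' @return Named list with `HC` and `OA` [group_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    HC = group_profile(band_energy = c(0.6, 1.0, 2.0),
                       band_centers_hz = c(600, 200, 50),
                       H_short = 0.60, H_long = 0.80, crossover_s = 0.5,
                       click_rate_hz = 0, mod_depth = 0.8),
    OA = group_profile(band_energy = c(1.5, 1.0, 1.4),
                       band_centers_hz = c(650, 210, 55),
                       H_short = 0.85, H_long = 0.75, crossover_s = 0.8,
                       click_rate_hz = 5, mod_depth = 0.8)
  )
}

#' Cohort specification
#'
#' @param n_per_group Recordings per group per channel (>= 2).
#' @param fs_hz Sampling rate; default 4000 Hz keeps the 300/150 Hz band
#'   edges far inside Nyquist.
#' @param n_cycles Flexion-extension cycles per recording.
#' @param cycle_s Cycle duration (seconds).
#' @param chain Kinetic-chain condition attached to the metadata.
#' @param channels Channels to simulate.
#' @param profiles Named list of [group_profile()]s (`HC`, `OA`).
#' @param seed Master seed; per-recording seeds are derived by hashing so
#'   cohorts are extensible without reshuffling existing subjects.
#' @return A list of class `vag_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 20L, fs_hz = 4000, n_cycles = 10L,
                        cycle_s = 3, chain = "CKC", channels = "K1",
                        profiles = default_profiles(), seed = 1L) {
  stopifnot(n_per_group >= 2, fs_hz > 0, n_cycles >= 1, cycle_s > 0,
            all(channels %in% CHANNELS), all(c("HC", "OA") %in% names(profiles)))
  chain <- match.arg(chain, CHAINS)
  structure(list(n_per_group = as.integer(n_per_group), fs_hz = fs_hz,
                 n_cycles = as.integer(n_cycles), cycle_s = cycle_s,
                 chain = chain, channels = channels, profiles = profiles,
                 seed = as.integer(seed)),
            class = "vag_cohort_spec")
}

#' Generate one synthetic VAG recording
#'
#' The signal is a cyclic amplitude envelope applied to the sum of three
#' band-limited noise bands and Poisson-timed damped 600-900 Hz bursts, plus
#' an additive crossover-fluctuation component from the profile's
#' `H_short`/`H_long`/`crossover_s` parameters.
#'
#' @param profile A [group_profile()].
#' @param spec A [cohort_spec()] (supplies fs, cycle count and duration).
#' @param subject_id Subject identifier.
#' @param seed Integer seed for this recording.
#' @param group,channel Metadata for the returned recording.
#' @return A `vag_recording`.
#' @export
generate_recording <- function(profile, spec, subject_id, seed,
                               group = "HC", channel = "K1") {
  fs <- spec$fs_hz
  dur <- spec$n_cycles * spec$cycle_s
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  env <- (1 - profile$mod_depth) + profile$mod_depth * abs(sin(pi * t / spec$cycle_s))
  with_seed(seed, {
    bands <- numeric(n)
    for (b in 1:3) {
      if (profile$band_energy[b] <= 0) next
      fc <- profile$band_centers_hz[b]
      bw <- 0.5 * fc
      noise <- rnorm(n)
      shaped <- fft_bandpass(noise, fs, max(fc - bw / 2, 1), min(fc + bw / 2, 0.49 * fs))
      shaped <- shaped / stats::sd(shaped) * sqrt(profile$band_energy[b])
      bands <- bands + shaped
    }
    clicks <- numeric(n)
    if (profile$click_rate_hz > 0) {
      n_clicks <- stats::rpois(1, profile$click_rate_hz * dur)
      if (n_clicks > 0) {
        pos <- sort(sample.int(n, min(n_clicks, n)))
        tau <- 0.005  # 5 ms decay
        len <- min(round(6 * tau * fs), n)
        amp <- 3 * stats::sd(bands)
        for (p in pos) {
          fc <- min(runif(1, 600, 900), 0.45 * fs)
          idx <- p:min(p + len - 1, n)
          tt <- (idx - p) / fs
          clicks[idx] <- clicks[idx] +
            amp * exp(-tt / tau) * sin(2 * pi * fc * tt + runif(1, 0, 2 * pi))
        }
      }
    }
    cross_s <- min(profile$crossover_s, 0.9 * n / (4 * fs))  # keep representable
    fluct <- generate_crossover_series(profile$H_short, profile$H_long,
                                       cross_s, fs, n,
                                       derive_seed(seed, "fluct"))
    # confine the fluctuation component below the analysis bands: DFA windows
    # (0.1-2 cycles) probe far lower frequencies, so the scaling structure at
    # those scales is untouched while the band spectrum stays clean
    fluct <- fft_lowpass(fluct, fs, min(100, 0.2 * fs))
    fluct <- fluct / stats::sd(fluct)
    x <- env * (bands + clicks) + 0.5 * stats::sd(bands + clicks) * fluct
    new_recording(x, recording_meta(subject_id, group, channel, spec$chain, fs))
  })
}

# Zero-phase FFT band-pass with raised-cosine edges.
fft_bandpass <- function(x, fs_hz, lo_hz, hi_hz) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (0:(n - 1)) / n * fs_hz
  f <- pmin(f, fs_hz - f)
  roll <- 0.1 * (hi_hz - lo_hz)
  up <- ifelse(f <= lo_hz - roll, 0,
               ifelse(f >= lo_hz, 1, 0.5 * (1 - cos(pi * (f - lo_hz + roll) / roll))))
  dn <- ifelse(f <= hi_hz, 1,
               ifelse(f >= hi_hz + roll, 0, 0.5 * (1 + cos(pi * (f - hi_hz) / roll))))
  Re(stats::fft(X * up * dn, inverse = TRUE)) / n
}

#' Generate a synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `vag_cohort` with `recordings` (named list of
#'   `vag_recording`s) and `manifest` (tibble in the manifest dialect; `path`
#'   holds the conventional file name).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "vag_cohort_spec"))
  rows <- tidyr::expand_grid(
    group = c("HC", "OA"),
    subject = seq_len(spec$n_per_group),
    channel = spec$channels
  )
  recs <- vector("list", nrow(rows))
  names_out <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    g <- rows$group[i]
    sid <- sprintf("s%02d%s", rows$subject[i], tolower(substr(g, 1, 1)))
    sd_i <- derive_seed(spec$seed, paste(g, sid, rows$channel[i]))
    recs[[i]] <- generate_recording(spec$profiles[[g]], spec, sid, sd_i,
                                    group = g, channel = rows$channel[i])
    names_out[i] <- sprintf("%s_%s_%s_%s.txt", g, sid, spec$chain, rows$channel[i])
  }
  names(recs) <- names_out
  manifest <- tibble::tibble(
    path = names_out,
    subject_id = purrr::map_chr(recs, \(r) r$meta$subject_id),
    group = rows$group,
    chain = spec$chain,
    channel = rows$channel,
    fs_hz = spec$fs_hz
  )
  structure(list(recordings = recs, manifest = manifest, spec = spec),
            class = "vag_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Writes one delimited-text file per recording plus `manifest.csv`.
#'
#' @param cohort A `vag_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vag_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  for (i in seq_len(nrow(man))) {
    write_recording(cohort$recordings[[man$path[i]]], file.path(dir, man$path[i]))
  }
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  invisible(man_path)
}
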