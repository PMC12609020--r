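# Recording input/output: delimited text and single-channel WAV, with a CSV
# manifest or filename-encoded metadata (<group>_<subject>_<chain>_<channel>).

GROUPS <- c("HC", "OA")
CHANNELS <- c("K1", "K2", "K3")
CHAINS <- c("OKC", "CKC")

#' Recording metadata record
#'
#' @param subject_id Subject identifier string.
#' @param group `"HC"` (healthy control) or `"OA"` (osteoarthritis).
#' @param channel Sensor channel, one of `"K1"`, `"K2"`, `"K3"`.
#' @param chain Kinetic-chain condition, `"OKC"` or `"CKC"`.
#' @param fs_hz Sampling rate in samples/s (> 0).
#' @return A list of class `vag_meta`.
#' @export
recording_meta <- function(subject_id, group, channel, chain, fs_hz) {
  group <- match.arg(group, GROUPS)
  channel <- match.arg(channel, CHANNELS)
  chain <- match.arg(chain, CHAINS)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1 || !is.finite(fs_hz) || fs_hz <= 0) {
    abort("`fs_hz` must be a single positive number.")
  }
  structure(
    list(subject_id = as.character(subject_id), group = group,
         channel = channel, chain = chain, fs_hz = as.numeric(fs_hz)),
    class = "vag_meta"
  )
}

new_recording <- function(samples, meta) {
  samples <- as.numeric(samples)
  if (length(samples) < 2) abort("A recording needs at least 2 samples.")
  if (!all(is.finite(samples))) abort("Recording contains non-finite samples.")
  structure(list(samples = samples, meta = meta), class = "vag_recording")
}

#' @export
print.vag_recording <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<vag_recording> %s %s %s %s: %d samples @ %g Hz (%.2f s)\n",
              m$subject_id, m$group, m$chain, m$channel,
              length(x$samples), m$fs_hz, length(x$samples) / m$fs_hz))
  invisible(x)
}

# Parse "<group>_<subject>_<chain>_<channel>" from a file name.
parse_recording_filename <- function(path) {
  base <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (length(parts) < 4) {
    abort(sprintf("Cannot parse metadata from file name '%s' (expected <group>_<subject>_<chain>_<channel>).", base))
  }
  grp <- parts[1]; chain <- parts[3]; channel <- parts[4]
  if (!grp %in% GROUPS) abort(sprintf("Unknown group token '%s' in '%s'.", grp, base))
  if (!chain %in% CHAINS) abort(sprintf("Unknown chain token '%s' in '%s'.", chain, base))
  if (!channel %in% CHANNELS) abort(sprintf("Unknown channel token '%s' in '%s'.", channel, base))
  list(subject_id = parts[2], group = grp, chain = chain, channel = channel)
}

read_wav_mono <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("Not a RIFF/WAV file.")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("Not a WAVE file.")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little"),
        n_channels = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort("Malformed WAV: missing fmt or data chunk.")
  if (fmt$n_channels != 1) abort("Only 1-channel WAV files are supported.")
  if (fmt$audio_format == 1 && fmt$bits == 16) {
    x <- readBin(data_raw, "integer", length(data_raw) %/% 2, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3 && fmt$bits == 32) {
    x <- readBin(data_raw, "double", length(data_raw) %/% 4, 4, endian = "little")
  } else {
    abort(sprintf("Unsupported WAV encoding (format %d, %d bit).", fmt$audio_format, fmt$bits))
  }
  list(samples = x, fs_hz = fmt$sample_rate)
}

#' Read one VAG recording
#'
#' Reads a single-column delimited-text file or a 1-channel WAV file. Metadata
#' come from `manifest_row` when given; otherwise the file name is parsed as
#' `<group>_<subject>_<chain>_<channel>` (labels assigned from file names).
#'
#' @param path File path.
#' @param manifest_row Optional one-row data frame or list with columns
#'   `subject_id`, `group`, `chain`, `channel`, `fs_hz`. Authoritative over
#'   the file name when present.
#' @param fs_hz Sampling rate, required for text files without a manifest.
#' @return A `vag_recording` (samples + `vag_meta`).
#' @export
read_recording <- function(path, manifest_row = NULL, fs_hz = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  is_wav <- grepl("\\.wav$", path, ignore.case = TRUE)
  if (is_wav) {
    wav <- read_wav_mono(path)
    samples <- wav$samples
    fs_file <- wav$fs_hz
  } else {
    txt <- readLines(path, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    samples <- suppressWarnings(as.numeric(txt))
    if (anyNA(samples)) abort(sprintf("Non-numeric content in '%s'.", path))
    fs_file <- NULL
  }
  if (!is.null(manifest_row)) {
    mr <- as.list(manifest_row)
    meta <- recording_meta(mr$subject_id, mr$group, mr$channel, mr$chain, as.numeric(mr$fs_hz))
  } else {
    p <- parse_recording_filename(path)
    fs_use <- fs_hz %||% fs_file
    if (is.null(fs_use)) abort("`fs_hz` is required when no manifest row is given for a text file.")
    meta <- recording_meta(p$subject_id, p$group, p$channel, p$chain, fs_use)
  }
  new_recording(samples, meta)
}

#' Read a cohort manifest
#'
#' @param path CSV with columns `path,subject_id,group,chain,channel,fs_hz`.
#' @return A tibble, one row per recording file.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("Manifest not found: '%s'.", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "subject_id", "group", "chain", "channel", "fs_hz")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("Manifest is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  as_tibble(df)
}

#' Write a recording as single-column delimited text
#'
#' @param rec A `vag_recording` or numeric vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  x <- if (inherits(rec, "vag_recording")) rec$samples else as.numeric(rec)
  writeLines(sprintf("%.12g", x), path)
  invisible(path)
}
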