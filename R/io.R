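# --- WAV codec --------------------------------------------------------------
#
# Minimal RIFF/WAVE support: mono (or first channel), 16-bit PCM or 32-bit
# IEEE float.  Enough for round-tripping surrogate signals; no compressed or
# multi-chunk exotica.

#' Read a WAV file as a signal
#'
#' Supports 16-bit PCM and 32-bit IEEE float; of multi-channel files only the
#' first channel is kept.  The sampling rate comes from the header.
#'
#' @param path path to a `.wav` file.
#' @param label signal label (defaults to the file name).
#' @return An [emg_signal]; PCM samples are rescaled to `[-1, 1)`.
#' @export
read_wav <- function(path, label = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE"))
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id)) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1L, 2L, endian = "little", signed = FALSE),
        n_channels   = readBin(con, "integer", 1L, 2L, endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1L, 4L, endian = "little"),
        byte_rate    = readBin(con, "integer", 1L, 4L, endian = "little"),
        block_align  = readBin(con, "integer", 1L, 2L, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1L, 2L, endian = "little", signed = FALSE))
      if (sz > 16L) invisible(readBin(con, "raw", sz - 16L))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt chunk", call. = FALSE)
      dat <- readBin(con, "raw", sz)
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
  }
  if (is.null(fmt) || is.null(dat)) stop("malformed WAV file: ", path, call. = FALSE)
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    v <- readBin(dat, "integer", length(dat) %/% 2L, 2L, endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    v <- readBin(dat, "double", length(dat) %/% 4L, 4L, endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bits)",
                 fmt$audio_format, fmt$bits), call. = FALSE)
  }
  if (fmt$n_channels > 1L) v <- v[seq.int(1L, length(v), by = fmt$n_channels)]
  emg_signal(v, fs = fmt$sample_rate, label = label)
}

#' Write a signal as a WAV file
#'
#' @param x an [emg_signal].
#' @param path output path.
#' @param bits 32 (IEEE float, default — lossless for analysis round trips)
#'   or 16 (PCM; samples must lie in `[-1, 1]`).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, bits = 32L) {
  stopifnot(inherits(x, "emg_signal"), bits %in% c(16L, 32L))
  v <- x$samples
  n_bytes <- length(v) * bits / 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(if (bits == 32L) 3L else 1L, 1L), con, 2L, endian = "little")
  writeBin(as.integer(round(x$fs)), con, 4L, endian = "little")
  writeBin(as.integer(round(x$fs) * bits / 8L), con, 4L, endian = "little")
  writeBin(as.integer(c(bits / 8L, bits)), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, 4L, endian = "little")
  if (bits == 32L) {
    writeBin(v, con, 4L, endian = "little")
  } else {
    if (any(abs(v) > 1)) stop("16-bit PCM requires samples in [-1, 1]", call. = FALSE)
    writeBin(as.integer(pmin(pmax(round(v * 32768), -32768L), 32767L)),
             con, 2L, endian = "little")
  }
  invisible(path)
}

# --- delimited text ---------------------------------------------------------

#' Read a signal from WAV or delimited text
#'
#' WAV files carry their own sampling rate (overridable); delimited text —
#' one column of values, or two columns `(time, value)` — requires
#' `fs_override`.  A non-numeric first row is treated as a header.
#'
#' @param path input file; `.wav` is detected by extension.
#' @param fs_override sampling frequency in Hz; mandatory for text input,
#'   overrides the header for WAV.
#' @param label signal label (defaults to the file name).
#' @return An [emg_signal].
#' @export
read_signal <- function(path, fs_override = NULL, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.wav$", path, ignore.case = TRUE)) {
    s <- read_wav(path, label = label)
    if (!is.null(fs_override)) s$fs <- as.numeric(fs_override)
    return(s)
  }
  if (is.null(fs_override))
    stop("'fs_override' is required for delimited-text input (no rate in the file)",
         call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty signal file: ", path, call. = FALSE)
  sep <- if (grepl(",", lines[[1L]])) "," else if (grepl("\t", lines[[1L]])) "\t" else ""
  split1 <- strsplit(trimws(lines[[1L]]), if (sep == "") "[[:space:]]+" else sep)[[1L]]
  skip_header <- anyNA(suppressWarnings(as.numeric(split1)))
  rows <- lines[(1L + skip_header):length(lines)]
  parsed <- lapply(seq_along(rows), function(i) {
    f <- strsplit(trimws(rows[[i]]), if (sep == "") "[[:space:]]+" else sep)[[1L]]
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop(sprintf("non-numeric value at line %d of %s",
                   i + skip_header, path), call. = FALSE)
    v
  })
  ncol <- length(parsed[[1L]])
  if (!ncol %in% c(1L, 2L))
    stop("signal text must have one (value) or two (time,value) columns",
         call. = FALSE)
  vals <- vapply(parsed, function(v) v[ncol], numeric(1L))
  emg_signal(vals, fs = as.numeric(fs_override), label = label)
}

#' Write a signal as delimited text
#'
#' @param x an [emg_signal].
#' @param path output path (CSV with `time_s,value` columns).
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(inherits(x, "emg_signal"))
  df <- data.frame(time_s = (seq_along(x$samples) - 1L) / x$fs,
                   value = x$samples)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- flat key-value config --------------------------------------------------

#' Read / write a flat key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Values are parsed
#' to numeric where possible, comma-separated values to vectors.
#'
#' @param path config file path.
#' @return `read_config`: a named list.  `write_config`: `path`, invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' @rdname read_config
#' @param config named list of scalar or vector values.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    sprintf("%s = %s", k, paste(format(config[[k]], digits = 15, trim = TRUE),
                                collapse = ", ")),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

# --- study results ----------------------------------------------------------

#' Write a fatigue study result to a directory
#'
#' Serializes the profiles, deltas, selected-scale entropy table, ANOVA
#' table and resolved configuration as delimited text plus a key-value
#' config, and a manifest listing every artifact.  Rerunning with the same
#' inputs overwrites deterministically.
#'
#' @param result a `fatigue_study` from [fatigue_study()].
#' @param dir output directory (created if missing).
#' @return Character vector of written file paths (the manifest content),
#'   invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "fatigue_study"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create output directory: ", dir, call. = FALSE)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(format(df, digits = 15, trim = TRUE), p,
                     row.names = FALSE, quote = FALSE)
    p
  }
  files <- c(
    wr(result$profiles, "profiles.csv"),
    wr(result$deltas, "deltas.csv"),
    wr(result$at_scale, "entropies_at_selected_scale.csv"),
    wr(result$anova$anova, "anova.csv"))
  cfg <- result$config
  cfg$selected_scale <- result$selected_scale
  cfg_path <- file.path(dir, "config.txt")
  write_config(cfg, cfg_path)
  files <- c(files, cfg_path)
  manifest <- file.path(dir, "MANIFEST.txt")
  writeLines(basename(files), manifest)
  invisible(c(files, manifest))
}

#' Write a synthetic cohort to a directory
#'
#' One WAV file per subject plus a key-value manifest (subject id, seed,
#' window boundaries in samples).
#'
#' @param cohort a `fatigue_cohort`.
#' @param dir output directory (created if missing).
#' @param format `"wav"` (default) or `"csv"`.
#' @return Character vector of written files, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("wav", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "fatigue_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (su in cohort$subjects) {
    p <- file.path(dir, paste0(su$id, if (format == "wav") ".wav" else ".csv"))
    if (format == "wav") write_wav(su$signal, p) else write_signal_csv(su$signal, p)
    files <- c(files, p)
  }
  spec <- cohort$spec
  man <- file.path(dir, "cohort.txt")
  write_config(list(
    n_subjects = spec$n_subjects, fs = spec$fs, duration_s = spec$duration_s,
    n_windows = spec$n_windows, band_start = spec$band_start,
    band_end_by_window = spec$band_end_by_window,
    noise_floor_db = spec$noise_floor_db, seed = spec$seed,
    window_starts = cohort$subjects[[1L]]$windows$start,
    window_ends = cohort$subjects[[1L]]$windows$end,
    subjects = vapply(cohort$subjects, `[[`, character(1L), "id")), man)
  invisible(c(files, man))
}
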