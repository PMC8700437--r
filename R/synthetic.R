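# --- seeded generation helpers ---------------------------------------------

# run expr under a local RNG state; the caller's stream is untouched
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Seeded Gaussian white noise signal
#'
#' @param n number of samples.
#' @param fs sampling frequency in Hz.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG state.
#' @param label signal label.
#' @return An [emg_signal] of i.i.d. standard normal samples.
#' @export
gen_white_noise <- function(n, fs = 1, seed = NULL, label = "white noise") {
  samples <- with_local_seed(seed, stats::rnorm(n))
  emg_signal(samples, fs = fs, label = label)
}

#' Surrogate surface-EMG signal
#'
#' Band-limited Gaussian noise emulating the second-order spectral statistics
#' of surface EMG: white noise is band-pass filtered with a linear-phase FIR
#' filter applied forward and backward (zero phase, so no phase-induced
#' ordinal-pattern artifacts), and a white noise floor is added at
#' `noise_floor_db` relative to the in-band power.  The result is scaled to
#' unit variance.  The FIR band edges are pulled in by half the transition
#' width so the realised spectrum is contained in `band`.
#'
#' @param fs sampling frequency in Hz (default 10000).
#' @param duration_s signal duration in seconds.
#' @param band numeric `c(f_lo, f_hi)` in Hz, inside `(0, fs/2)`; default
#'   `c(20, 500)`, the physiological sEMG band.
#' @param noise_floor_db white-floor power relative to in-band power, in dB
#'   (default -30, i.e. a 30 dB in-band to out-of-band ratio); `-Inf`
#'   disables the floor.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param label signal label.
#' @return An [emg_signal].
#' @examples
#' s <- gen_semg_surrogate(fs = 2000, duration_s = 2, band = c(20, 400), seed = 1)
#' @export
gen_semg_surrogate <- function(fs = 10000, duration_s = 27.4,
                               band = c(20, 500), noise_floor_db = -30,
                               seed = NULL, label = "sEMG surrogate") {
  if (length(band) != 2L || band[1L] <= 0 || band[2L] >= fs / 2 ||
      band[1L] >= band[2L])
    stop(sprintf("'band' must satisfy 0 < f_lo < f_hi < fs/2 = %g", fs / 2),
         call. = FALSE)
  n <- round(fs * duration_s)
  if (n < 64L) stop("duration too short", call. = FALSE)
  samples <- with_local_seed(seed, {
    x <- stats::rnorm(n)
    y <- .bandpass_zero_phase(x, fs, band)
    y <- y / stats::sd(y)
    if (is.finite(noise_floor_db))
      y <- y + stats::rnorm(n, sd = 10^(noise_floor_db / 20))
    y / stats::sd(y)
  })
  emg_signal(samples, fs = fs, label = label)
}

# Hamming-window FIR bandpass applied forward and backward (zero phase).
# The two passes are performed in the frequency domain — multiplying the
# spectrum by |B(w)|^2 — which is the forward-backward filter up to circular
# boundary handling and is O(n log n) for long records.  Edges are pulled in
# by half the Hamming transition width (~3.3 fs / ntaps) so stopband
# attenuation is reached by the nominal band edges.
.bandpass_zero_phase <- function(x, fs, band) {
  n <- length(x)
  ntaps <- min(1024L, 2L * (n %/% 8L))  # keep well short of the signal
  tw <- 3.3 * fs / ntaps
  lo <- band[1L] + tw / 2
  hi <- band[2L] - tw / 2
  if (lo >= hi) { lo <- band[1L]; hi <- band[2L] }  # narrow band: no margin
  b <- signal::fir1(ntaps, c(lo, hi) / (fs / 2), type = "pass")
  H2 <- Mod(stats::fft(c(b, numeric(n - length(b)))))^2
  Re(stats::fft(stats::fft(x) * H2, inverse = TRUE)) / n
}

#' Specification of a synthetic fatigue cohort
#'
#' Parameters of a multi-subject surrogate sEMG fatigue experiment: each
#' subject sustains a contraction split into `n_windows` chronological
#' windows, and fatigue is modelled as progressive spectral compression — the
#' upper band edge of the surrogate activity decreases window by window,
#' mimicking action-potential widening, which biases the ordinal-pattern
#' distribution toward monotone patterns and lowers entropy.
#'
#' @param n_subjects number of subjects (default 10).
#' @param fs sampling frequency in Hz (default 10000).
#' @param duration_s total record duration per subject in seconds (default
#'   27.4, i.e. 274,000 samples at 10 kHz).
#' @param n_windows number of equal chronological windows (default 4).
#' @param band_start lower band edge in Hz for every window (default 20).
#' @param band_end_by_window non-increasing upper band edges in Hz, one per
#'   window (default `c(500, 400, 320, 250)`).
#' @param noise_floor_db white-floor level in dB relative to in-band power
#'   (default -30).
#' @param seed master seed; per-subject/window seeds are derived from it.
#' @return Object of class `cohort_spec` (validated list).
#' @export
cohort_spec <- function(n_subjects = 10L, fs = 10000, duration_s = 27.4,
                        n_windows = 4L, band_start = 20,
                        band_end_by_window = c(500, 400, 320, 250),
                        noise_floor_db = -30, seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  n_windows <- as.integer(n_windows)
  if (n_subjects < 1L) stop("'n_subjects' must be >= 1", call. = FALSE)
  if (n_windows < 2L) stop("'n_windows' must be >= 2", call. = FALSE)
  if (length(band_end_by_window) != n_windows)
    stop("'band_end_by_window' must have one entry per window", call. = FALSE)
  if (any(diff(band_end_by_window) > 0))
    stop("'band_end_by_window' must be non-increasing (fatigue = spectral compression)",
         call. = FALSE)
  if (any(band_end_by_window > fs / 2) || any(band_end_by_window <= band_start))
    stop("band edges must lie in (band_start, fs/2]", call. = FALSE)
  if (fs * duration_s / n_windows < 64)
    stop("windows too short for the given fs and duration", call. = FALSE)
  structure(list(n_subjects = n_subjects, fs = fs, duration_s = duration_s,
                 n_windows = n_windows, band_start = band_start,
                 band_end_by_window = band_end_by_window,
                 noise_floor_db = noise_floor_db, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d subjects, %g s @ %g Hz, %d windows, band %g-[%s] Hz, floor %g dB, seed %d\n",
              x$n_subjects, x$duration_s, x$fs, x$n_windows, x$band_start,
              paste(x$band_end_by_window, collapse = ","),
              x$noise_floor_db, x$seed))
  invisible(x)
}

#' Generate a synthetic fatigue cohort
#'
#' For each subject, concatenates `n_windows` surrogate sEMG segments whose
#' upper band edge follows `band_end_by_window` — the chronological spectral
#' compression that emulates progressive muscle fatigue.  All randomness is
#' derived deterministically from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return Object of class `fatigue_cohort`: list with `spec` and `subjects`,
#'   where each subject is a list with `id`, `signal` (an [emg_signal]) and
#'   `windows` (data.frame of window index and first/last sample).
#' @examples
#' co <- gen_fatigue_cohort(cohort_spec(n_subjects = 2, duration_s = 2, fs = 2000,
#'                                      band_end_by_window = c(500, 400, 320, 250)))
#' co$subjects[[1]]$windows
#' @export
gen_fatigue_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- with_local_seed(spec$seed,
    matrix(sample.int(.Machine$integer.max, spec$n_subjects * spec$n_windows),
           spec$n_subjects, spec$n_windows))
  win_s <- spec$duration_s / spec$n_windows
  nwin <- round(spec$fs * win_s)
  subjects <- lapply(seq_len(spec$n_subjects), function(s) {
    segs <- lapply(seq_len(spec$n_windows), function(w)
      gen_semg_surrogate(fs = spec$fs, duration_s = win_s,
                         band = c(spec$band_start, spec$band_end_by_window[w]),
                         noise_floor_db = spec$noise_floor_db,
                         seed = seeds[s, w])$samples)
    windows <- data.frame(window = seq_len(spec$n_windows),
                          start = (seq_len(spec$n_windows) - 1L) * nwin + 1L,
                          end = seq_len(spec$n_windows) * nwin)
    list(id = sprintf("S%02d", s),
         signal = emg_signal(unlist(segs), fs = spec$fs,
                             label = sprintf("subject S%02d", s)),
         windows = windows)
  })
  structure(list(spec = spec, subjects = subjects), class = "fatigue_cohort")
}

#' @export
print.fatigue_cohort <- function(x, ...) {
  cat(sprintf("<fatigue_cohort> %d subjects x %d windows (%d samples each)\n",
              length(x$subjects), x$spec$n_windows,
              length(x$subjects[[1L]]$signal$samples)))
  invisible(x)
}
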