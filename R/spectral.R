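# --- Welch PSD --------------------------------------------------------------

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the signal is split into overlapping
#' segments, each windowed (Hann by default) and Fourier transformed, and the
#' squared magnitudes are averaged.  The one-sided density is scaled so that
#' its integral over `[0, fs/2]` equals the signal variance; with
#' `normalize = TRUE` it is rescaled to unit integral (trapezoidal rule), the
#' form used for band-fraction reasoning.
#'
#' @param x an [emg_signal], or numeric vector with `fs` given.
#' @param fs sampling frequency in Hz; taken from the signal when omitted.
#' @param segment_s segment length in seconds (default 1).
#' @param overlap fractional overlap between segments in `[0, 1)` (default 0.5).
#' @param window taper: `"hann"` (default) or `"rect"`.
#' @param normalize rescale the density to unit trapezoidal integral?
#' @param detrend remove the segment mean before windowing (default `TRUE`).
#'
#' @return Object of class `psd_estimate`: list with `freq` (Hz), `density`,
#'   `fs`, `normalized`, `n_segments`.
#' @examples
#' s <- emg_signal(rnorm(20000), fs = 2000)
#' p <- welch_psd(s)
#' head(as.data.frame(p))
#' @export
welch_psd <- function(x, fs = NULL, segment_s = 1, overlap = 0.5,
                      window = c("hann", "rect"), normalize = TRUE,
                      detrend = TRUE) {
  window <- match.arg(window)
  if (is.null(fs)) fs <- signal_fs(x)
  if (!is.finite(fs) || fs <= 0)
    stop("'fs' is required for a bare numeric vector", call. = FALSE)
  x <- as_samples(x)
  nseg <- max(2L, round(segment_s * fs))
  if (nseg > length(x))
    stop(sprintf("segment of %d samples longer than signal (%d samples)",
                 nseg, length(x)), call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("'overlap' must be in [0, 1)", call. = FALSE)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq.int(1L, length(x) - nseg + 1L, by = step)
  w <- if (window == "hann") as.numeric(signal::hanning(nseg)) else rep(1, nseg)
  nfreq <- nseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)]
    if (detrend) seg <- seg - mean(seg)
    X <- stats::fft(seg * w)[seq_len(nfreq)]
    acc <- acc + Re(X * Conj(X))
  }
  # one-sided density in units^2/Hz (interior bins doubled)
  dens <- acc / length(starts) / (fs * sum(w^2))
  if (nfreq > 2L) dens[2L:(nfreq - 1L)] <- 2 * dens[2L:(nfreq - 1L)]
  freq <- seq.int(0L, nfreq - 1L) * fs / nseg
  if (normalize) dens <- dens / pracma::trapz(freq, dens)
  structure(list(freq = freq, density = dens, fs = fs,
                 normalized = isTRUE(normalize),
                 n_segments = length(starts)),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins, 0-%g Hz, %d segments%s\n",
              length(x$freq), max(x$freq), x$n_segments,
              if (x$normalized) ", unit integral" else ""))
  invisible(x)
}

#' @export
as.data.frame.psd_estimate <- function(x, ...) {
  data.frame(freq_hz = x$freq, density = x$density)
}

# trapezoidal band power of a psd_estimate, with linear interpolation at the
# band edges so adjacent bands tile the spectrum exactly
.band_power <- function(psd, band) {
  f1 <- band[1L]; f2 <- band[2L]
  if (f1 < 0 || f2 > max(psd$freq) + 1e-9 || f1 >= f2)
    stop(sprintf("band [%g, %g] Hz outside [0, %g] Hz", f1, f2, max(psd$freq)),
         call. = FALSE)
  inside <- psd$freq > f1 & psd$freq < f2
  f <- c(f1, psd$freq[inside], f2)
  dy <- stats::approx(psd$freq, psd$density, xout = f, rule = 2)$y
  pracma::trapz(f, dy)
}

#' Band power ratio in decibels
#'
#' `10 * log10` of the ratio of the integrated PSD in `band_a` to that in
#' `band_b`, e.g. the sEMG band `[0, 500]` Hz against the noise band
#' `[500, 5000]` Hz.  Antisymmetric in its two bands.
#'
#' @param psd a `psd_estimate` from [welch_psd()].
#' @param band_a,band_b numeric `c(f_lo, f_hi)` in Hz, within `[0, fs/2]`.
#' @return Ratio in dB; `Inf` (with a warning) when `band_b` holds no power.
#' @export
band_power_ratio_db <- function(psd, band_a, band_b) {
  pa <- .band_power(psd, band_a)
  pb <- .band_power(psd, band_b)
  if (pb <= 0) {
    warning("zero integrated power in the reference band; ratio is infinite",
            call. = FALSE)
    return(Inf)
  }
  10 * log10(pa / pb)
}

# --- scale <-> bandwidth ----------------------------------------------------

#' -3 dB cutoff of the m-tap moving-average filter
#'
#' Coarse-graining at scale `m` is an `m`-tap constant-coefficient FIR filter
#' followed by decimation; its magnitude response is
#' `|sin(pi m f / fs) / (m sin(pi f / fs))|`.  The cutoff is the frequency at
#' which this response falls to `1/sqrt(2)`, found by numeric root finding
#' (exact also at small `m`, unlike the `0.443 fs / m` approximation).
#'
#' @param m tap count (= coarse-graining scale), integer >= 1.
#' @param fs sampling frequency in Hz.
#' @return Cutoff frequency in Hz; `fs / 2` for `m = 1` (identity filter).
#' @examples
#' ma_filter_cutoff(2, 10000)   # 2500 Hz exactly
#' ma_filter_cutoff(10, 10000)  # about 443 Hz
#' @export
ma_filter_cutoff <- function(m, fs) {
  m <- as.integer(m)
  if (m < 1L) stop("'m' must be an integer >= 1", call. = FALSE)
  if (fs <= 0) stop("'fs' must be positive", call. = FALSE)
  if (m == 1L) return(fs / 2)
  g <- function(f) abs(sin(pi * m * f / fs) / (m * sin(pi * f / fs))) - 1 / sqrt(2)
  # response decreases from 1 at f -> 0 to 0 at the first null fs/m
  stats::uniroot(g, lower = fs * 1e-9, upper = fs / m * (1 - 1e-9),
                 tol = 1e-10)$root
}

#' Effective sampling rate after scaling
#'
#' Coarse-graining or decimating by `scale` reduces the sampling rate to
#' `fs / scale`; the analysable band then ends at the new Nyquist frequency
#' `fs / (2 * scale)`.
#'
#' @param fs original sampling frequency in Hz.
#' @param scale coarse-graining scale or downsampling factor, integer >= 1.
#' @return Rate in Hz.
#' @examples
#' effective_rate(10000, 10)  # 1000 Hz
#' nyquist_after(10000, 10)   # 500 Hz
#' @export
effective_rate <- function(fs, scale) {
  stopifnot(fs > 0, scale >= 1)
  fs / scale
}

#' @rdname effective_rate
#' @export
nyquist_after <- function(fs, scale) effective_rate(fs, scale) / 2

#' Write a PSD estimate as two-column delimited text
#'
#' @param psd a `psd_estimate`.
#' @param path output file; columns `freq_hz,density` with header.
#' @return `path`, invisibly.
#' @export
write_psd <- function(psd, path) {
  utils::write.csv(as.data.frame(psd), path, row.names = FALSE)
  invisible(path)
}
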