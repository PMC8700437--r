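#' Construct a sampled signal
#'
#' The universal input of the package: a finite real sample vector together
#' with its sampling frequency.
#'
#' @param samples numeric vector of samples (length >= 2, all finite).
#' @param fs sampling frequency in Hz (> 0).
#' @param label free-text label carried through analyses.
#'
#' @return An object of class `emg_signal`: a list with elements `samples`,
#'   `fs` and `label`.
#' @examples
#' s <- emg_signal(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), fs = 1000)
#' s
#' @export
emg_signal <- function(samples, fs, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("signal must contain at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("signal contains non-finite samples", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number (Hz)", call. = FALSE)
  structure(list(samples = samples, fs = as.numeric(fs),
                 label = as.character(label)[1L]),
            class = "emg_signal")
}

#' @export
print.emg_signal <- function(x, ...) {
  cat(sprintf("<emg_signal> %s: %d samples @ %g Hz (%.3f s)\n",
              if (nzchar(x$label)) x$label else "unlabelled",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.emg_signal <- function(x) length(x$samples)

# Accept either an emg_signal or a bare numeric vector everywhere.
as_samples <- function(x) {
  if (inherits(x, "emg_signal")) return(x$samples)
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("signal contains non-finite samples", call. = FALSE)
  x
}

signal_fs <- function(x, default = NA_real_) {
  if (inherits(x, "emg_signal")) x$fs else default
}
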