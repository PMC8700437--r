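# --- coarse-graining --------------------------------------------------------

#' Coarse-grain a signal at scale m
#'
#' Replaces non-overlapping blocks of `m` consecutive samples by their
#' arithmetic mean.  `k` shifts the starting sample of the first block, which
#' generates the `m` composite coarse-grained phases used by [cmpe()] and
#' [rcmpe()]; `k = 1` is the classical coarse-graining.  Trailing samples that
#' do not fill a complete block are discarded.
#'
#' @param x an [emg_signal] or numeric vector.
#' @param m scale (block length), integer >= 1.
#' @param k phase offset, `1 <= k <= m`.
#' @return Numeric vector of length `floor((N - k + 1) / m)`.
#' @examples
#' coarse_grain(1:6, m = 3)         # c(2, 5)
#' coarse_grain(1:7, m = 3, k = 2)  # means of (2,3,4) and (5,6,7)
#' @export
coarse_grain <- function(x, m, k = 1L) {
  x <- as_samples(x)
  m <- as.integer(m); k <- as.integer(k)
  if (m < 1L) stop("'m' must be an integer >= 1", call. = FALSE)
  if (k < 1L || k > m)
    stop(sprintf("phase offset k=%d out of range 1..m=%d", k, m), call. = FALSE)
  n_out <- (length(x) - k + 1L) %/% m
  if (n_out < 1L)
    stop(sprintf("signal too short for scale m=%d, phase k=%d", m, k),
         call. = FALSE)
  if (m == 1L) return(x)
  .colMeans(x[k + seq_len(n_out * m) - 1L], m, n_out)
}

#' All m coarse-grained phases of a signal
#'
#' @inheritParams coarse_grain
#' @return List of `m` numeric vectors; element `k` starts at sample `k`.
#' @seealso [coarse_grain()], [composite_downsample()]
#' @export
coarse_grain_set <- function(x, m) {
  x <- as_samples(x)
  m <- as.integer(m)
  if (m < 1L) stop("'m' must be an integer >= 1", call. = FALSE)
  if (m == 1L) return(list(x))
  # one cumulative sum serves every phase: block mean = difference of the
  # cumulative sum at the block ends, so each phase costs O(N/m), not O(N)
  cs <- c(0, cumsum(x))
  lapply(seq_len(m), function(k) {
    n_out <- (length(x) - k + 1L) %/% m
    if (n_out < 1L)
      stop(sprintf("signal too short for scale m=%d, phase k=%d", m, k),
           call. = FALSE)
    hi <- k + seq_len(n_out) * m - 1L
    (cs[hi + 1L] - cs[hi - m + 1L]) / m
  })
}

# --- MPE family -------------------------------------------------------------

#' Multiscale permutation entropy (MPE)
#'
#' Permutation entropy (delay 1) of the classical (`k = 1`) coarse-grained
#' signal at scale `m`.  Coarse-graining acts as an `m`-tap moving-average
#' filter followed by decimation by `m`, so the effective sampling rate of the
#' analysed sequence is `fs / m` (see [effective_rate()]).
#'
#' @inheritParams coarse_grain
#' @inheritParams permutation_entropy
#' @return A single entropy value (nats, or in `[0, 1]` when normalized).
#' @examples
#' x <- rnorm(5000)
#' mpe(x, m = 5, d = 3)
#' @export
mpe <- function(x, m, d = 3L, normalized = TRUE,
                tie_policy = c("stable", "random"), warn_short = TRUE) {
  permutation_entropy(coarse_grain(x, m, 1L), d = d, tau = 1L,
                      normalized = normalized,
                      tie_policy = match.arg(tie_policy),
                      warn_short = warn_short)
}

#' Composite multiscale permutation entropy (cMPE)
#'
#' Mean over the `m` coarse-grained phases of their individual permutation
#' entropies.  The phase shift recovers patterns that classical MPE discards,
#' easing the length constraint at high scales.
#'
#' @inheritParams mpe
#' @return A single entropy value.
#' @export
cmpe <- function(x, m, d = 3L, normalized = TRUE,
                 tie_policy = c("stable", "random"), warn_short = TRUE) {
  tie_policy <- match.arg(tie_policy)
  phases <- coarse_grain_set(x, m)
  mean(vapply(phases, permutation_entropy, numeric(1L), d = d, tau = 1L,
              normalized = normalized, tie_policy = tie_policy,
              warn_short = warn_short))
}

#' Refined composite multiscale permutation entropy (rcMPE)
#'
#' Averages the per-phase ordinal-pattern probability distributions of the
#' `m` coarse-grained phases first, then takes a single Shannon entropy of the
#' pooled distribution.  By concavity of the entropy this is always at least
#' the composite average [cmpe()].
#'
#' @inheritParams mpe
#' @return A single entropy value.
#' @export
rcmpe <- function(x, m, d = 3L, normalized = TRUE,
                  tie_policy = c("stable", "random"), warn_short = TRUE) {
  tie_policy <- match.arg(tie_policy)
  phases <- coarse_grain_set(x, m)
  pmfs <- vapply(phases,
                 function(p) count_patterns(p, d = d, tau = 1L,
                                            tie_policy = tie_policy,
                                            warn_short = warn_short)$pmf,
                 numeric(factorial(as.integer(d))))
  shannon_entropy(rowMeans(pmfs), d = d, normalized = normalized)
}
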