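# Naive reference implementations used as independent oracles.  They work
# window by window with explicit sorting / explicit index arithmetic, never
# through the package's vectorized rank-matrix path.

# Lehmer index of one window: explicitly sort (value, position) pairs.
# order() is stable, so equal values keep temporal order (earlier rank lower).
oracle_pattern_index <- function(window) {
  p <- order(window)  # sorting permutation, stable on ties
  d <- length(p)
  idx <- 0L
  for (i in seq_len(d - 1L))
    idx <- idx + sum(p[(i + 1L):d] < p[i]) * as.integer(factorial(d - i))
  idx
}

# pattern counts by exhaustive double loop over windows
oracle_pattern_counts <- function(x, d, tau) {
  n <- length(x) - (d - 1L) * tau
  counts <- integer(factorial(d))
  for (s in seq_len(n)) {
    w <- x[s + (0:(d - 1L)) * tau]
    i <- oracle_pattern_index(w)
    counts[i + 1L] <- counts[i + 1L] + 1L
  }
  counts
}

oracle_entropy <- function(counts, d, normalized = TRUE) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  h <- -sum(p * log(p))
  if (normalized) h / log(factorial(d)) else h
}

# coarse-grained phase k by direct per-block means
oracle_coarse <- function(x, m, k) {
  n_out <- (length(x) - k + 1L) %/% m
  vapply(seq_len(n_out),
         function(j) mean(x[(m * (j - 1L) + k):(m * (j - 1L) + k + m - 1L)]),
         numeric(1L))
}

oracle_phases_downsample <- function(x, tau)
  lapply(seq_len(tau), function(k) x[seq.int(k, length(x), by = tau)])

# small battery of qualitatively different test signals
make_test_signals <- function(seed = 1L, n = 3000L) {
  set.seed(seed)
  list(
    white    = rnorm(n),
    uniform  = runif(n),
    ar1      = as.numeric(stats::arima.sim(list(ar = 0.9), n)),
    sinusoid = sin(2 * pi * (1:n) / 37.3) + 1e-3 * rnorm(n),
    ramp_jit = seq_len(n) / n + 0.05 * rnorm(n),
    steps    = rep(rnorm(n %/% 10L + 1L), each = 10L)[1:n] + 1e-6 * rnorm(n)
  )
}
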