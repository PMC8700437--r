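# --- permutation bookkeeping -------------------------------------------------
#
# Ordinal patterns are indexed by the lexicographic Lehmer code of the
# permutation that sorts the embedded window ascending (index 0 is the fully
# ascending window, index d!-1 the fully descending one).  A lookup table maps
# the rank vector of a window to that index; tables are cached per dimension.

.rcdpe_cache <- new.env(parent = emptyenv())

# all permutations of 1:d as a d! x d integer matrix, lexicographic row order
.permutations <- function(d) {
  if (d == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(d - 1L)
  out <- matrix(0L, nrow(sub) * d, d)
  row <- 1L
  for (first in seq_len(d)) {
    rest <- setdiff(seq_len(d), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# Lehmer (lexicographic) index of a single permutation, 0-based
.lehmer_index <- function(p) {
  d <- length(p)
  idx <- 0L
  for (i in seq_len(d - 1L))
    idx <- idx + sum(p[(i + 1L):d] < p[i]) * as.integer(factorial(d - i))
  idx
}

# table mapping rank-vector key -> Lehmer index of the sorting permutation.
# key(r) = sum (r_j - 1) d^(j-1); r_j is the rank of window element j.
.pattern_table <- function(d) {
  key <- paste0("d", d)
  tab <- .rcdpe_cache[[key]]
  if (!is.null(tab)) return(tab)
  if (d > 8L) stop("embedding dimension above 8 is not supported", call. = FALSE)
  P <- .permutations(d)                      # rows: possible rank vectors
  pow <- d^(0:(d - 1L))
  keys <- as.numeric((P - 1L) %*% pow)
  lehmer <- integer(nrow(P))
  for (r in seq_len(nrow(P))) lehmer[r] <- .lehmer_index(order(P[r, ]))
  tab <- list(keys = keys, lehmer = lehmer, pow = pow)
  .rcdpe_cache[[key]] <- tab
  tab
}

# rank matrix of embedded windows: R[w, j] = rank of element j within window w.
# ties: "stable" gives the earlier element the lower rank; "random" breaks each
# tie by an i.i.d. uniform draw (transitive: ranks by the pair (value, u)).
.window_ranks <- function(W, tie_policy) {
  n <- nrow(W); d <- ncol(W)
  R <- matrix(1L, n, d)
  U <- if (tie_policy == "random") matrix(stats::runif(n * d), n, d) else NULL
  for (j in 2:d) {
    for (i in 1:(j - 1L)) {
      eq <- W[, i] == W[, j]
      if (tie_policy == "random") {
        i_below <- W[, i] < W[, j] | (eq & U[, i] < U[, j])
      } else {
        i_below <- W[, i] < W[, j] | eq   # earlier index ranks lower
      }
      R[, j] <- R[, j] + i_below
      R[, i] <- R[, i] + !i_below
    }
  }
  R
}

# ordinal pattern index (0-based Lehmer) of every embedded window
.ordinal_indices <- function(x, d, tau, tie_policy = "stable") {
  n <- length(x) - (d - 1L) * tau
  if (n < 1L)
    stop(sprintf("signal too short: need N - (d-1)*tau >= 1, got N=%d, d=%d, tau=%d",
                 length(x), d, tau), call. = FALSE)
  W <- matrix(0, n, d)
  for (j in seq_len(d)) W[, j] <- x[seq_len(n) + (j - 1L) * tau]
  tab <- .pattern_table(d)
  keyw <- as.numeric((.window_ranks(W, tie_policy) - 1L) %*% tab$pow)
  tab$lehmer[match(keyw, tab$keys)]
}

#' Encode the ordinal pattern of a single window
#'
#' Returns the lexicographic (Lehmer) index, in `0:(factorial(d) - 1)`, of the
#' permutation that sorts the window ascending.  Index 0 is the fully
#' ascending pattern, `factorial(d) - 1` the fully descending one.
#'
#' @param window numeric vector of `d >= 2` finite values.
#' @param tie_policy how equal values are ranked: `"stable"` (default; the
#'   earlier sample receives the lower rank — the usual Bandt-Pompe
#'   convention) or `"random"` (each tie broken by an independent uniform
#'   draw; seed-controlled via [set.seed()]).
#'
#' @return Integer pattern index in `[0, factorial(d) - 1]`.
#' @examples
#' encode_pattern(c(1, 3))       # ascending "12" -> 0
#' encode_pattern(c(5, 2))       # descending "21" -> 1
#' encode_pattern(c(2, 2))       # tie -> stable policy gives "12" -> 0
#' pattern_label(encode_pattern(c(0.2, 0.9, 0.4)), d = 3)
#' @seealso [pattern_label()], [count_patterns()]
#' @export
encode_pattern <- function(window, tie_policy = c("stable", "random")) {
  tie_policy <- match.arg(tie_policy)
  window <- as.numeric(window)
  d <- length(window)
  if (d < 2L) stop("window must contain at least 2 values", call. = FALSE)
  if (!all(is.finite(window)))
    stop("window contains non-finite values", call. = FALSE)
  .ordinal_indices(window, d = d, tau = 1L, tie_policy = tie_policy)
}

#' Human-readable label of an ordinal pattern
#'
#' @param index integer pattern index as returned by [encode_pattern()].
#' @param d embedding dimension.
#' @return Character string such as `"231"`: position `i` of the string names
#'   the original time position of the `i`-th smallest value.
#' @examples
#' pattern_label(0, 3)  # "123", fully ascending
#' @export
pattern_label <- function(index, d) {
  tab <- .pattern_table(d)
  P <- .permutations(d)
  vapply(index, function(i) {
    stopifnot(i >= 0, i < factorial(d))
    paste(P[i + 1L, ], collapse = "")
  }, character(1L))
}

#' Count ordinal patterns of a signal
#'
#' Slides the delay embedding `(x[n], x[n + tau], ..., x[n + (d-1) tau])` over
#' the signal and tallies the `factorial(d)` ordinal patterns.  The number of
#' windows is `N - (d - 1) * tau`.
#'
#' @param x an [emg_signal] or numeric vector.
#' @param d embedding dimension (integer >= 2).
#' @param tau time delay / downsampling factor (integer >= 1).
#' @inheritParams encode_pattern
#' @param warn_short warn when fewer than `5 * factorial(d)` windows are
#'   available (a common minimum-length recommendation); never an error.
#'
#' @return An object of class `pattern_distribution`: list with integer
#'   `counts` (length `factorial(d)`), `pmf`, `n_windows`, `d`, `tau`.
#' @examples
#' count_patterns(c(1, 2, 3, 4, 5), d = 3)  # all windows ascending
#' @export
count_patterns <- function(x, d, tau = 1L, tie_policy = c("stable", "random"),
                           warn_short = TRUE) {
  tie_policy <- match.arg(tie_policy)
  x <- as_samples(x)
  d <- as.integer(d); tau <- as.integer(tau)
  if (d < 2L) stop("'d' must be an integer >= 2", call. = FALSE)
  if (tau < 1L) stop("'tau' must be an integer >= 1", call. = FALSE)
  idx <- .ordinal_indices(x, d, tau, tie_policy)
  if (warn_short && length(idx) < 5L * factorial(d))
    warning(sprintf(
      "only %d embedded windows for d=%d (recommended >= 5*d! = %d); pattern probabilities may be poorly estimated",
      length(idx), d, 5L * factorial(d)), call. = FALSE)
  counts <- tabulate(idx + 1L, nbins = factorial(d))
  new_pattern_distribution(counts, d, tau)
}

new_pattern_distribution <- function(counts, d, tau = NA_integer_) {
  n <- sum(counts)
  structure(list(counts = as.integer(counts), pmf = counts / n,
                 n_windows = as.integer(n), d = as.integer(d),
                 tau = as.integer(tau)),
            class = "pattern_distribution")
}

#' @export
print.pattern_distribution <- function(x, ...) {
  cat(sprintf("<pattern_distribution> d=%d (%d patterns), %d windows\n",
              x$d, length(x$counts), x$n_windows))
  top <- order(x$counts, decreasing = TRUE)[seq_len(min(5L, length(x$counts)))]
  for (i in top[x$counts[top] > 0])
    cat(sprintf("  %s : %d (%.4f)\n", pattern_label(i - 1L, x$d),
                x$counts[i], x$pmf[i]))
  invisible(x)
}

#' Shannon entropy of a pattern distribution
#'
#' Computes `H = -sum(p * log(p))` in nats with the convention
#' `0 * log(0) = 0`; the normalized form divides by `log(factorial(d))` so the
#' value lies in `[0, 1]` with 1 attained by the uniform pattern distribution.
#'
#' @param dist a `pattern_distribution` (from [count_patterns()]) or a bare
#'   probability vector summing to 1.
#' @param d embedding dimension; taken from `dist` when it is a
#'   `pattern_distribution`.
#' @param normalized divide by `log(factorial(d))`? Default `TRUE`.
#' @return A single nonnegative number.
#' @examples
#' shannon_entropy(c(0.5, 0.5, 0, 0, 0, 0), d = 3, normalized = FALSE)  # log(2)
#' @export
shannon_entropy <- function(dist, d = NULL, normalized = TRUE) {
  if (inherits(dist, "pattern_distribution")) {
    p <- dist$pmf
    if (is.null(d)) d <- dist$d
  } else {
    p <- as.numeric(dist)
    if (is.null(d)) stop("'d' is required for a bare probability vector", call. = FALSE)
  }
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-8)
    stop("invalid probability mass function", call. = FALSE)
  nz <- p > 0
  h <- -sum(p[nz] * log(p[nz]))
  if (normalized) h <- h / log(factorial(d))
  h
}

#' Permutation entropy of a signal
#'
#' Shannon entropy (nats) of the empirical ordinal-pattern distribution of the
#' delay embedding with dimension `d` and delay `tau`.  With
#' `normalized = TRUE` the value is divided by `log(factorial(d))` and lies in
#' `[0, 1]`; it is invariant under strictly increasing transformations of the
#' signal.
#'
#' @inheritParams count_patterns
#' @param normalized divide by `log(factorial(d))`? Default `TRUE`.
#' @return A single number in `[0, 1]` (normalized) or
#'   `[0, log(factorial(d))]`.
#' @examples
#' permutation_entropy(seq_len(100), d = 3)          # ramp: one pattern -> 0
#' permutation_entropy(rnorm(1e4), d = 3)            # white noise -> close to 1
#' @seealso [mpe()], [rcmpe()], [rcdpe()] for the multiscale variants.
#' @export
permutation_entropy <- function(x, d = 3L, tau = 1L, normalized = TRUE,
                                tie_policy = c("stable", "random"),
                                warn_short = TRUE) {
  dist <- count_patterns(x, d = d, tau = tau, tie_policy = match.arg(tie_policy),
                         warn_short = warn_short)
  shannon_entropy(dist, normalized = normalized)
}
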