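test_that("composite downsampling partitions the signal into disjoint phases", {
  p <- composite_downsample(1:7, 3)
  expect_equal(p, list(c(1, 4, 7), c(2, 5), c(3, 6)))
  expect_equal(composite_downsample(1:5, 1), list(1:5 + 0))
  expect_error(composite_downsample(1:5, 6), "exceeds")
  # partition property: indices of a seeded signal are used exactly once
  set.seed(21)
  x <- rnorm(1037)
  ph <- composite_downsample(x, 10)
  expect_equal(sort(unlist(ph)), sort(x))
  expect_equal(sum(lengths(ph)), length(x))
  expect_lte(diff(range(lengths(ph))), 1L)
})

test_that("DPE equals PE of the decimated first phase and collapses correctly", {
  set.seed(22)
  x <- rnorm(4000)
  expect_identical(dpe(x, 1, d = 3), permutation_entropy(x, d = 3))
  # ramp stays a ramp; short decimated phase triggers the length guard
  expect_warning(h0 <- dpe(seq_len(200), 7, d = 3), "5\\*d!")
  expect_equal(h0, 0)
  ph1 <- x[seq.int(1, length(x), by = 4)]
  expect_identical(dpe(x, 4, d = 3), permutation_entropy(ph1, d = 3))
})

test_that("cDPE and rcDPE match their per-phase oracles", {
  set.seed(23)
  x <- rnorm(2500)
  tau <- 5L; d <- 3L
  counts <- lapply(oracle_phases_downsample(x, tau),
                   function(p) oracle_pattern_counts(p, d, 1L))
  per_phase <- vapply(counts, oracle_entropy, numeric(1L), d = d)
  expect_equal(cdpe(x, tau, d = d), mean(per_phase))
  pmfs <- sapply(counts, function(ct) ct / sum(ct))
  expect_equal(rcdpe(x, tau, d = d), oracle_entropy(rowMeans(pmfs), d))
  # length-weighted pooling equals pooling the raw counts
  pooled <- Reduce(`+`, counts)
  expect_equal(rcdpe(x, tau, d = d, weights = "length"),
               oracle_entropy(pooled, d))
})

test_that("rcDPE dominates cDPE on every battery signal and factor", {
  for (x in make_test_signals(seed = 24)) {
    for (tau in c(2L, 5L, 10L)) {
      expect_gte(rcdpe(x, tau, d = 3, warn_short = FALSE) + 1e-12,
                 cdpe(x, tau, d = 3, warn_short = FALSE))
    }
  }
})

test_that("scale-1 collapse holds across the whole estimator family", {
  set.seed(25)
  x <- rnorm(1200)
  h <- permutation_entropy(x, d = 3)
  for (f in list(mpe, cmpe, rcmpe)) expect_identical(f(x, 1, d = 3), h)
  for (f in list(dpe, cdpe, rcdpe)) expect_identical(f(x, 1, d = 3), h)
})

test_that("decimating i.i.d. noise preserves whiteness: rcDPE stays near one", {
  set.seed(26)
  x <- runif(1e5)
  for (tau in c(2L, 5L, 10L))
    expect_lt(abs(rcdpe(x, tau, d = 4) - 1), 0.02)
})

test_that("rcDPE of an incommensurate sinusoid is deterministic and phase-stable", {
  x <- sin(2 * pi * (1:5000) / 13.7)   # period not a multiple of tau
  a <- rcdpe(x, 4, d = 3, warn_short = FALSE)
  b <- rcdpe(x, 4, d = 3, warn_short = FALSE)
  expect_identical(a, b)
  expect_true(is.finite(a) && a >= 0 && a <= 1)
})

test_that("the moving-average prefilter flag changes decimation of broadband noise", {
  set.seed(27)
  x <- rnorm(20000)
  plain <- rcdpe(x, 10, d = 3)
  filt <- rcdpe(x, 10, d = 3, prefilter = TRUE)
  # prefiltering correlates neighbouring retained samples, lowering entropy
  expect_lt(filt, plain)
})
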