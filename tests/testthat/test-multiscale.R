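test_that("coarse_grain reproduces direct block-mean arithmetic", {
  expect_equal(coarse_grain(1:6, m = 3), c(2, 5))
  expect_equal(coarse_grain(1:6, m = 1), 1:6)
  expect_equal(coarse_grain(1:7, m = 3, k = 2), c(3, 6))  # blocks (2,3,4), (5,6,7)
  expect_error(coarse_grain(1:6, m = 3, k = 4), "out of range")
  expect_error(coarse_grain(1:3, m = 5), "too short")
})

test_that("coarse-grained phases match the per-block oracle across scales", {
  set.seed(11)
  x <- rnorm(257)  # deliberately not divisible by any scale
  for (m in c(1L, 2L, 3L, 10L)) {
    phases <- coarse_grain_set(x, m)
    expect_length(phases, m)
    for (k in seq_len(m)) {
      expect_equal(phases[[k]], oracle_coarse(x, m, k))
      expect_length(phases[[k]], (length(x) - k + 1L) %/% m)
    }
  }
})

test_that("k=1 coarse-graining equals m-tap FIR filtering followed by m-decimation", {
  set.seed(12)
  x <- rnorm(500)
  for (m in c(2L, 5L, 10L)) {
    fir <- stats::filter(x, rep(1 / m, m), method = "convolution", sides = 1)
    dec <- as.numeric(fir)[seq.int(m, length(x), by = m)]
    expect_equal(coarse_grain(x, m), dec)
  }
})

test_that("MPE, cMPE and rcMPE all collapse to PE at scale 1", {
  set.seed(13)
  x <- rnorm(2000)
  h <- permutation_entropy(x, d = 4)
  expect_identical(mpe(x, 1, d = 4), h)
  expect_identical(cmpe(x, 1, d = 4), h)
  expect_identical(rcmpe(x, 1, d = 4), h)
})

test_that("cMPE equals the independent per-phase PE average and lies within the phase range", {
  set.seed(14)
  x <- rnorm(1500)
  for (m in c(2L, 5L)) {
    per_phase <- vapply(seq_len(m), function(k)
      oracle_entropy(oracle_pattern_counts(oracle_coarse(x, m, k), 3L, 1L), 3L),
      numeric(1L))
    expect_equal(cmpe(x, m, d = 3), mean(per_phase))
    expect_gte(cmpe(x, m, d = 3), min(per_phase))
    expect_lte(cmpe(x, m, d = 3), max(per_phase))
  }
})

test_that("rcMPE equals the entropy of the explicitly pooled per-phase pmfs", {
  set.seed(15)
  x <- rnorm(3000)
  m <- 7L; d <- 4L
  pmfs <- sapply(seq_len(m), function(k) {
    cts <- oracle_pattern_counts(oracle_coarse(x, m, k), d, 1L)
    cts / sum(cts)
  })
  expect_equal(rcmpe(x, m, d = d), oracle_entropy(rowMeans(pmfs), d))
})

test_that("rcMPE dominates cMPE (Jensen) on every battery signal and scale", {
  for (x in make_test_signals(seed = 16)) {
    for (m in c(2L, 5L, 10L)) {
      expect_gte(rcmpe(x, m, d = 3, warn_short = FALSE) + 1e-12,
                 cmpe(x, m, d = 3, warn_short = FALSE))
    }
  }
})

test_that("MPE of block-averaged i.i.d. noise stays near one, and rises with scale for near-unit-root AR(1)", {
  set.seed(17)
  g <- rnorm(1e5)
  for (m in c(2L, 10L, 20L))
    expect_lt(abs(mpe(g, m, d = 3) - 1), 0.02)
  # coarse-graining decorrelates short-memory AR(1), raising entropy
  ar <- as.numeric(stats::arima.sim(list(ar = 0.9), 5e4))
  expect_gt(mpe(ar, 20, d = 3), mpe(ar, 1, d = 3))
  # same rising branch for oversampled band-limited noise
  s <- gen_semg_surrogate(fs = 10000, duration_s = 5, band = c(20, 500), seed = 18)
  expect_gt(mpe(s, 20, d = 3), mpe(s, 1, d = 3) + 0.2)
})
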