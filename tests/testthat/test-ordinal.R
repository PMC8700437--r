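test_that("encode_pattern reproduces the elementary d=2 patterns and the tie convention", {
  expect_identical(encode_pattern(c(1, 3)), 0L)   # ascending "12"
  expect_identical(encode_pattern(c(5, 2)), 1L)   # descending "21"
  expect_identical(encode_pattern(c(2, 2)), 0L)   # tie: earlier index ranks lower
  expect_identical(pattern_label(0L, 2), "12")
  expect_identical(pattern_label(1L, 2), "21")
  expect_error(encode_pattern(c(1, NA)), "non-finite")
  expect_error(encode_pattern(3), "at least 2")
})

test_that("encode_pattern matches the explicit sort-pairs oracle on random windows", {
  set.seed(42)
  for (d in 2:5) {
    for (rep in 1:40) {
      w <- rnorm(d)
      expect_identical(encode_pattern(w), oracle_pattern_index(w))
    }
    # windows with ties
    for (rep in 1:20) {
      w <- sample(1:3, d, replace = TRUE)
      expect_identical(encode_pattern(w), oracle_pattern_index(w))
    }
  }
})

test_that("count_patterns handles monotone series and the window-count arithmetic", {
  d1 <- suppressWarnings(count_patterns(c(1, 2, 3, 4, 5), d = 3, tau = 1))
  expect_identical(d1$counts, c(3L, 0L, 0L, 0L, 0L, 0L))
  expect_identical(d1$n_windows, 3L)
  d2 <- suppressWarnings(count_patterns(c(1, 2, 3, 4, 5), d = 3, tau = 2))
  expect_identical(d2$n_windows, 1L)
  expect_error(count_patterns(c(1, 2), d = 3, tau = 5), "too short")
  expect_warning(count_patterns(rnorm(20), d = 3), "5\\*d!")
})

test_that("pattern counting equals the naive enumeration oracle across d and tau", {
  set.seed(7)
  for (d in 2:5) for (tau in c(1L, 2L, 3L, 10L)) {
    x <- rnorm(400)
    got <- suppressWarnings(count_patterns(x, d = d, tau = tau))
    expect_identical(got$counts, oracle_pattern_counts(x, d, tau))
    expect_identical(got$n_windows, length(x) - (d - 1L) * tau)
  }
  # quantized signals force many ties through the same oracle path
  for (d in 2:4) {
    x <- sample(0:4, 300, replace = TRUE)
    got <- suppressWarnings(count_patterns(x, d = d, tau = 2))
    expect_identical(got$counts, oracle_pattern_counts(x, d, 2L))
  }
})

test_that("shannon_entropy matches closed forms and both normalizations", {
  one_hot <- c(1, rep(0, 5))
  expect_equal(shannon_entropy(one_hot, d = 3), 0)
  expect_equal(shannon_entropy(one_hot, d = 3, normalized = FALSE), 0)
  expect_equal(shannon_entropy(rep(1 / 24, 24), d = 4), 1)
  expect_equal(shannon_entropy(c(0.5, 0.5, 0, 0, 0, 0), d = 3, normalized = FALSE),
               log(2))
  expect_error(shannon_entropy(c(0.7, 0.7), d = 2), "invalid probability")
})

test_that("permutation entropy is zero on ramps, near one on white noise, and monotone-invariant", {
  expect_equal(permutation_entropy(seq_len(100), d = 3), 0)
  set.seed(123)
  x <- runif(1e5)
  h <- permutation_entropy(x, d = 3)
  expect_lt(abs(h - 1), 0.01)
  # strictly increasing transforms leave ordinal patterns untouched
  expect_identical(permutation_entropy(x^3, d = 3), h)
  expect_identical(permutation_entropy(exp(2 * x) - 5, d = 3), h)
})

test_that("pmf normalization and entropy bounds hold on a signal battery", {
  for (x in make_test_signals(seed = 3)) {
    for (d in c(3L, 4L)) {
      dist <- suppressWarnings(count_patterns(x, d = d))
      expect_identical(sum(dist$counts), dist$n_windows)
      expect_lt(abs(sum(dist$pmf) - 1), 1e-12)
      h <- shannon_entropy(dist)
      expect_gte(h, 0); expect_lte(h, 1)
      hn <- shannon_entropy(dist, normalized = FALSE)
      expect_lte(hn, log(factorial(d)) + 1e-12)
    }
  }
})

test_that("random tie policy is seed-reproducible and differs from stable on heavily tied data", {
  x <- rep(c(1, 1, 2, 2), 50)
  set.seed(5); a <- count_patterns(x, d = 3, tie_policy = "random")$counts
  set.seed(5); b <- count_patterns(x, d = 3, tie_policy = "random")$counts
  expect_identical(a, b)
  s <- count_patterns(x, d = 3, tie_policy = "stable")$counts
  expect_false(identical(a, s))
  # random ties still produce valid pattern counts
  expect_identical(sum(a), length(x) - 2L)
})
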