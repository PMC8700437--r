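test_that("white-noise generation is seed-reproducible with sane moments", {
  a <- gen_white_noise(5000, fs = 100, seed = 41)
  b <- gen_white_noise(5000, fs = 100, seed = 41)
  expect_identical(a$samples, b$samples)
  expect_lt(abs(mean(a$samples)), 4 / sqrt(5000))
  expect_lt(abs(permutation_entropy(gen_white_noise(1e5, 1, seed = 42), d = 3) - 1),
            0.01)
})

test_that("the sEMG surrogate is calibrated: 30 dB in-band ratio at a -30 dB floor", {
  s <- gen_semg_surrogate(fs = 10000, duration_s = 10, band = c(20, 500),
                          noise_floor_db = -30, seed = 43)
  p <- welch_psd(s)
  r <- band_power_ratio_db(p, c(0, 500), c(500, 5000))
  expect_lt(abs(r - 30), 1)
  expect_lt(abs(var(s$samples) - 1), 1e-9)
  # spectral mass concentrated below the upper band edge
  below <- pracma::trapz(p$freq[p$freq <= 500], p$density[p$freq <= 500])
  expect_gt(below, 0.95)
})

test_that("disabling the noise floor leaves only filter leakage above the band", {
  s <- gen_semg_surrogate(fs = 10000, duration_s = 5, band = c(20, 500),
                          noise_floor_db = -Inf, seed = 44)
  p <- welch_psd(s)
  above <- pracma::trapz(p$freq[p$freq >= 600], p$density[p$freq >= 600])
  expect_lt(above, 1e-4)
  expect_identical(s$samples,
                   gen_semg_surrogate(fs = 10000, duration_s = 5,
                                      band = c(20, 500), noise_floor_db = -Inf,
                                      seed = 44)$samples)
  expect_error(gen_semg_surrogate(fs = 1000, duration_s = 1, band = c(20, 600)),
               "band")
})

test_that("cohort generation is deterministic at every level and annotates windows", {
  sp <- cohort_spec(n_subjects = 3, duration_s = 2, fs = 2000, seed = 45)
  a <- gen_fatigue_cohort(sp)
  b <- gen_fatigue_cohort(sp)
  for (i in 1:3)
    expect_identical(a$subjects[[i]]$signal$samples, b$subjects[[i]]$signal$samples)
  w <- a$subjects[[1]]$windows
  expect_equal(w$window, 1:4)
  expect_equal(w$start, c(1, 1001, 2001, 3001))
  expect_equal(w$end, c(1000, 2000, 3000, 4000))
  # different subjects get different realizations
  expect_false(identical(a$subjects[[1]]$signal$samples,
                         a$subjects[[2]]$signal$samples))
})

test_that("cohort_spec validates its fatigue progression", {
  expect_error(cohort_spec(band_end_by_window = c(400, 500, 320, 250)),
               "non-increasing")
  expect_error(cohort_spec(band_end_by_window = c(500, 400, 320)), "one entry per window")
  expect_error(cohort_spec(n_windows = 1), ">= 2")
  expect_error(cohort_spec(fs = 800, band_end_by_window = c(500, 450, 420, 410)),
               "band edges")
})

test_that("spectral compression lowers rcDPE monotonically across fatigue windows", {
  co <- gen_fatigue_cohort(cohort_spec(n_subjects = 2, duration_s = 8, seed = 46))
  for (su in co$subjects) {
    wins <- segment_windows(su$signal, 4)
    v <- vapply(wins, rcdpe, numeric(1L), tau = 10, d = 4, warn_short = FALSE)
    expect_true(all(diff(v) < 0))
  }
})

test_that("identical band edges across windows yield only estimator-noise deltas", {
  sp <- cohort_spec(n_subjects = 4, duration_s = 8, n_windows = 2,
                    band_end_by_window = c(500, 500), seed = 47)
  co <- gen_fatigue_cohort(sp)
  deltas <- vapply(co$subjects, function(su) {
    wins <- segment_windows(su$signal, 2)
    rcdpe(wins[[1]], 10, d = 4, warn_short = FALSE) -
      rcdpe(wins[[2]], 10, d = 4, warn_short = FALSE)
  }, numeric(1L))
  expect_lt(abs(mean(deltas)), 0.005)
})

test_that("widening the injected band gap increases the W1-W4 entropy delta", {
  gap_delta <- function(w4_edge, seed) {
    sp <- cohort_spec(n_subjects = 3, duration_s = 6,
                      band_end_by_window = c(500, 450, 400, w4_edge), seed = seed)
    co <- gen_fatigue_cohort(sp)
    mean(vapply(co$subjects, function(su) {
      wins <- segment_windows(su$signal, 4)
      rcdpe(wins[[1]], 10, d = 4, warn_short = FALSE) -
        rcdpe(wins[[4]], 10, d = 4, warn_short = FALSE)
    }, numeric(1L)))
  }
  expect_gt(gap_delta(250, 48), gap_delta(390, 48))
})
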