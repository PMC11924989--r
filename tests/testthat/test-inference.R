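test_that("the JZS Bayes factor matches the brute-force oracle", {
  for (n in c(5, 10, 20)) {
    for (d in seq(0, 3, length.out = 7)) {
      t <- d * sqrt(n)
      expect_equal(saccdecode:::jzs_bf10(t, n), bf10_oracle(t, n),
                   tolerance = 1e-4)
    }
  }
  # sample interface: a d ~ 1.5 effect at n = 10 is substantial evidence
  withr::with_seed(1, {
    x <- rnorm(10, 0.65, 0.1)
    d <- t_stat(x, 0.5) / sqrt(10)
    bf <- bf_ttest(x, 0.5)
    expect_gt(bf, 3)
    expect_equal(bf, bf10_oracle(t_stat(x, 0.5), 10), tolerance = 1e-4)
  })
})

test_that("bf_ttest favours the null at t = 0 and is reciprocal and symmetric", {
  x <- c(0.45, 0.55, 0.48, 0.52, 0.47, 0.53, 0.49, 0.51, 0.46, 0.54) # mean 0.5
  bf <- bf_ttest(x, 0.5)
  expect_lt(bf, 1)
  # BF01 = 1 / BF10 by construction of the ratio
  expect_equal(bf * (1 / bf), 1)
  # two-sided prior: reflection about the null leaves the BF unchanged
  expect_equal(bf_ttest(1 - x, 0.5), bf, tolerance = 1e-10)
  expect_error(bf_ttest(rep(0.5, 5), 0.5), "zero variance")
  expect_error(bf_ttest(0.5), "at least 2")
})

test_that("onset detection applies the three-consecutive rule exactly", {
  step <- 1000 / 256
  mk <- function(v) tibble::tibble(time_ms = (seq_along(v) - 1) * step, bf10 = v)
  expect_equal(detect_onset(mk(c(1, 4, 5, 6, 2, 1))), step)
  expect_equal(detect_onset(mk(c(4, 4, 2, 4, 4, 4))), 3 * step)
  expect_true(is.na(detect_onset(mk(c(2.9, 2, 1, 2, 2, 2)))))
  # runs outside the search window are ignored
  expect_true(is.na(detect_onset(mk(c(4, 4, 4, 1, 1, 1)), window = c(15, 100))))
})

test_that("directional onset detection ignores below-null evidence", {
  series <- synthetic_series(10, onset_ms = 145, post = 0.9, seed = 3)
  # plant a strong below-chance excursion well before the true onset
  early <- series$time_ms >= 50 & series$time_ms < 70
  series$accuracy[early] <- series$accuracy[early] - 0.2
  bf <- bf_timecourse(series, 0.5)
  expect_lt(detect_onset(bf, direction = "any"), 70)
  expect_equal(detect_onset(bf, direction = "above"), 145.
               , tolerance = 4)
})

test_that("Bayes-factor time courses classify evidence sensibly", {
  series <- synthetic_series(10, onset_ms = 145, post = 0.9, seed = 2)
  bf <- bf_timecourse(series, 0.5)
  post <- bf$time_ms > 160
  expect_true(all(bf$bf10[post] > 3))
  expect_true(all(bf$evidence[post] == "alternative"))
  pre <- bf$time_ms < 130 & bf$time_ms >= 0
  expect_lt(mean(bf$bf10[pre] > 3), 0.05)
  # single-timepoint composition equals bf_ttest on the same numbers
  tp <- series[series$time_ms == series$time_ms[1], ]
  expect_equal(bf$bf10[1], bf_ttest(tp$accuracy, 0.5))
  expect_error(bf_timecourse(series[series$subject == "S01", ]), "2 subjects")
})

test_that("spurious evidence under the null is rare", {
  withr::with_seed(9, {
    frac <- replicate(10, {
      t_ms <- epoch_times_ms()
      series <- purrr::map_dfr(1:10, function(i) {
        tibble::tibble(subject = as.character(i), time_ms = t_ms,
                       accuracy = 0.5 + rnorm(length(t_ms), 0, 0.05))
      })
      bf <- bf_timecourse(series, 0.5)
      mean(bf$bf10 > 3)
    })
    expect_lt(mean(frac), 0.05)
  })
})

test_that("leave-two-out jackknife has the right combinatorics and recovery", {
  series <- synthetic_series(10, onset_ms = 145, post = 0.9, seed = 5)
  est <- jackknife_onset_ci(series, 0.5, direction = "above")
  expect_equal(est$n_permutations, choose(10, 2))
  expect_equal(est$n_permutations, 45)
  expect_false(is.na(est$onset_ms))
  expect_true(est$ci_low_ms <= est$onset_ms && est$onset_ms <= est$ci_high_ms)
  expect_lt(est$ci_high_ms - est$ci_low_ms, 40)
  expect_lt(abs(est$onset_ms - 145), 8)
  expect_equal(est$n_absent, 0)
  # identical subjects: zero-width interval at the full-sample onset
  t_ms <- epoch_times_ms()
  acc <- ifelse(t_ms >= 200, 0.9, 0.5) + rep(seq(0, 0.009, length.out = 10),
                                             each = length(t_ms))
  ident <- tibble::tibble(subject = rep(sprintf("S%02d", 1:10), each = length(t_ms)),
                          time_ms = rep(t_ms, 10), accuracy = acc)
  est2 <- jackknife_onset_ci(ident, 0.5, direction = "above")
  expect_equal(est2$ci_low_ms, est2$ci_high_ms)
  expect_equal(est2$ci_low_ms, est2$onset_ms)
  expect_error(jackknife_onset_ci(series[series$subject %in% c("S01", "S02"), ]),
               "4 subjects")
})

test_that("paired condition differences are tested against zero", {
  a <- synthetic_series(10, onset_ms = 100, post = 0.9, noise_sd = 0.02, seed = 7)
  b <- withr::with_seed(8, a %>% dplyr::mutate(
    accuracy = accuracy - ifelse(time_ms >= 100, 0.2, 0) +
      rnorm(dplyr::n(), 0, 0.005)))
  d <- difference_bf(a, b)
  expect_true(all(d$bf10[d$time_ms > 120] > 3))
  expect_lt(mean(d$bf10[d$time_ms < 80] > 3), 0.05)
  # symmetric under argument order (two-sided prior)
  d2 <- difference_bf(b, a)
  expect_equal(d$bf10, d2$bf10, tolerance = 1e-9)
  # near-identical series favour the null at almost every timepoint (pure
  # noise still produces the occasional large t) and never yield an onset
  bsame <- withr::with_seed(9, a %>% dplyr::mutate(
    accuracy = accuracy + rnorm(dplyr::n(), 0, 1e-4)))
  dnull <- difference_bf(a, bsame)
  expect_gt(mean(dnull$bf10 < 1), 0.85)
  expect_true(is.na(detect_onset(dnull)))
  expect_error(difference_bf(a, b[b$subject != "S01", ]), "paired")
})
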