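test_that("separable classes are decoded perfectly after their onset", {
  ep <- separable_epochs(n = 20, gap = 8, onset_ms = 100)
  stack <- train_stack(ep, 1, "left", seed = 1)
  # testing the training trials upper-bounds held-out accuracy
  train_acc <- cross_test(stack, ep, seq_len(40), "selftest")
  post <- train_acc$accuracy[train_acc$time_ms > 120]
  expect_true(all(post == 1))
  cv <- crossval_same(ep, 1, "left", k = 5, seed = 1)
  expect_gt(mean(cv$accuracy[cv$time_ms > 120]), 0.95)
  expect_gte(min(train_acc$accuracy), max(0, mean(cv$accuracy) - 0.5)) # sanity
})

test_that("label-shuffled and pure-noise data decode at chance", {
  ep <- separable_epochs(n = 20, gap = 0) # gap 0: no class signal at all
  cv <- crossval_same(ep, 1, "left", k = 5, seed = 2)
  # multiplicity-aware: the fraction of timepoints outside a 99% binomial
  # band around 0.5 should be small
  band <- 2.58 * sqrt(0.25 / unique(cv$n_test))
  frac_out <- mean(abs(cv$accuracy - 0.5) > band)
  expect_lt(frac_out, 0.08)
  ep2 <- separable_epochs(n = 20, gap = 8)
  ep2$meta$sf_class <- withr::with_seed(4, sample(ep2$meta$sf_class))
  cv2 <- crossval_same(ep2, 1, "left", k = 5, seed = 2)
  expect_lt(abs(mean(cv2$accuracy) - 0.5), 0.05)
})

test_that("discriminant weights recover the embedded topography", {
  cfg <- session_config()
  truth <- make_ground_truth()
  des <- cohort_design(n_train_per_class = 40, sides = "left", seed = 31)
  ep <- simulate_epochs(des, truth, cfg, seed = 32)
  stack <- train_stack(ep, 1, "left", seed = 1)
  topo <- truth$topographies[, 1]
  post <- which(stack$times_ms > 120 & stack$times_ms < 400)
  cors <- abs(apply(stack$weights[, post], 2, stats::cor, y = topo))
  expect_gt(median(cors), 0.5)
  pre <- which(stack$times_ms < 60)
  expect_lt(median(abs(apply(stack$weights[, pre], 2, stats::cor, y = topo))), 0.3)
})

test_that("a sign-flipped test pattern yields below-chance accuracy", {
  ep <- separable_epochs(n = 30, gap = 8)
  stack <- train_stack(ep, 1, "left", seed = 1)
  flipped <- ep
  flipped$data <- -flipped$data
  acc <- cross_test(stack, flipped, seq_len(60), "flipped")
  expect_lt(mean(acc$accuracy[acc$time_ms > 120]), 0.1)
})

test_that("decoding errors are informative", {
  ep <- separable_epochs(n = 20, gap = 4)
  expect_error(crossval_same(ep, 1, "left", k = 25), "exceeds")
  one_class <- ep
  one_class$meta$sf_class <- "high"
  expect_error(train_stack(one_class, 1, "left"), "class")
  stack <- train_stack(ep, 1, "left")
  expect_error(cross_test(stack, ep, integer(0), "far"), "far")
})

test_that("the evaluation is strictly on the time diagonal", {
  ep <- separable_epochs(n = 15, gap = 6, onset_ms = 0)
  stack <- train_stack(ep, 1, "left", seed = 1)
  # zero out the discriminants except at one timepoint: accuracy must revert
  # to chance everywhere else, so no off-diagonal evaluation can occur
  tstar <- 120
  keep <- which.min(abs(stack$times_ms - tstar))
  stack$weights[, -keep] <- 0
  stack$bias[-keep] <- 0
  acc <- cross_test(stack, ep, seq_len(30), "diag")
  expect_gt(acc$accuracy[keep], 0.9)
  off <- acc$accuracy[-keep]
  expect_true(all(abs(off - 0.5) < 0.35))
})

test_that("aggregation averages within condition then across sides", {
  base <- tibble::tibble(subject = "S01", condition = "near", side = "left",
                         train_location = 1L, test_location = 2L,
                         time_ms = c(0, 10), accuracy = c(0.4, 0.4), n_test = 10)
  twin <- base %>% dplyr::mutate(test_location = 3L, accuracy = c(0.6, 0.6))
  right <- base %>% dplyr::mutate(side = "right", train_location = 5L,
                                  test_location = 6L, accuracy = c(0.8, 0.8))
  agg <- aggregate_series(dplyr::bind_rows(base, twin, right))
  # left: mean(0.4, 0.6) = 0.5; across sides: mean(0.5, 0.8) = 0.65
  expect_equal(agg$accuracy, c(0.65, 0.65))
  # identity and permutation invariance
  expect_equal(aggregate_series(base)$accuracy, base$accuracy)
  perm <- aggregate_series(dplyr::bind_rows(right, twin, base))
  expect_equal(perm, agg)
})

test_that("saccade-latency binning assigns and drops bins correctly", {
  ep <- separable_epochs(n = 20, gap = 6)
  n <- nrow(ep$meta)
  ep$meta$base_type <- "saccade_peripheral"
  ep$meta$stim_to_saccade_ms <- rep(200, n)
  stack <- train_stack_on <- NULL
  ep_tr <- separable_epochs(n = 20, gap = 6)
  stack <- train_stack(ep_tr, 1, "left", seed = 1)
  expect_message(
    out <- bin_by_saccade_latency(stack, ep, seq_len(n),
                                  edges = c(100, 200, 300)),
    "empty"
  )
  expect_equal(unique(out$condition), "lat200-300")
  expect_equal(unique(out$n_test), n)
  # near-uniform latencies spread over equal bins within multinomial tolerance
  ep$meta$stim_to_saccade_ms <- withr::with_seed(5, runif(n, 100, 400))
  out2 <- bin_by_saccade_latency(stack, ep, seq_len(n),
                                 edges = c(100, 200, 300, 400))
  counts <- out2 %>% dplyr::distinct(condition, n_test)
  expect_true(all(abs(counts$n_test - n / 3) <= 3 * sqrt(n * (1 / 3) * (2 / 3))))
})

test_that("chance-level pipelines produce no onset under label permutation", {
  cfg <- session_config()
  truth <- make_ground_truth()
  detected <- 0
  for (rep in 1:40) {
    series <- purrr::map_dfr(1:6, function(i) {
      sseed <- 40000 + rep * 17 + i
      des <- cohort_design(n_train_per_class = 15, n_test_per_class = 0,
                           n_saccade_per_class = 0, sides = "left",
                           include_incongruent = FALSE, seed = sseed)
      ep <- simulate_epochs(des, subject_truth(truth, sseed), cfg,
                            subject_id = sprintf("S%02d", i), seed = sseed + 1)
      ep$meta$sf_class <- withr::with_seed(sseed + 2, sample(ep$meta$sf_class))
      crossval_same(ep, 1, "left", k = 5, seed = sseed + 3) %>%
        dplyr::mutate(subject = sprintf("S%02d", i))
    })
    bf <- bf_timecourse(series, null_value = 0.5)
    if (!is.na(detect_onset(bf, direction = "above"))) detected <- detected + 1
  }
  expect_lte(detected / 40, 0.05)
})

test_that("the compiled discriminant matches the pure-R reference", {
  withr::with_seed(13, {
    n <- 30
    X <- array(rnorm(n * 64 * 3), dim = c(n, 64, 3))
    y <- rep(c(TRUE, FALSE), each = n / 2)
    fit_c <- saccdecode:::lda_fit_stack_cpp(X, seq_len(n) - 1L, as.integer(y))
    for (t in 1:3) {
      fit_r <- saccdecode:::fit_lda(X[, , t], y)
      expect_equal(as.vector(fit_c$weights[, t]), unname(fit_r$w),
                   tolerance = 1e-10)
      expect_equal(fit_c$bias[t], fit_r$b, tolerance = 1e-10)
    }
  })
})
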