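test_that("five-sample velocity is exact for constant and linear motion", {
  g <- flat_gaze(1)
  v <- compute_velocity(g)
  expect_true(all(v$vx[3:(nrow(g) - 2)] == 0))
  ramp <- flat_gaze(1)
  ramp$x_dva <- ramp$x_dva + 10 * ramp$time_s
  v <- compute_velocity(ramp)
  expect_equal(v$vx[100:900], rep(10, 801), tolerance = 1e-9)
  expect_error(compute_velocity(flat_gaze(0.004)), "at least 5 samples")
})

test_that("velocity peak of a raised-cosine saccade matches the analytic maximum", {
  g <- flat_gaze(2)
  g <- inject_saccade(g, 1, amp = 20, dur_s = 0.050)
  v <- compute_velocity(g)
  analytic <- pi * 20 / 0.050 / 2
  expect_equal(max(v$vx, na.rm = TRUE), analytic, tolerance = 0.02 * analytic)
})

test_that("velocity is NA inside and within two samples of blinks", {
  g <- flat_gaze(1)
  g$blink[300:350] <- TRUE
  g$x_dva[300:350] <- NaN
  v <- compute_velocity(g)
  expect_true(all(is.na(v$vx[298:352])))
  expect_false(anyNA(v$vx[260:290]))
})

test_that("detector finds injected saccades and nothing in quiet fixation", {
  quiet <- flat_gaze(20, jitter_sd = 0.02, seed = 3)
  expect_equal(nrow(detect_saccades(quiet)), 0)
  g <- inject_saccade(quiet, 10, amp = 20, dur_s = 0.050)
  ev <- detect_saccades(g)
  expect_equal(sum(ev$valid), 1)
  expect_lt(abs(ev$onset_s[ev$valid] - 10) * 1000, 2)
  expect_equal(ev$amplitude[ev$valid], 20, tolerance = 0.1)
  expect_warning(detect_saccades(flat_gaze(1)), "constant")
})

test_that("events closer than 50 ms are merged keeping the first", {
  g <- flat_gaze(4, jitter_sd = 0.02, seed = 4)
  g <- inject_saccade(g, 1, amp = 3, dur_s = 0.025)
  g <- inject_saccade(g, 1.055, amp = 3, dur_s = 0.025) # 30 ms after offset
  ev <- detect_saccades(g, amplitude_threshold = 1)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset_s - 1), 0.005)
  # idempotence of the merge rule at the event level
  ev2 <- saccdecode:::merge_saccade_events(
    tibble::tibble(i0 = c(100, 160, 400), i1 = c(130, 190, 430)),
    dt = 0.001, merge_ms = 50)
  expect_identical(saccdecode:::merge_saccade_events(ev2, 0.001, 50), ev2)
})

test_that("raising the threshold multiplier never increases event counts", {
  g <- flat_gaze(30, jitter_sd = 0.02, seed = 5)
  for (i in 1:12) g <- inject_saccade(g, 2 * i, amp = runif(1, 1, 6), dur_s = 0.025)
  counts <- vapply(c(5, 6, 8, 12, 20), function(lam) {
    nrow(detect_saccades(g, lambda = lam, amplitude_threshold = 0.5))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detector recovers small saccades in realistic fixational noise", {
  withr::with_seed(11, {
    hits <- 0; total <- 0; errs <- numeric(0)
    for (b in 1:5) {
      g <- flat_gaze(26, jitter_sd = 0.02, seed = 100 + b)
      onsets <- seq(1, 25, by = 1)
      for (on in onsets) {
        g <- inject_saccade(g, on, amp = runif(1, 1, 5), dur_s = 0.025,
                            angle = runif(1, 0, 2 * pi))
      }
      ev <- detect_saccades(g, amplitude_threshold = 0.5)
      total <- total + length(onsets)
      for (on in onsets) {
        d <- min(abs(ev$onset_s - on)) * 1000
        if (d <= 2 + 1e-6) { hits <- hits + 1; errs <- c(errs, d) }
      }
    }
    expect_gte(hits / total, 0.95)
  })
  # false-event rate on saccade-free noise at most 1 per 100 s
  g0 <- flat_gaze(100, jitter_sd = 0.02, seed = 55)
  expect_lte(nrow(detect_saccades(g0, amplitude_threshold = 0.5)), 1)
})

test_that("exclusion rules fire in fixed order with single reasons", {
  cfg <- tiny_config()
  fx <- cfg$geometry$fixation_points
  sched <- tibble::tibble(
    trial_id = 1:2, block = 1L,
    trial_type = c("fixation", "fixation"), base_type = trial_type,
    is_catch = FALSE, fixation_side = "left", location_id = 1L,
    sf_class = "low", stimulus_onset_s = c(1, 3), stimulus_duration_ms = 100,
    cue_onset_s = NA_real_, true_saccade_onset_s = NA_real_,
    stim_to_saccade_ms = NA_real_
  )
  g <- flat_gaze(5, jitter_sd = 0.02, seed = 60)
  # 3 dva excursion during trial 1's stimulus
  g$y_dva[1001:1100] <- g$y_dva[1001:1100] + 3
  rep_ <- exclude_trials(sched, g, detect_saccades(g, amplitude_threshold = 1), cfg)
  expect_equal(rep_$reason, c("gaze_deviation", "none"))
  expect_equal(rep_$kept, c(FALSE, TRUE))
})

test_that("saccade-trial exclusions: latency window, landing, stimulus offset", {
  cfg <- tiny_config()
  mk_sacc_trial <- function(stim_s, cue_s, id = 1L) tibble::tibble(
    trial_id = id, block = 1L, trial_type = "saccade_peripheral",
    base_type = "saccade_peripheral", is_catch = FALSE,
    fixation_side = "left", location_id = 5L, sf_class = "low",
    stimulus_onset_s = stim_s, stimulus_duration_ms = 100,
    cue_onset_s = cue_s, true_saccade_onset_s = NA_real_,
    stim_to_saccade_ms = NA_real_
  )
  base_gaze <- function(seed) flat_gaze(4, jitter_sd = 0.02, seed = seed)
  # saccade 80 ms after stimulus onset -> out of the 100-400 ms window
  # (it lands after stimulus offset, so the latency rule is what fires)
  g <- inject_saccade(base_gaze(61), 2.08, amp = 20.08, dur_s = 0.05)
  rep_ <- exclude_trials(mk_sacc_trial(2.0, 1.8), g,
                         detect_saccades(g), cfg)
  expect_equal(rep_$reason, "saccade_latency_out_of_range")
  # saccade at 200 ms latency, landing on target, stimulus gone -> kept
  g <- inject_saccade(base_gaze(62), 2.2, amp = 20.08, dur_s = 0.05)
  rep_ <- exclude_trials(mk_sacc_trial(2.0, 1.8), g, detect_saccades(g), cfg)
  expect_equal(rep_$reason, "none")
  # landing 3 dva off target
  g <- base_gaze(63)
  g <- inject_saccade(g, 2.2, amp = 20.08, dur_s = 0.05)
  g <- inject_saccade(g, 2.2, amp = 3, dur_s = 0.05, angle = pi / 2)
  rep_ <- exclude_trials(mk_sacc_trial(2.0, 1.8), g, detect_saccades(g), cfg)
  expect_equal(rep_$reason, "bad_landing")
  # eyes arrive while the stimulus is still on screen
  g <- inject_saccade(base_gaze(64), 2.03, amp = 20.08, dur_s = 0.05)
  rep_ <- exclude_trials(mk_sacc_trial(2.0, 1.9), g, detect_saccades(g), cfg)
  expect_equal(rep_$reason, "stimulus_visible_at_landing")
})
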