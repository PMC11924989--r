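make_rec <- function(eeg, rate = 256, events = NULL) {
  rownames(eeg) <- saccdecode:::eeg_channel_names()
  structure(list(eeg = eeg, rate_hz = rate,
                 events = events %||% tibble::tibble(sample_index = integer(),
                                                     event_code = integer(),
                                                     trial_id = integer()),
                 channel_names = rownames(eeg), subject_id = "SYN"),
            class = "continuous_recording")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("standardization is identity at 256 Hz with silent mastoids", {
  eeg <- matrix(rnorm(64 * 512), 64)
  eeg[63:64, ] <- 0
  rec <- standardize_record(make_rec(eeg))
  expect_equal(unname(rec$eeg), unname(eeg))
})

test_that("mastoid referencing removes common-mode offsets", {
  eeg <- matrix(rnorm(64 * 512), 64)
  a <- standardize_record(make_rec(eeg))
  b <- standardize_record(make_rec(eeg + 7.3)) # common offset on all channels
  expect_equal(a$eeg, b$eeg, tolerance = 1e-12)
  bad <- make_rec(eeg)
  bad$channel_names <- bad$channel_names[1:62]
  rownames(bad$eeg) <- NULL
  expect_error(standardize_record(bad), "mastoid")
})

test_that("resampling from 512 Hz attenuates 100 Hz by at least 20 dB", {
  t <- (0:(512 * 4 - 1)) / 512
  eeg <- matrix(rep(sin(2 * pi * 100 * t), each = 64), 64, byrow = FALSE)
  eeg[63:64, ] <- 0
  rec <- standardize_record(make_rec(eeg, rate = 512))
  expect_equal(rec$rate_hz, 256)
  mid <- 200:800
  atten <- 20 * log10(max(abs(rec$eeg[1, mid])) / 1)
  expect_lt(atten, -20)
  # and a 10 Hz component survives resampling nearly unchanged
  eeg2 <- matrix(rep(sin(2 * pi * 10 * t), each = 64), 64)
  eeg2[63:64, ] <- 0
  rec2 <- standardize_record(make_rec(eeg2, rate = 512))
  expect_equal(max(abs(rec2$eeg[1, mid])), 1, tolerance = 0.05)
})

test_that("band-pass and notch behave as specified", {
  t <- (0:(256 * 10 - 1)) / 256
  mk <- function(f) {
    eeg <- matrix(rep(sin(2 * pi * f * t), each = 64), 64)
    eeg[63:64, ] <- 0
    make_rec(eeg)
  }
  mid <- 700:1860
  out50 <- filter_eeg(mk(50))
  expect_lt(max(abs(out50$eeg[1, mid])), 0.05) # >= 95% reduction
  out10 <- filter_eeg(mk(10))
  expect_equal(max(abs(out10$eeg[1, mid])), 1, tolerance = 0.05)
  # the 0.1 Hz high-pass needs a few of its ~1.6 s time constants to settle,
  # so judge DC removal well inside a longer record
  dc <- filter_eeg(make_rec(matrix(1, 64, 256 * 40)))
  expect_lt(max(abs(dc$eeg[1, (256 * 15):(256 * 25)])), 0.05)
  slow <- make_rec(matrix(0, 64, 100), rate = 100)
  expect_error(filter_eeg(slow), "configuration error")
})

test_that("epoching and baseline correction satisfy their invariants", {
  cfg <- tiny_config(seed = 12, eeg_rate_hz = 256, gaze_jitter_sd_dva = 0,
                     microsaccade_rate_hz = 0, blink_rate_hz = 0)
  sch <- build_session_schedule(cfg)
  g <- generate_gaze(sch, cfg)
  truth <- make_ground_truth()
  rec <- standardize_record(generate_eeg(sch, g, truth, cfg))
  ep <- epoch_and_baseline(rec, sch)
  expect_equal(dim(ep$data)[1], sum(!sch$is_catch))
  expect_equal(nrow(ep$meta), dim(ep$data)[1])
  expect_true(0 %in% ep$times_ms)
  expect_equal(diff(ep$times_ms)[1], 1000 / 256)
  bl <- apply(ep$data[, , ep$times_ms >= -100 & ep$times_ms <= 0], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-10)
  # baseline correction is idempotent
  again <- saccdecode:::baseline_correct(ep$data, ep$times_ms)
  expect_equal(again, ep$data, tolerance = 1e-12)
})

test_that("a constant recording epochs to all zeros", {
  cfg <- tiny_config(seed = 13)
  sch <- build_session_schedule(cfg)
  n <- ceiling((max(sch$trial_id) * cfg$trial_slot_s + 1.5) * 256)
  rec <- make_rec(matrix(5, 64, n),
                  events = tibble::tibble(
                    sample_index = round(sch$stimulus_onset_s * 256) + 1L,
                    event_code = 1L, trial_id = sch$trial_id))
  ep <- epoch_and_baseline(rec, sch)
  expect_equal(max(abs(ep$data)), 0)
})

test_that("a post-stimulus step survives epoching at its amplitude", {
  cfg <- tiny_config(seed = 14)
  sch <- build_session_schedule(cfg)
  n <- ceiling((max(sch$trial_id) * cfg$trial_slot_s + 1.5) * 256)
  eeg <- matrix(0, 64, n)
  for (s in round(sch$stimulus_onset_s * 256) + 1L) {
    idx <- (s + round(0.1 * 256)):(s + round(0.5 * 256))
    eeg[, idx] <- eeg[, idx] + 5
  }
  rec <- make_rec(eeg, events = tibble::tibble(
    sample_index = round(sch$stimulus_onset_s * 256) + 1L,
    event_code = 1L, trial_id = sch$trial_id))
  ep <- epoch_and_baseline(rec, sch)
  late <- ep$times_ms > 110 & ep$times_ms < 490
  expect_equal(mean(ep$data[1, 1, late]), 5, tolerance = 0.01)
})

test_that("ocular components are selected by the saccade/fixation variance ratio", {
  withr::with_seed(21, {
    rate <- 256
    n <- 60 * rate
    # the per-window variance is estimated from ~8 samples, so the ratio only
    # stabilizes with many saccades, as in a real session
    sacc <- seq(1, 59, by = 0.15)
    acts <- matrix(rnorm(3 * n), 3, n)
    # component 2: 3x variance bursts locked to saccade onsets
    for (on in sacc) {
      idx <- round((on - 0.02) * rate):round((on + 0.01) * rate)
      acts[2, idx] <- acts[2, idx] * sqrt(3)
    }
    spans <- fixation_spans(tibble::tibble(onset_s = sacc, offset_s = sacc + 0.05),
                            span_s = 40)
    sel <- select_ocular_components(acts, sacc, spans, rate)
    expect_equal(sel$rejected, 2L)
    expect_equal(sel$ratios$ratio[c(1, 3)], c(1, 1), tolerance = 0.15)
    # strict inequality at the boundary: a ratio of exactly 1.1 is kept
    sel2 <- select_ocular_components(acts, sacc, spans, rate,
                                     ratio_threshold = sel$ratios$ratio[2])
    expect_false(2L %in% sel2$rejected)
    expect_warning(
      out <- select_ocular_components(acts, numeric(0), spans, rate),
      "inapplicable")
    expect_equal(out$rejected, integer(0))
  })
})

test_that("the variance-ratio criterion isolates planted ocular components", {
  rate <- 256
  n <- 60 * rate
  sacc <- seq(1, 59, by = 0.15)
  spans <- fixation_spans(tibble::tibble(onset_s = sacc, offset_s = sacc + 0.04),
                          span_s = 60)
  hits <- 0; false_rej <- 0
  for (run in 1:100) {
    withr::with_seed(3000 + run, {
      acts <- matrix(rnorm(4 * n), 4, n)
      # component 1 ocular; 2-4 neural (stimulus-locked but saccade-agnostic)
      for (on in sacc) {
        idx <- round((on - 0.02) * rate):round((on + 0.01) * rate)
        acts[1, idx] <- acts[1, idx] * 2
      }
      sel <- select_ocular_components(acts, sacc, spans, rate)
      if (1L %in% sel$rejected) hits <- hits + 1
      if (length(setdiff(sel$rejected, 1L))) false_rej <- false_rej + 1
    })
  }
  expect_gte(hits, 95)
  expect_lte(false_rej, 5)
})
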