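#' Gaze velocity by five-sample moving-window differentiation
#'
#' Computes per-axis velocity `v[n] = (p[n+2] + p[n+1] - p[n-1] - p[n-2]) /
#' (6 * dt)` (exact for linear motion, noise-suppressing for jittery
#' fixation). Samples inside, or within two samples of, a blink span are set
#' to `NA`.
#'
#' @param gaze Gaze tibble (`time_s`, `x_dva`, `y_dva`, optionally `blink`)
#'   sampled uniformly.
#' @return Tibble with `time_s`, `vx`, `vy` (dva/s).
#' @export
compute_velocity <- function(gaze) {
  n <- nrow(gaze)
  if (n < 5) abort("input error: gaze trace must have at least 5 samples")
  dt <- median(diff(gaze$time_s))
  five_point <- function(p) {
    v <- rep(NA_real_, n)
    i <- 3:(n - 2)
    v[i] <- (p[i + 2] + p[i + 1] - p[i - 1] - p[i - 2]) / (6 * dt)
    v
  }
  vx <- five_point(gaze$x_dva)
  vy <- five_point(gaze$y_dva)
  if (!is.null(gaze$blink) && any(gaze$blink)) {
    bad <- which(gaze$blink)
    bad <- unique(pmax(1L, pmin(n, rep(bad, each = 5) + (-2:2))))
    vx[bad] <- NA_real_; vy[bad] <- NA_real_
  }
  vx[is.nan(vx)] <- NA_real_; vy[is.nan(vy)] <- NA_real_
  tibble::tibble(time_s = gaze$time_s, vx = vx, vy = vy)
}

# median-based robust SD: sqrt(median(v^2) - median(v)^2)
median_sd <- function(v) {
  v <- v[!is.na(v)]
  sqrt(max(0, median(v^2) - median(v)^2))
}

#' Detect saccades with a median-based velocity threshold
#'
#' Implements an elliptical velocity-threshold detector: per-axis thresholds
#' are `lambda` (default 5) times the median-based standard deviation of all
#' recorded velocities (blink samples excluded), an event is a run of samples
#' with `(vx/thx)^2 + (vy/thy)^2 > 1` lasting at least `min_dur_ms`, events
#' separated by less than `merge_ms` are merged by keeping the first, and an
#' event is flagged `valid` when its endpoint displacement exceeds
#' `amplitude_threshold` (15 dva by default, targeting the ~20 dva cued
#' saccades; lower it to retain microsaccades).
#'
#' @param gaze Gaze tibble; velocity is computed with [compute_velocity()].
#' @param lambda Threshold multiplier on the median-based SD.
#' @param min_dur_ms Minimum suprathreshold duration, ms.
#' @param merge_ms Events closer than this (onset-to-previous-offset) are
#'   merged by keeping the first, suppressing post-saccadic oscillations.
#' @param amplitude_threshold Validity threshold on endpoint displacement, dva.
#' @return Tibble of events: `onset_s`, `offset_s`, `peak_velocity`,
#'   `amplitude`, `valid`.
#' @export
detect_saccades <- function(gaze, lambda = 5, min_dur_ms = 15, merge_ms = 50,
                            amplitude_threshold = 15) {
  vel <- compute_velocity(gaze)
  if (all(is.na(vel$vx) | is.na(vel$vy))) {
    abort("input error: velocity trace is all-NA")
  }
  sx <- median_sd(vel$vx); sy <- median_sd(vel$vy)
  if (sx == 0 && sy == 0) {
    warn("constant gaze trace: zero velocity spread, no events detectable")
    return(empty_events())
  }
  # an axis with zero spread (perfectly still) drops out of the criterion
  tx <- if (sx > 0) (vel$vx / (lambda * sx))^2 else 0
  ty <- if (sy > 0) (vel$vy / (lambda * sy))^2 else 0
  crit <- tx + ty > 1
  crit[is.na(crit)] <- FALSE
  r <- rle(crit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- median(diff(gaze$time_s))
  min_len <- ceiling(min_dur_ms / 1000 / dt)
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) return(empty_events())
  ev <- tibble::tibble(i0 = starts[keep], i1 = ends[keep])
  ev <- merge_saccade_events(ev, dt, merge_ms)
  sp <- sqrt(vel$vx^2 + vel$vy^2)
  purrr::pmap_dfr(ev, function(i0, i1) {
    amp <- sqrt((gaze$x_dva[i1] - gaze$x_dva[i0])^2 +
                  (gaze$y_dva[i1] - gaze$y_dva[i0])^2)
    tibble::tibble(
      onset_s = gaze$time_s[i0], offset_s = gaze$time_s[i1],
      peak_velocity = max(sp[i0:i1], na.rm = TRUE),
      amplitude = amp, valid = amp > amplitude_threshold
    )
  })
}

empty_events <- function() {
  tibble::tibble(onset_s = numeric(), offset_s = numeric(),
                 peak_velocity = numeric(), amplitude = numeric(),
                 valid = logical())
}

# keep-the-first merge of events whose gap to the last kept event is < merge_ms
merge_saccade_events <- function(ev, dt, merge_ms) {
  if (nrow(ev) <= 1) return(ev)
  kept <- 1L
  last <- 1L
  for (i in 2:nrow(ev)) {
    gap_s <- (ev$i0[i] - ev$i1[last]) * dt
    if (gap_s >= merge_ms / 1000) {
      kept <- c(kept, i)
      last <- i
    }
  }
  ev[kept, ]
}

#' Apply the trial-exclusion rules
#'
#' Evaluates, in fixed order, the exclusion criteria for each trial and
#' reports a single (first-failing) reason: (1) gaze deviating more than
#' `deviation_dva` from the current fixation point while the stimulus is on
#' screen (on saccade trials this check ends at the detected saccade onset:
#' it targets fixation instability, not the commanded saccade's own flight);
#' for saccade trials additionally (2) the saccade landing more than
#' `deviation_dva` from the saccade target, (3) the eyes arriving before the
#' physical stimulus has been removed, and (4) the stimulus-to-saccade
#' latency falling outside `latency_range_ms` (the decoding inclusion
#' window). A saccade trial with no detected valid saccade after the cue is
#' reported under reason (4). Blink (`NaN`) gaze samples are ignored by rule
#' (1).
#'
#' @param schedule Session trial table.
#' @param gaze Gaze trace aligned to the schedule clock.
#' @param events Detected saccades from [detect_saccades()].
#' @param config The [session_config()] (geometry and timing).
#' @param deviation_dva Gaze-deviation / landing tolerance, dva.
#' @param latency_range_ms Decoding inclusion window for stimulus-to-saccade
#'   latency, ms.
#' @return Tibble: `trial_id`, `kept`, `reason` (one of `none`,
#'   `gaze_deviation`, `bad_landing`, `stimulus_visible_at_landing`,
#'   `saccade_latency_out_of_range`).
#' @export
exclude_trials <- function(schedule, gaze, events, config,
                           deviation_dva = 2.5,
                           latency_range_ms = c(100, 400)) {
  rate <- attr(gaze, "rate_hz")
  if (is.null(rate)) rate <- 1 / median(diff(gaze$time_s))
  n <- nrow(gaze)
  fx <- config$geometry$fixation_points
  valid_ev <- events[events$valid, , drop = FALSE]

  purrr::map_dfr(seq_len(nrow(schedule)), function(i) {
    tr <- schedule[i, ]
    is_sacc <- tr$base_type %in% c("saccade_central", "saccade_peripheral")
    sac <- NULL
    if (is_sacc) {
      cand <- valid_ev[valid_ev$onset_s > tr$cue_onset_s &
                         valid_ev$onset_s < tr$cue_onset_s + 1.5, , drop = FALSE]
      if (nrow(cand)) sac <- cand[1, ]
    }
    stim0 <- tr$stimulus_onset_s
    stim1 <- stim0 + tr$stimulus_duration_ms / 1000
    # the deviation rule targets fixation instability, not the commanded
    # saccade itself: on saccade trials the check stops at saccade onset
    dev1 <- if (is_sacc && !is.null(sac)) min(stim1, sac$onset_s) else stim1
    i0 <- round(stim0 * rate) + 1L
    i1 <- round(dev1 * rate) + 1L
    if (i0 < 1 || round(stim1 * rate) + 1L > n) {
      abort("input error: trial window outside gaze span")
    }
    fxy <- c(fx$x[fx$side == tr$fixation_side], fx$y[fx$side == tr$fixation_side])
    d <- sqrt((gaze$x_dva[i0:i1] - fxy[1])^2 + (gaze$y_dva[i0:i1] - fxy[2])^2)
    if (any(d > deviation_dva, na.rm = TRUE)) {
      return(tibble::tibble(trial_id = tr$trial_id, kept = FALSE,
                            reason = "gaze_deviation"))
    }
    if (is_sacc) {
      if (is.null(sac)) {
        return(tibble::tibble(trial_id = tr$trial_id, kept = FALSE,
                              reason = "saccade_latency_out_of_range"))
      }
      tgt_side <- other_side(tr$fixation_side)
      tgt <- c(fx$x[fx$side == tgt_side], fx$y[fx$side == tgt_side])
      li <- min(n, round(sac$offset_s * rate) + 1L)
      land <- c(gaze$x_dva[li], gaze$y_dva[li])
      if (sqrt(sum((land - tgt)^2)) > deviation_dva) {
        return(tibble::tibble(trial_id = tr$trial_id, kept = FALSE,
                              reason = "bad_landing"))
      }
      if (sac$offset_s < stim1) {
        return(tibble::tibble(trial_id = tr$trial_id, kept = FALSE,
                              reason = "stimulus_visible_at_landing"))
      }
      lat_ms <- (sac$onset_s - stim0) * 1000
      if (lat_ms < latency_range_ms[1] || lat_ms > latency_range_ms[2]) {
        return(tibble::tibble(trial_id = tr$trial_id, kept = FALSE,
                              reason = "saccade_latency_out_of_range"))
      }
    }
    tibble::tibble(trial_id = tr$trial_id, kept = TRUE, reason = "none")
  })
}

#' Summarize exclusion fractions per trial type and reason
#'
#' @param report Exclusion report from [exclude_trials()].
#' @param schedule The matching trial table.
#' @return Tibble with per-`base_type` totals, kept/excluded counts, the
#'   excluded fraction, and per-reason counts in long form.
#' @export
summarize_exclusions <- function(report, schedule) {
  joined <- dplyr::left_join(report,
                             schedule[, c("trial_id", "base_type")],
                             by = "trial_id")
  joined %>%
    group_by(.data$base_type, .data$reason) %>%
    summarise(n = dplyr::n(), .groups = "drop_last") %>%
    mutate(total = sum(.data$n),
           fraction = .data$n / .data$total) %>%
    ungroup()
}
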