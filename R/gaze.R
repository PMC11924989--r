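#' Generate a synthetic gaze trace for a session
#'
#' Produces a 1000 Hz (configurable) two-dimensional gaze trace covering the
#' whole session: fixational jitter (low-pass filtered white noise) around the
#' currently fixated point, Poisson-rate microsaccades (0.1-0.8 dva
#' there-and-back jerks), cued ~20 dva saccades executed as raised-cosine
#' displacements at each saccade trial's true onset, occasional blinks written
#' as `NaN` spans (placed in inter-trial gaps), and - if
#' `config$violation_fraction > 0` - planted fixation-excursion and
#' saccade-landing violations to exercise the trial-exclusion rules.
#'
#' @param schedule Trial table from [build_session_schedule()].
#' @param config The [session_config()] used to build it.
#'
#' @return A tibble (`time_s`, `x_dva`, `y_dva`, `blink`) with attributes
#'   `planted_violations` (tibble: trial_id, kind), `true_saccades` (tibble:
#'   trial_id, onset_s, target_x, target_y) and `microsaccade_times`.
#' @export
generate_gaze <- function(schedule, config) {
  if (!nrow(schedule)) abort("schedule must contain at least one trial")
  withr::with_seed(config$seed + 1L, generate_gaze_impl(schedule, config))
}

generate_gaze_impl <- function(schedule, config) {
  rate <- config$gaze_rate_hz
  span_s <- max(schedule$trial_id) * config$trial_slot_s + 1
  n <- ceiling(span_s * rate)
  t_s <- (seq_len(n) - 1) / rate
  fx <- config$geometry$fixation_points

  sacc <- schedule[!is.na(schedule$true_saccade_onset_s), ]
  if (nrow(sacc) &&
      any(diff(sort(sacc$true_saccade_onset_s)) < config$saccade_duration_ms / 1000)) {
    abort("scheduling error: overlapping saccade commands")
  }

  # planted violations
  planted <- tibble::tibble(trial_id = integer(), kind = character())
  if (config$violation_fraction > 0) {
    viol <- runif(nrow(schedule)) < config$violation_fraction
    planted <- tibble::tibble(
      trial_id = schedule$trial_id[viol],
      kind = ifelse(schedule$base_type[viol] == "saccade_peripheral",
                    "bad_landing", "gaze_deviation")
    )
  }

  # piecewise-constant fixation position with raised-cosine cued saccades
  x <- numeric(n); y <- numeric(n)
  cur <- c(fx$x[fx$side == "left"], 0)
  ptr <- 1L
  dur <- config$saccade_duration_ms / 1000
  true_sacc <- tibble::tibble(trial_id = integer(), onset_s = numeric(),
                              target_x = numeric(), target_y = numeric())
  if (nrow(sacc)) {
    sacc <- sacc[order(sacc$true_saccade_onset_s), ]
    for (i in seq_len(nrow(sacc))) {
      tgt_side <- other_side(sacc$fixation_side[i])
      tgt <- c(fx$x[fx$side == tgt_side], fx$y[fx$side == tgt_side])
      if (sacc$trial_id[i] %in% planted$trial_id[planted$kind == "bad_landing"]) {
        tgt <- tgt + c(0, 3.2) # land well off target
      }
      s0 <- round(sacc$true_saccade_onset_s[i] * rate) + 1L
      s1 <- min(n, s0 + round(dur * rate))
      if (s0 > ptr) { x[ptr:(s0 - 1L)] <- cur[1]; y[ptr:(s0 - 1L)] <- cur[2] }
      u <- (seq(s0, s1) - s0) / (s1 - s0)
      w <- (1 - cos(pi * u)) / 2
      x[s0:s1] <- cur[1] + (tgt[1] - cur[1]) * w
      y[s0:s1] <- cur[2] + (tgt[2] - cur[2]) * w
      true_sacc <- dplyr::bind_rows(true_sacc, tibble::tibble(
        trial_id = sacc$trial_id[i], onset_s = sacc$true_saccade_onset_s[i],
        target_x = tgt[1], target_y = tgt[2]))
      cur <- tgt
      ptr <- s1 + 1L
    }
  }
  if (ptr <= n) { x[ptr:n] <- cur[1]; y[ptr:n] <- cur[2] }

  # microsaccades: small there-and-back jerks during fixation
  ms_times <- numeric(0)
  if (config$microsaccade_rate_hz > 0) {
    n_ms <- rpois(1, config$microsaccade_rate_hz * span_s)
    if (n_ms > 0) {
      ms_times <- sort(runif(n_ms, 0.2, span_s - 0.5))
      # keep clear of cued saccades
      if (nrow(true_sacc)) {
        ok <- vapply(ms_times, function(tm) {
          all(abs(tm - true_sacc$onset_s) > 0.15)
        }, logical(1))
        ms_times <- ms_times[ok]
      }
      for (tm in ms_times) {
        amp <- runif(1, 0.1, 0.8)
        th <- runif(1, 0, 2 * pi)
        prof <- microsaccade_profile(rate)
        s0 <- round(tm * rate) + 1L
        idx <- s0 + seq_along(prof) - 1L
        keep <- idx <= n
        x[idx[keep]] <- x[idx[keep]] + amp * cos(th) * prof[keep]
        y[idx[keep]] <- y[idx[keep]] + amp * sin(th) * prof[keep]
      }
    }
  }

  # planted fixation-excursion violations: smooth 3.2 dva bump during stimulus
  gd <- planted$trial_id[planted$kind == "gaze_deviation"]
  for (tid in gd) {
    row <- schedule[schedule$trial_id == tid, ]
    s0 <- round(row$stimulus_onset_s * rate) + 1L
    len <- round(0.15 * rate)
    idx <- s0 + seq_len(len) - 1L
    keep <- idx <= n
    bump <- 3.2 * sin(pi * seq_len(len) / len)^2
    y[idx[keep]] <- y[idx[keep]] + bump[keep]
  }

  # fixational jitter: boxcar-smoothed white noise at the configured RMS
  if (config$gaze_jitter_sd_dva > 0) {
    k <- 25
    jx <- stats::filter(rnorm(n, 0, config$gaze_jitter_sd_dva * sqrt(k)),
                        rep(1 / k, k), sides = 2)
    jy <- stats::filter(rnorm(n, 0, config$gaze_jitter_sd_dva * sqrt(k)),
                        rep(1 / k, k), sides = 2)
    x <- x + ifelse(is.na(jx), 0, as.numeric(jx))
    y <- y + ifelse(is.na(jy), 0, as.numeric(jy))
  }

  # blinks: NaN spans in early-slot gaps (before the earliest stimulus time)
  blink <- rep(FALSE, n)
  if (config$blink_rate_hz > 0) {
    n_bl <- rpois(1, config$blink_rate_hz * span_s)
    if (n_bl > 0) {
      slots <- sample(unique(schedule$trial_id), min(n_bl, nrow(schedule)))
      for (tid in slots) {
        t0 <- (tid - 1) * config$trial_slot_s + runif(1, 0.02, 0.1)
        s0 <- round(t0 * rate) + 1L
        idx <- s0 + seq_len(round(0.15 * rate)) - 1L
        idx <- idx[idx <= n]
        blink[idx] <- TRUE
        x[idx] <- NaN; y[idx] <- NaN
      }
    }
  }

  out <- tibble::tibble(time_s = t_s, x_dva = x, y_dva = y, blink = blink)
  attr(out, "planted_violations") <- planted
  attr(out, "true_saccades") <- true_sacc
  attr(out, "microsaccade_times") <- ms_times
  attr(out, "rate_hz") <- rate
  out
}

# there-and-back displacement profile: 25 ms out, 50 ms hold, 25 ms back
microsaccade_profile <- function(rate) {
  go <- round(0.025 * rate); hold <- round(0.05 * rate)
  u <- seq_len(go) / go
  c((1 - cos(pi * u)) / 2, rep(1, hold), rev((1 - cos(pi * u)) / 2), 0)
}
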