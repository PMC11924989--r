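# Small shared fixtures, all generated in code.

tiny_config <- function(seed = 1L, ...) {
  session_config(n_blocks = 1, trials_per_block = 24,
                 n_fixation_per_block = 12, n_saccade_per_block = 8,
                 n_control_per_block = 4, seed = seed, ...)
}

# hand-built epoch set: `n` trials per class whose channel-1/2 means separate
# the classes from `onset_ms` onward by `gap` (noise sd 1 elsewhere)
separable_epochs <- function(n = 20, gap = 4, onset_ms = 100, seed = 1) {
  withr::with_seed(seed, {
    t_ms <- epoch_times_ms()
    nt <- length(t_ms)
    data <- array(rnorm(2 * n * 64 * nt), dim = c(2 * n, 64, nt))
    shift <- outer(rep(c(1, -1), each = n), (t_ms >= onset_ms) * gap / 2)
    data[, 1, ] <- data[, 1, ] + shift
    data[, 2, ] <- data[, 2, ] - shift
    meta <- tibble::tibble(
      trial_id = seq_len(2 * n), block = 1L, trial_type = "fixation",
      base_type = "fixation", is_catch = FALSE, fixation_side = "left",
      location_id = 1L, sf_class = rep(c("high", "low"), each = n),
      stimulus_onset_s = seq_len(2 * n) * 1.6, stimulus_duration_ms = 100,
      cue_onset_s = NA_real_, true_saccade_onset_s = NA_real_,
      stim_to_saccade_ms = NA_real_
    )
    new_epoch_set(data, meta, "SYN")
  })
}

# flat gaze trace at a fixation point with optional injected saccades
flat_gaze <- function(dur_s = 10, rate = 1000, x0 = -10.04, y0 = 0,
                      jitter_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    n <- dur_s * rate
    x <- rep(x0, n); y <- rep(y0, n)
    if (jitter_sd > 0) {
      k <- 25
      jx <- stats::filter(rnorm(n, 0, jitter_sd * sqrt(k)), rep(1 / k, k), sides = 2)
      jy <- stats::filter(rnorm(n, 0, jitter_sd * sqrt(k)), rep(1 / k, k), sides = 2)
      x <- x + ifelse(is.na(jx), 0, jx)
      y <- y + ifelse(is.na(jy), 0, jy)
    }
    out <- tibble::tibble(time_s = (seq_len(n) - 1) / rate, x_dva = x,
                          y_dva = y, blink = FALSE)
    attr(out, "rate_hz") <- rate
    out
  })
}

# add a raised-cosine displacement of `amp` dva starting at `onset_s`
inject_saccade <- function(gaze, onset_s, amp, dur_s = 0.025, angle = 0) {
  rate <- attr(gaze, "rate_hz")
  i0 <- round(onset_s * rate) + 1L
  len <- round(dur_s * rate)
  prof <- (1 - cos(pi * seq_len(len) / len)) / 2
  idx <- i0 + seq_len(len) - 1L
  gaze$x_dva[idx] <- gaze$x_dva[idx] + amp * cos(angle) * prof
  gaze$y_dva[idx] <- gaze$y_dva[idx] + amp * sin(angle) * prof
  later <- seq(max(idx) + 1L, nrow(gaze))
  gaze$x_dva[later] <- gaze$x_dva[later] + amp * cos(angle)
  gaze$y_dva[later] <- gaze$y_dva[later] + amp * sin(angle)
  gaze
}

# subject-level decode series with a step from 0.5 to `post` at `onset_ms`
synthetic_series <- function(n_subjects = 10, onset_ms = 145, post = 0.9,
                             noise_sd = 0.03, seed = 1) {
  withr::with_seed(seed, {
    t_ms <- epoch_times_ms()
    purrr::map_dfr(seq_len(n_subjects), function(i) {
      acc <- ifelse(t_ms >= onset_ms, post, 0.5) + rnorm(length(t_ms), 0, noise_sd)
      tibble::tibble(subject = sprintf("S%02d", i), time_ms = t_ms,
                     accuracy = pmin(1, pmax(0, acc)))
    })
  })
}
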