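#' Generate continuous synthetic EEG for a session
#'
#' Renders a 64-channel continuous recording at `config$eeg_rate_hz`:
#' spatially mixed autoregressive background noise, the class-signed
#' discriminative components defined by the ground truth (time-locked to each
#' non-catch trial's stimulus onset; sustained 500 ms, then a 50 ms
#' raised-cosine offset), an optional frontal ocular artifact locked to cued
#' saccade onsets, and an event marker for every trial's stimulus onset
#' (catch trials included). The two mastoid channels carry noise only.
#'
#' @param schedule Trial table from [build_session_schedule()].
#' @param gaze Gaze trace from [generate_gaze()] (defines the session span).
#' @param truth A [make_ground_truth()] (or [subject_truth()]) object.
#' @param config The [session_config()].
#' @param subject_id Label stored with the recording.
#'
#' @return An object of class `continuous_recording`: list with `eeg`
#'   (64 x samples matrix, microvolts), `rate_hz`, `events` (tibble:
#'   sample_index, event_code, trial_id), `channel_names`, `subject_id`.
#' @export
generate_eeg <- function(schedule, gaze, truth, config, subject_id = "S01") {
  stopifnot(inherits(truth, "ground_truth"))
  check_truth_covers(truth, schedule)
  withr::with_seed(config$seed + 2L, {
    rate <- config$eeg_rate_hz
    span_s <- max(gaze$time_s) + 1 / attr(gaze, "rate_hz")
    n <- ceiling(span_s * rate)
    eeg <- noise_matrix(64, n, config$noise_sd_uv, phi = 0.97,
                        mix = config$noise_spatial_mix)

    t_rel <- seq(0, 0.55, by = 1 / rate) # signal support after stimulus onset
    # sustained to the epoch end (500 ms), then a 50 ms raised-cosine offset
    fall <- 1 - signal_envelope(t_rel * 1000, 500, 50)
    for (i in seq_len(nrow(schedule))) {
      tr <- schedule[i, ]
      if (tr$is_catch) next
      comp <- trial_components(truth, tr)
      if (!nrow(comp)) next
      env <- vapply(seq_len(nrow(comp)), function(j) {
        signal_envelope(t_rel * 1000, comp$onset_ms[j], truth$rise_ms) * fall
      }, numeric(length(t_rel)))
      sgn <- if (tr$sf_class == "high") 1 else -1
      sig <- truth$topographies[, comp$train_location, drop = FALSE] %*%
        (sgn * t(env) * comp$amplitude)
      s0 <- round(tr$stimulus_onset_s * rate) + 1L
      idx <- s0 + seq_along(t_rel) - 1L
      keep <- idx <= n
      eeg[, idx[keep]] <- eeg[, idx[keep]] + sig[, keep, drop = FALSE]
    }

    if (config$ocular_artifact_uv > 0) {
      ts <- attr(gaze, "true_saccades")
      if (!is.null(ts) && nrow(ts)) {
        art_t <- seq(-0.005, 0.02, by = 1 / rate)
        art <- config$ocular_artifact_uv * sin(pi * seq_along(art_t) / length(art_t))^2
        for (on in ts$onset_s) {
          s0 <- round((on - 0.005) * rate) + 1L
          idx <- s0 + seq_along(art_t) - 1L
          keep <- idx >= 1 & idx <= n
          eeg[1:4, idx[keep]] <- eeg[1:4, idx[keep]] +
            matrix(art[keep], 4, sum(keep), byrow = TRUE)
        }
      }
    }

    events <- tibble::tibble(
      sample_index = round(schedule$stimulus_onset_s * rate) + 1L,
      event_code = match(schedule$base_type,
                         c("fixation", "saccade_central", "saccade_peripheral",
                           "control")),
      trial_id = schedule$trial_id
    )
    rownames(eeg) <- truth$channel_names
    structure(
      list(eeg = eeg, rate_hz = rate, events = events,
           channel_names = truth$channel_names, subject_id = subject_id),
      class = "continuous_recording"
    )
  })
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz, %d events (%s)\n",
              nrow(x$eeg), ncol(x$eeg), x$rate_hz, nrow(x$events), x$subject_id))
  invisible(x)
}

# component rows applying to one trial (by type and stimulus location)
trial_components <- function(truth, trial) {
  ty <- trial$base_type
  if (ty == "saccade_central") {
    # unanalysed trials: local stimulus response only
    return(dplyr::filter(truth$components,
                         .data$trial_type == "saccade_central",
                         .data$test_location == trial$location_id))
  }
  dplyr::filter(truth$components, .data$trial_type == ty,
                .data$test_location == trial$location_id)
}

check_truth_covers <- function(truth, schedule) {
  need <- unique(schedule$base_type[!schedule$is_catch])
  have <- unique(c(truth$components$trial_type, "fixation"))
  miss <- setdiff(need, have)
  if (length(miss)) {
    abort(paste0("configuration error: ground truth lacks components for trial type(s): ",
                 paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

# spatially mixed AR(1) noise; returns channels x samples at per-channel SD `sd`
noise_matrix <- function(n_chan, n_samp, sd, phi, mix) {
  # one long AR chain reshaped into channels: the correlation bleed at the
  # n_chan segment boundaries is a single sample and statistically irrelevant
  z <- rnorm(n_chan * n_samp)
  if (phi > 0) {
    z <- as.numeric(stats::filter(z, phi, "recursive")) * sqrt(1 - phi^2)
  }
  z <- t(matrix(z, n_samp, n_chan))
  if (mix > 0) {
    w <- qr.Q(qr(matrix(rnorm(n_chan^2), n_chan, n_chan)))
    a <- diag(n_chan) + mix * w
    a <- a / sqrt(rowSums(a^2))
    (a %*% z) * sd
  } else {
    z * sd
  }
}

#' Simulate baseline-corrected epochs directly
#'
#' Fast path for cohort-scale simulation: draws the trials' epochs on the
#' canonical 256 Hz, -200..+500 ms grid without rendering the continuous
#' recording, using the same ground-truth component injection as
#' [generate_eeg()] and the same baseline convention as
#' [epoch_and_baseline()] (mean of -100..0 ms subtracted per trial and
#' channel). Catch trials are dropped. Statistically this matches the full
#' continuous path after preprocessing, except that it bypasses the filtering
#' steps (the embedded signal lies inside the 0.1-80 Hz passband, so those
#' are close to identity on it).
#'
#' @param schedule Trial table from [build_session_schedule()].
#' @param truth A [make_ground_truth()] / [subject_truth()] object.
#' @param config A [session_config()] (noise parameters are taken from it).
#' @param subject_id Subject label.
#' @param seed Seed for the noise draw; defaults to `config$seed + 2`.
#' @return An `epoch_set`, see [epoch_and_baseline()].
#' @export
simulate_epochs <- function(schedule, truth, config, subject_id = "S01",
                            seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  check_truth_covers(truth, schedule)
  if (is.null(seed)) seed <- config$seed + 2L
  meta <- schedule[!schedule$is_catch, ]
  n <- nrow(meta)
  t_ms <- epoch_times_ms()
  nt <- length(t_ms)
  withr::with_seed(seed, {
    noise <- noise_matrix(64, n * nt, config$noise_sd_uv, phi = config$noise_ar,
                          mix = config$noise_spatial_mix)
    # noise columns run trial-major: reshape to trials x channels x timepoints
    data <- aperm(array(noise, dim = c(64, nt, n)), c(3, 1, 2))
    sgn <- ifelse(meta$sf_class == "high", 1, -1)
    # the injected signal is identical (up to class sign) for every trial of
    # a (trial type, location) cell, so render each cell's 64 x T template once
    cells <- dplyr::distinct(meta[, c("base_type", "location_id")])
    for (ci in seq_len(nrow(cells))) {
      comp <- trial_components(truth, cells[ci, ])
      if (!nrow(comp)) next
      env <- vapply(seq_len(nrow(comp)), function(j) {
        signal_envelope(t_ms, comp$onset_ms[j], truth$rise_ms)
      }, numeric(nt))
      template <- truth$topographies[, comp$train_location, drop = FALSE] %*%
        (comp$amplitude * t(env)) # 64 x T
      idx <- which(meta$base_type == cells$base_type[ci] &
                     meta$location_id == cells$location_id[ci])
      data[idx, , ] <- data[idx, , , drop = FALSE] +
        outer(sgn[idx], template)
    }
    new_epoch_set(baseline_correct(data, t_ms), meta, subject_id)
  })
}
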