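#' Balanced reduced-scale trial design for cohort simulations
#'
#' Builds the trial table of one synthetic subject for cohort-scale recovery
#' studies: for each fixation side, a training cell (fixation trials at one
#' parafoveal location), cross-test fixation trials at the remaining
#' parafoveal locations, control trials at every opposite-side location, and
#' peripheral-saccade trials at the training location's congruent partner
#' with latencies drawn from the truncated-normal latency distribution.
#' Exactly balanced across spatial-frequency classes; no catch trials. This
#' is the desk-scale counterpart of a full session (a few hundred rather
#' than 2,400 trials), keeping every decoding condition populated.
#'
#' @param n_train_per_class Fixation trials per SF class at each training
#'   location.
#' @param n_test_per_class Trials per SF class at each cross-test (fixation
#'   and control) location.
#' @param n_saccade_per_class Peripheral-saccade trials per SF class at the
#'   congruent location.
#' @param train_locations Named vector: training location per side.
#' @param sides Fixation sides simulated.
#' @param latency_mean_ms,latency_sd_ms,latency_range_ms Stimulus-to-saccade
#'   latency distribution.
#' @param include_incongruent Also generate peripheral-saccade trials at the
#'   incongruent location?
#' @param seed Seed for the latency draws.
#' @return A schedule-like tibble accepted by [simulate_epochs()].
#' @export
cohort_design <- function(n_train_per_class = 30, n_test_per_class = 10,
                          n_saccade_per_class = 12,
                          train_locations = c(left = 1L, right = 5L),
                          sides = c("left", "right"),
                          latency_mean_ms = 200, latency_sd_ms = 60,
                          latency_range_ms = c(100, 400),
                          include_incongruent = TRUE, seed = 1L) {
  rows <- list()
  add <- function(type, side, loc, n_per_class) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      base_type = type, fixation_side = side, location_id = loc,
      sf_class = rep(c("low", "high"), each = n_per_class)
    )
  }
  for (s in sides) {
    ktr <- unname(train_locations[s])
    add("fixation", s, ktr, n_train_per_class)
    for (L in setdiff(parafoveal_locations(s), ktr)) {
      add("fixation", s, L, n_test_per_class)
    }
    for (L in parafoveal_locations(other_side(s))) {
      add("control", s, L, n_test_per_class)
    }
    add("saccade_peripheral", s, congruent_location(ktr), n_saccade_per_class)
    if (include_incongruent) {
      add("saccade_peripheral", s, incongruent_location(ktr), n_saccade_per_class)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$trial_id <- seq_len(nrow(out))
  out$block <- 1L
  out$trial_type <- out$base_type
  out$is_catch <- FALSE
  out$stimulus_onset_s <- out$trial_id * 1.6
  out$stimulus_duration_ms <- 100
  out$cue_onset_s <- NA_real_
  out$true_saccade_onset_s <- NA_real_
  out$stim_to_saccade_ms <- NA_real_
  is_sacc <- out$base_type == "saccade_peripheral"
  out$stim_to_saccade_ms[is_sacc] <- withr::with_seed(seed, {
    rtruncnorm(sum(is_sacc), latency_mean_ms, latency_sd_ms,
               latency_range_ms[1], latency_range_ms[2])
  })
  out$true_saccade_onset_s[is_sacc] <- out$stimulus_onset_s[is_sacc] +
    out$stim_to_saccade_ms[is_sacc] / 1000
  out$cue_onset_s[is_sacc] <- out$stimulus_onset_s[is_sacc] - 0.2
  out[, c("trial_id", "block", "trial_type", "base_type", "is_catch",
          "fixation_side", "location_id", "sf_class", "stimulus_onset_s",
          "stimulus_duration_ms", "cue_onset_s", "true_saccade_onset_s",
          "stim_to_saccade_ms")]
}

#' Simulate and decode a multi-subject synthetic cohort
#'
#' Runs the reduced-scale recovery experiment end to end: for each subject,
#' draws a subject-specific ground truth ([subject_truth()]), simulates
#' epochs ([simulate_epochs()]), and runs the requested decoding schemes
#' ([decode_subject()]); then computes group-level Bayes-factor time courses
#' and onsets per condition and joins them with the embedded ground-truth
#' onsets into a recovery report.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param truth Cohort-level [make_ground_truth()].
#' @param config A [session_config()] supplying the noise model.
#' @param design_args List of arguments for [cohort_design()].
#' @param schemes Decoding schemes to run (see [decode_subject()]).
#' @param train_locations Training location per side (named vector).
#' @param seed Master seed; every subject-level draw derives from it.
#' @param onset_window Onset search window in ms.
#' @param direction Onset direction constraint (see [detect_onset()]);
#'   cohort recovery asks when decoding rises above chance, so the default
#'   requires above-null evidence.
#' @return A `cohort_result`: list with `series` (subject-level decode
#'   series), `bf` (per-condition `bf_series`), `onsets` (tibble: condition,
#'   onset_ms, embedded_ms, error_ms), `n_subjects`, `seed`.
#' @export
run_cohort <- function(n_subjects = 10, truth = make_ground_truth(),
                       config = session_config(),
                       design_args = list(),
                       schemes = c("fixation-cross", "saccade-congruency"),
                       train_locations = c(left = 1L, right = 5L),
                       seed = 1L, onset_window = c(0, 500),
                       direction = "above") {
  series <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    sseed <- seed * 1009L + i
    struth <- subject_truth(truth, subject_seed = sseed)
    sched <- do.call(cohort_design, utils::modifyList(
      list(train_locations = train_locations, seed = sseed + 7L), design_args))
    epochs <- simulate_epochs(sched, struth, config,
                              subject_id = sprintf("S%02d", i),
                              seed = sseed + 13L)
    decode_subject(epochs, schemes, train_locations = unname(train_locations),
                   seed = sseed + 29L)
  })

  conds <- dplyr::distinct(series, .data$scheme, .data$condition)
  keys <- paste(conds$scheme, conds$condition, sep = ":")
  bf <- purrr::map(seq_len(nrow(conds)), function(i) {
    bf_timecourse(series[series$scheme == conds$scheme[i] &
                           series$condition == conds$condition[i], ],
                  null_value = 0.5)
  })
  names(bf) <- keys
  onsets <- purrr::map_dfr(seq_len(nrow(conds)), function(i) {
    tibble::tibble(scheme = conds$scheme[i], condition = conds$condition[i],
                   onset_ms = detect_onset(bf[[i]], window = onset_window,
                                           direction = direction))
  })
  onsets$embedded_ms <- embedded_onset(onsets$condition, truth, train_locations)
  onsets$error_ms <- onsets$onset_ms - onsets$embedded_ms

  structure(list(series = series, bf = bf, onsets = onsets,
                 n_subjects = n_subjects, seed = seed,
                 truth = truth, train_locations = train_locations),
            class = "cohort_result")
}

# embedded (generator) onset for a recovered condition label
embedded_onset <- function(condition, truth, train_locations) {
  o <- truth$onsets_ms
  vapply(condition, function(cn) {
    if (cn %in% names(o)) return(unname(o[cn]))
    if (cn %in% c("congruent", "incongruent")) return(unname(o["saccade"]))
    if (cn == "control") {
      rows <- dplyr::filter(truth$components, .data$trial_type == "control",
                            .data$train_location %in% unname(train_locations),
                            .data$test_location ==
                              congruent_location(.data$train_location))
      return(mean(rows$onset_ms))
    }
    NA_real_
  }, numeric(1))
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects, seed %d\n", x$n_subjects, x$seed))
  print(x$onsets)
  invisible(x)
}

#' @export
tidy.cohort_result <- function(x, ...) x$onsets

#' @export
glance.cohort_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_conditions = nrow(x$onsets),
    n_detected = sum(!is.na(x$onsets$onset_ms)),
    median_abs_error_ms = median(abs(x$onsets$error_ms), na.rm = TRUE)
  )
}

#' @export
tidy.onset_estimate <- function(x, ...) tibble::as_tibble(unclass(x))

#' Run the full synthetic pipeline for one subject
#'
#' Exercises every stage on the continuous path: schedule, gaze trace,
#' continuous EEG, saccade detection, trial exclusion, standardization
#' (resample + mastoid re-reference), band-pass/notch filtering, epoching
#' with baseline correction, and (optionally) decoding. Intended for
#' moderate session sizes; cohort-scale recovery uses [run_cohort()].
#'
#' @param config A [session_config()].
#' @param truth Ground truth; defaults to [make_ground_truth()].
#' @param subject_id Subject label.
#' @param decode Run the fixation-cross decoding scheme on the result?
#' @return List with `schedule`, `gaze`, `events`, `exclusions`,
#'   `exclusion_summary`, `epochs`, `series` (or `NULL`), and `manifest`
#'   (stage-by-stage counts and checksums; identical configs and seeds give
#'   identical manifests).
#' @export
run_session <- function(config, truth = make_ground_truth(),
                        subject_id = "S01", decode = FALSE) {
  schedule <- build_session_schedule(config, require_decodable = decode)
  gaze <- generate_gaze(schedule, config)
  rec <- generate_eeg(schedule, gaze, truth, config, subject_id = subject_id)
  events <- detect_saccades(gaze)
  excl <- exclude_trials(schedule, gaze, events, config)
  rec <- standardize_record(rec)
  rec <- filter_eeg(rec)
  epochs <- epoch_and_baseline(rec, schedule, keep = excl)
  series <- if (decode) decode_subject(epochs, "fixation-cross") else NULL
  manifest <- list(
    seed = config$seed,
    n_trials = nrow(schedule),
    n_catch = sum(schedule$is_catch),
    n_saccades_detected = nrow(events),
    n_excluded = sum(!excl$kept),
    n_epochs = dim(epochs$data)[1],
    checksum_gaze = round(sum(gaze$x_dva[!is.nan(gaze$x_dva)]), 6),
    checksum_eeg = round(sum(rec$eeg), 4)
  )
  list(schedule = schedule, gaze = gaze, events = events, exclusions = excl,
       exclusion_summary = summarize_exclusions(excl, schedule),
       epochs = epochs, series = series, manifest = manifest)
}
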