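#' Build a randomized session schedule
#'
#' Lays out every trial of a synthetic session: per-block counts follow the
#' configuration exactly, trial types are randomly interleaved under the
#' configured seed, saccade trials are split evenly between central and
#' peripheral variants, and a catch (oddball) trial is overlaid on a scheduled
#' trial every `catch_interval` trials. The fixated side starts left and flips
#' after every saccade trial; fixation and central-saccade stimuli appear at
#' the four locations around current fixation, control and peripheral-saccade
#' stimuli at the four locations around the opposite fixation point. Within
#' each (trial type, location) cell the two spatial-frequency classes are
#' balanced to within one trial. Peripheral and central saccade trials draw
#' their stimulus-to-saccade latency from a truncated normal distribution
#' (defaults: mean 200 ms, sd 60 ms, truncated to 100-400 ms).
#'
#' @param config A [session_config()].
#' @param require_decodable If `TRUE`, error when any populated fixation
#'   (location, SF) cell ends up with fewer than two trials (too few to train
#'   and cross-validate a classifier). Off by default so that degenerate
#'   miniature sessions can be built.
#'
#' @return A tibble with one row per trial: `trial_id`, `block`, `trial_type`
#'   (`"catch"` for overlaid catch trials), `base_type` (the underlying
#'   scheduled type), `is_catch`, `fixation_side`, `location_id`, `sf_class`,
#'   `stimulus_onset_s`, `stimulus_duration_ms`, `cue_onset_s`,
#'   `true_saccade_onset_s`, `stim_to_saccade_ms`.
#' @export
#' @examples
#' cfg <- session_config(n_blocks = 1, trials_per_block = 24,
#'                       n_fixation_per_block = 12, n_saccade_per_block = 8,
#'                       n_control_per_block = 4)
#' build_session_schedule(cfg)
build_session_schedule <- function(config, require_decodable = FALSE) {
  stopifnot(inherits(config, "session_config"))
  withr::with_seed(config$seed, build_schedule_impl(config, require_decodable))
}

build_schedule_impl <- function(config, require_decodable) {
  n_sacc_central <- config$n_saccade_per_block %/% 2
  n_sacc_periph <- config$n_saccade_per_block - n_sacc_central

  blocks <- purrr::map(seq_len(config$n_blocks), function(b) {
    types <- c(
      rep("fixation", config$n_fixation_per_block),
      rep("saccade_central", n_sacc_central),
      rep("saccade_peripheral", n_sacc_periph),
      rep("control", config$n_control_per_block)
    )
    tibble::tibble(block = b, base_type = sample(types))
  })
  sched <- dplyr::bind_rows(blocks)
  n <- nrow(sched)
  sched$trial_id <- seq_len(n)

  # catch overlay every catch_interval[1]..catch_interval[2] trials
  is_catch <- rep(FALSE, n)
  pos <- 0
  repeat {
    pos <- pos + sample(seq(config$catch_interval[1], config$catch_interval[2]), 1)
    if (pos > n) break
    is_catch[pos] <- TRUE
  }
  sched$is_catch <- is_catch

  # fixation side tracking: flips after every saccade trial
  is_sacc <- sched$base_type %in% c("saccade_central", "saccade_peripheral")
  n_sacc_before <- cumsum(is_sacc) - as.integer(is_sacc)
  sched$fixation_side <- ifelse(n_sacc_before %% 2 == 0, "left", "right")

  # balanced (location, sf) queues per (base type, side)
  stim_side <- ifelse(sched$base_type %in% c("control", "saccade_peripheral"),
                      other_side(sched$fixation_side), sched$fixation_side)
  sched$location_id <- NA_integer_
  sched$sf_class <- NA_character_
  for (ty in unique(sched$base_type)) {
    for (s in c("left", "right")) {
      idx <- which(sched$base_type == ty & stim_side == s)
      if (!length(idx)) next
      cells <- expand.grid(location_id = parafoveal_locations(s),
                           sf_class = c("low", "high"),
                           stringsAsFactors = FALSE)
      k <- ceiling(length(idx) / nrow(cells))
      queue <- do.call(rbind, purrr::map(seq_len(k), function(i) {
        cells[sample.int(nrow(cells)), ]
      }))
      sched$location_id[idx] <- queue$location_id[seq_along(idx)]
      sched$sf_class[idx] <- queue$sf_class[seq_along(idx)]
    }
  }

  # timing within sequential trial slots
  slot <- (sched$trial_id - 1) * config$trial_slot_s
  lat_ms <- rep(NA_real_, n)
  lat_ms[is_sacc] <- rtruncnorm(sum(is_sacc),
                                config$saccade_latency_mean_ms,
                                config$saccade_latency_sd_ms,
                                config$saccade_latency_range_ms[1],
                                config$saccade_latency_range_ms[2])
  sacc_onset <- rep(NA_real_, n)
  sacc_onset[is_sacc] <- slot[is_sacc] + 0.85 + runif(sum(is_sacc), 0, 0.05)
  cue <- rep(NA_real_, n)
  cue[is_sacc] <- slot[is_sacc] + 0.30
  stim <- slot + runif(n, 0.4, 0.8)
  stim[is_sacc] <- sacc_onset[is_sacc] - lat_ms[is_sacc] / 1000

  sched$stimulus_onset_s <- stim
  sched$stimulus_duration_ms <- config$stimulus_duration_ms
  sched$cue_onset_s <- cue
  sched$true_saccade_onset_s <- sacc_onset
  sched$stim_to_saccade_ms <- lat_ms
  sched$trial_type <- ifelse(sched$is_catch, "catch", sched$base_type)

  sched <- sched[, c("trial_id", "block", "trial_type", "base_type", "is_catch",
                     "fixation_side", "location_id", "sf_class",
                     "stimulus_onset_s", "stimulus_duration_ms", "cue_onset_s",
                     "true_saccade_onset_s", "stim_to_saccade_ms")]
  sched <- tibble::as_tibble(sched)

  if (require_decodable) {
    cell_n <- sched %>%
      filter(.data$base_type == "fixation", !.data$is_catch) %>%
      count(.data$location_id, .data$sf_class)
    if (nrow(cell_n) && any(cell_n$n < 2)) {
      abort("infeasibility error: fewer than 2 fixation trials in a populated (location, SF) cell")
    }
  }
  sched
}
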