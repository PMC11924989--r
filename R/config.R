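#' Session configuration for the synthetic generator
#'
#' Bundles the experimental design parameters (block and trial counts,
#' stimulus geometry, spatial-frequency classes, sampling rates) together with
#' the generator's nuisance parameters (gaze jitter, microsaccade and blink
#' rates, saccade kinematics, planted-violation fractions, EEG noise model).
#' Defaults reproduce the study design: five blocks of 480 trials
#' (224 fixation + 224 saccade + 32 control), gratings of 0.33 or 1 cycles/dva
#' shown for 100 ms, catch trials every 11-20 trials, cued ~20 dva saccades
#' with stimulus-to-saccade latencies drawn from a truncated normal
#' (mean 200 ms, sd 60 ms) on [100, 400] ms.
#'
#' @param n_blocks Number of blocks per session.
#' @param trials_per_block Trials per block (must equal the sum of the three
#'   per-type counts).
#' @param n_fixation_per_block,n_saccade_per_block,n_control_per_block
#'   Per-block allocation of fixation, saccade (split evenly between central
#'   and peripheral) and control trials.
#' @param catch_interval Integer range; a catch (oddball-orientation) trial is
#'   overlaid on a scheduled trial every `catch_interval[1]` to
#'   `catch_interval[2]` trials.
#' @param geometry Stimulus geometry, see [default_geometry()].
#' @param sf_classes The two spatial frequencies, cycles per dva.
#' @param stimulus_duration_ms Stimulus duration in ms.
#' @param eeg_rate_hz Sampling rate of the generated continuous EEG.
#' @param gaze_rate_hz Sampling rate of the generated gaze trace.
#' @param seed Integer seed governing every random draw of the generator.
#' @param trial_slot_s Duration of one trial slot in the session timeline, s.
#' @param saccade_latency_mean_ms,saccade_latency_sd_ms Parameters of the
#'   truncated-normal stimulus-to-saccade latency distribution.
#' @param saccade_latency_range_ms Truncation bounds of that distribution, ms.
#' @param saccade_duration_ms Duration of the cued saccade's raised-cosine
#'   displacement profile, ms.
#' @param gaze_jitter_sd_dva RMS amplitude of fixational gaze jitter, dva. The
#'   jitter is low-pass (25 ms boxcar) filtered white noise, so its velocity
#'   content stays well below the saccade detection threshold.
#' @param microsaccade_rate_hz Poisson rate of fixational microsaccades
#'   (0.1-0.8 dva, 25 ms).
#' @param blink_rate_hz Poisson rate of blinks, written as NaN spans into the
#'   gaze trace (placed between trials so they do not interact with the
#'   exclusion rules).
#' @param violation_fraction Fraction of trials planted with a gaze violation
#'   (fixation excursion > 2.5 dva during the stimulus, or a saccade landing
#'   > 2.5 dva off target) to exercise the exclusion rules.
#' @param noise_sd_uv Per-channel standard deviation of the EEG background
#'   noise, microvolts.
#' @param noise_ar Lag-one autoregressive coefficient of the temporal noise
#'   correlation.
#' @param noise_spatial_mix Strength of random spatial mixing across channels
#'   (0 = independent channels).
#' @param ocular_artifact_uv Amplitude of the saccade-locked ocular artifact
#'   added to frontal channels of the continuous EEG (0 disables it).
#'
#' @return An object of class `session_config` (a validated list).
#' @export
#' @examples
#' cfg <- session_config(n_blocks = 1, trials_per_block = 24,
#'                       n_fixation_per_block = 12, n_saccade_per_block = 8,
#'                       n_control_per_block = 4)
session_config <- function(n_blocks = 5,
                           trials_per_block = 480,
                           n_fixation_per_block = 224,
                           n_saccade_per_block = 224,
                           n_control_per_block = 32,
                           catch_interval = c(11L, 20L),
                           geometry = default_geometry(),
                           sf_classes = c(low = 0.33, high = 1),
                           stimulus_duration_ms = 100,
                           eeg_rate_hz = 512,
                           gaze_rate_hz = 1000,
                           seed = 1L,
                           trial_slot_s = 1.6,
                           saccade_latency_mean_ms = 200,
                           saccade_latency_sd_ms = 60,
                           saccade_latency_range_ms = c(100, 400),
                           saccade_duration_ms = 50,
                           gaze_jitter_sd_dva = 0.02,
                           microsaccade_rate_hz = 0.5,
                           blink_rate_hz = 0.05,
                           violation_fraction = 0,
                           noise_sd_uv = 1,
                           noise_ar = 0.4,
                           noise_spatial_mix = 0.5,
                           ocular_artifact_uv = 0) {
  cfg <- list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    n_fixation_per_block = as.integer(n_fixation_per_block),
    n_saccade_per_block = as.integer(n_saccade_per_block),
    n_control_per_block = as.integer(n_control_per_block),
    catch_interval = as.integer(catch_interval),
    geometry = geometry,
    sf_classes = sf_classes,
    stimulus_duration_ms = stimulus_duration_ms,
    eeg_rate_hz = eeg_rate_hz,
    gaze_rate_hz = gaze_rate_hz,
    seed = as.integer(seed),
    trial_slot_s = trial_slot_s,
    saccade_latency_mean_ms = saccade_latency_mean_ms,
    saccade_latency_sd_ms = saccade_latency_sd_ms,
    saccade_latency_range_ms = saccade_latency_range_ms,
    saccade_duration_ms = saccade_duration_ms,
    gaze_jitter_sd_dva = gaze_jitter_sd_dva,
    microsaccade_rate_hz = microsaccade_rate_hz,
    blink_rate_hz = blink_rate_hz,
    violation_fraction = violation_fraction,
    noise_sd_uv = noise_sd_uv,
    noise_ar = noise_ar,
    noise_spatial_mix = noise_spatial_mix,
    ocular_artifact_uv = ocular_artifact_uv
  )
  class(cfg) <- "session_config"
  validate_session_config(cfg)
}

validate_session_config <- function(cfg) {
  with(cfg, {
    if (n_fixation_per_block + n_saccade_per_block + n_control_per_block !=
        trials_per_block) {
      abort(paste0(
        "configuration error: per-block counts (",
        n_fixation_per_block, " + ", n_saccade_per_block, " + ",
        n_control_per_block, ") do not sum to trials_per_block (",
        trials_per_block, ")"
      ))
    }
    if (length(catch_interval) != 2 || catch_interval[1] > catch_interval[2] ||
        catch_interval[1] < 1) {
      abort("configuration error: catch_interval must be an increasing pair of positive integers")
    }
    if (length(sf_classes) != 2 || any(sf_classes <= 0) ||
        sf_classes[1] == sf_classes[2]) {
      abort("configuration error: sf_classes must be two distinct positive values")
    }
  })
  locs <- cfg$geometry$locations
  fx <- cfg$geometry$fixation_points
  if (nrow(locs) != 8) abort("configuration error: geometry must define exactly 8 locations")
  d <- outer(seq_len(nrow(locs)), seq_len(nrow(fx)), function(i, j) {
    sqrt((locs$x[i] - fx$x[j])^2 + (locs$y[i] - fx$y[j])^2)
  })
  if (any(rowSums(d < 6) != 1)) {
    abort("configuration error: each location must lie within 6 dva of exactly one fixation point")
  }
  cfg
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  cat(sprintf("  %d block(s) x %d trials (%d fixation + %d saccade + %d control)\n",
              x$n_blocks, x$trials_per_block, x$n_fixation_per_block,
              x$n_saccade_per_block, x$n_control_per_block))
  cat(sprintf("  SF classes: %s c/dva; stimulus %g ms; EEG %g Hz; gaze %g Hz; seed %d\n",
              paste(x$sf_classes, collapse = " / "), x$stimulus_duration_ms,
              x$eeg_rate_hz, x$gaze_rate_hz, x$seed))
  invisible(x)
}

# truncated-normal draw on [lo, hi] by rejection (vectorized)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}
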