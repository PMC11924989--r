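#' Ground-truth discriminative structure for the generator
#'
#' Defines, per (trial type, train-view location, test-view location), the
#' latency at which a spatial-frequency-discriminative component becomes
#' available in the synthetic EEG, together with the 64-channel topography of
#' each train-view component and a common signal amplitude. Every non-catch
#' trial carries, for each train-view location of its fixation side, a
#' class-signed component along that location's topography starting at the
#' condition's embedded onset; a classifier trained at location K therefore
#' decodes test trials at location L from exactly `onset(type, K, L)`.
#'
#' Default onsets emulate the qualitative structure of cross-location decoding
#' during fixation (decodability spreading outward with eccentricity) and its
#' acceleration under saccade preparation: same-location 80 ms, near 145 ms,
#' mid 205 ms, far 295 ms, and a uniform 140 ms for peripheral stimuli on
#' saccade trials. Control trials follow the fixation eccentricity mapping.
#' Each trial also carries an early (80 ms) component along its own location's
#' topography; topographies are mutually orthogonal, so this never leaks into
#' cross-location decoding.
#'
#' @param geometry Stimulus geometry, see [default_geometry()].
#' @param onsets_ms Named vector with entries `same`, `near`, `mid`, `far`
#'   (fixation/control conditions, by test-location eccentricity from current
#'   fixation) and `saccade` (peripheral saccade trials, all train views).
#' @param effect_amplitude Amplitude (microvolts) of each discriminative
#'   component along its unit-norm topography; 0 yields pure-noise sessions.
#' @param rise_ms Rise time of the component's raised-cosine onset ramp.
#' @param seed Seed for the (orthonormal) topography draw.
#'
#' @return An object of class `ground_truth`: list with `components` (tibble:
#'   trial_type, train_location, test_location, condition, onset_ms,
#'   amplitude), `topographies` (64 x 8 matrix, zero on the mastoid rows),
#'   `effect_amplitude`, `rise_ms`, `channel_names`.
#' @export
#' @examples
#' truth <- make_ground_truth()
#' dplyr::filter(truth$components, train_location == 1)
make_ground_truth <- function(geometry = default_geometry(),
                              onsets_ms = c(same = 80, near = 145, mid = 205,
                                            far = 295, saccade = 140),
                              effect_amplitude = 1.5,
                              rise_ms = 4,
                              seed = 1L) {
  stopifnot(all(c("same", "near", "mid", "far", "saccade") %in% names(onsets_ms)))
  if (any(onsets_ms < 0) || any(onsets_ms > 500)) {
    abort("embedded onsets must lie within the 0-500 ms epoch window")
  }
  o <- onsets_ms
  if (!(o["same"] <= o["near"] && o["near"] <= o["mid"] && o["mid"] <= o["far"])) {
    abort("fixation-condition onsets must be nondecreasing: same <= near <= mid <= far")
  }

  rows <- list()
  for (s in c("left", "right")) {
    train <- parafoveal_locations(s)
    # fixation: test views around current fixation
    for (K in train) for (L in train) {
      cond <- if (K == L) "same" else eccentricity_group(L, s, geometry)
      rows[[length(rows) + 1]] <- tibble::tibble(
        trial_type = "fixation", train_location = K, test_location = L,
        condition = cond, onset_ms = unname(o[cond])
      )
    }
    # control and peripheral saccade: test views around the other fixation point
    for (K in train) for (L in parafoveal_locations(other_side(s))) {
      ecc <- eccentricity_group(L, s, geometry)
      rows[[length(rows) + 1]] <- tibble::tibble(
        trial_type = "control", train_location = K, test_location = L,
        condition = ecc, onset_ms = unname(o[ecc])
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        trial_type = "saccade_peripheral", train_location = K, test_location = L,
        condition = if (L == congruent_location(K)) "congruent"
                    else if (L == incongruent_location(K)) "incongruent"
                    else ecc,
        onset_ms = unname(o["saccade"])
      )
    }
    # early stimulus-driven response along the stimulated location's own
    # topography (orthogonal to every cross-view component)
    for (L in parafoveal_locations(other_side(s))) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        trial_type = c("control", "saccade_peripheral", "saccade_central"),
        train_location = L, test_location = L,
        condition = "local", onset_ms = unname(o["same"])
      )
    }
  }
  comp <- dplyr::distinct(dplyr::bind_rows(rows))
  comp$amplitude <- effect_amplitude

  topo <- withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(62 * 8), 62, 8)))
    rbind(q, matrix(0, 2, 8)) # mastoid channels carry no signal
  })
  colnames(topo) <- paste0("loc", 1:8)

  structure(
    list(components = comp, topographies = topo,
         effect_amplitude = effect_amplitude, onsets_ms = o,
         rise_ms = rise_ms, channel_names = eeg_channel_names()),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat(sprintf("  embedded onsets (ms): %s\n",
              paste(names(x$onsets_ms), round(x$onsets_ms), sep = "=", collapse = ", ")))
  cat(sprintf("  effect amplitude: %g; %d component rows\n",
              x$effect_amplitude, nrow(x$components)))
  invisible(x)
}

eeg_channel_names <- function() c(sprintf("Ch%02d", 1:62), "M1", "M2")

#' Subject-level perturbation of the ground truth
#'
#' Gives each synthetic subject its own variant of the cohort ground truth:
#' topographies receive additive Gaussian jitter (then renormalized) and every
#' component onset is jittered by one epoch sample at most, providing the
#' across-subject variance that group-level Bayes-factor inference needs.
#'
#' @param truth A [make_ground_truth()] object.
#' @param subject_seed Integer seed identifying the subject.
#' @param topo_jitter SD of the topography perturbation before renormalizing.
#' @param onset_jitter_samples Maximum onset jitter, in 256 Hz samples.
#' @return A `ground_truth` object specific to the subject.
#' @export
subject_truth <- function(truth, subject_seed, topo_jitter = 0.2,
                          onset_jitter_samples = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  withr::with_seed(subject_seed, {
    topo <- truth$topographies
    pert <- topo[1:62, ] + topo_jitter * matrix(rnorm(62 * 8), 62, 8)
    pert <- sweep(pert, 2, sqrt(colSums(pert^2)), "/")
    truth$topographies <- rbind(pert, matrix(0, 2, 8))
    colnames(truth$topographies) <- colnames(topo)
    step_ms <- 1000 / EPOCH_RATE
    jit <- sample(seq(-onset_jitter_samples, onset_jitter_samples),
                  nrow(truth$components), replace = TRUE) * step_ms
    truth$components$onset_ms <- pmax(0, truth$components$onset_ms + jit)
    truth
  })
}

# raised-cosine onset envelope on a time grid (ms); 0 before onset, 1 after
# onset + rise, sustained thereafter
signal_envelope <- function(t_ms, onset_ms, rise_ms) {
  u <- (t_ms - onset_ms) / rise_ms
  ifelse(u <= 0, 0, ifelse(u >= 1, 1, (1 - cos(pi * u)) / 2))
}
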