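#' Epoch sets
#'
#' An `epoch_set` holds baseline-corrected trials on the canonical grid:
#' `data` is a trials x 64 channels x 180 timepoints array (microvolts,
#' 256 Hz, -200..+500 ms), `times_ms` the grid, `meta` the aligned trial
#' table and `subject_id` a label.
#'
#' @param data trials x channels x timepoints array.
#' @param meta Tibble of trial rows aligned with the first array dimension.
#' @param subject_id Subject label.
#' @return An `epoch_set` object.
#' @export
new_epoch_set <- function(data, meta, subject_id = "S01") {
  t_ms <- epoch_times_ms()
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(t_ms))
  if (dim(data)[1] != nrow(meta)) {
    abort("meta row count must equal the trials dimension of data")
  }
  structure(list(data = data, times_ms = t_ms, meta = tibble::as_tibble(meta),
                 subject_id = subject_id),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d timepoints (%s)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$subject_id))
  print(count(x$meta, .data$base_type))
  invisible(x)
}

# subtract the per-trial per-channel mean over -100..0 ms
baseline_correct <- function(data, t_ms) {
  bl <- which(t_ms >= -100 & t_ms <= 0)
  base <- apply(data[, , bl, drop = FALSE], c(1, 2), mean)
  data - as.vector(base) # recycles (trials x channels) over timepoints
}

#' Cut a continuous recording into baseline-corrected epochs
#'
#' Extracts -200..+500 ms windows time-locked to every stimulus-onset event,
#' subtracts each trial's and channel's mean over the -100..0 ms pre-stimulus
#' period, and drops catch trials, trials excluded by `keep`, and trials whose
#' window would fall outside the recording.
#'
#' @param rec A `continuous_recording` at 256 Hz (see [standardize_record()]).
#' @param schedule The session trial table.
#' @param keep Optional logical vector or tibble with `trial_id` and `kept`
#'   (as returned by [exclude_trials()]); trials not kept are dropped.
#' @return An `epoch_set`.
#' @export
epoch_and_baseline <- function(rec, schedule, keep = NULL) {
  if (rec$rate_hz != EPOCH_RATE) {
    abort(sprintf("recording must be at %d Hz; run standardize_record() first",
                  EPOCH_RATE))
  }
  sched <- schedule[!schedule$is_catch, ]
  if (!is.null(keep)) {
    if (is.data.frame(keep)) {
      kept_ids <- keep$trial_id[keep$kept]
      sched <- sched[sched$trial_id %in% kept_ids, ]
    } else {
      sched <- sched[keep[match(sched$trial_id, schedule$trial_id)], ]
    }
  }
  ev <- rec$events[match(sched$trial_id, rec$events$trial_id), ]
  if (anyNA(ev$sample_index)) {
    abort("input error: events missing for some scheduled trials")
  }
  n_samp <- ncol(rec$eeg)
  ok <- ev$sample_index - EPOCH_PRE_SAMPLES >= 1 &
    ev$sample_index + EPOCH_POST_SAMPLES <= n_samp
  if (any(!ok)) {
    message(sprintf("dropping %d trial(s) too close to the record edge", sum(!ok)))
  }
  sched <- sched[ok, ]; ev <- ev[ok, ]
  t_ms <- epoch_times_ms()
  data <- array(0, dim = c(nrow(sched), nrow(rec$eeg), length(t_ms)))
  offs <- -EPOCH_PRE_SAMPLES:EPOCH_POST_SAMPLES
  for (i in seq_len(nrow(sched))) {
    data[i, , ] <- rec$eeg[, ev$sample_index[i] + offs]
  }
  new_epoch_set(baseline_correct(data, t_ms), sched, rec$subject_id)
}
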