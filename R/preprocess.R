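#' Resample to 256 Hz and re-reference to the mastoids
#'
#' Anti-alias filters (zero-phase FIR, 80 Hz band) and decimates the
#' recording to 256 Hz, re-expresses every channel relative to the average of
#' the two mastoid channels, and remaps event sample indices to the new rate.
#' A recording already at 256 Hz is not resampled. Zero-phase filtering is
#' used throughout the package so that onset latencies are not biased by
#' filter delay.
#'
#' @param rec A `continuous_recording`.
#' @param mastoids Names of the two mastoid reference channels.
#' @return The standardized `continuous_recording` at 256 Hz.
#' @export
standardize_record <- function(rec, mastoids = c("M1", "M2")) {
  if (!all(mastoids %in% rec$channel_names)) {
    abort("input error: mastoid channels missing from the recording")
  }
  eeg <- rec$eeg
  if (rec$rate_hz != EPOCH_RATE) {
    fac <- rec$rate_hz / EPOCH_RATE
    if (abs(fac - round(fac)) > 1e-9 || fac < 1) {
      abort("input error: generator rate must be an integer multiple of 256 Hz")
    }
    fac <- as.integer(round(fac))
    aa <- signal::fir1(96, 80 / (rec$rate_hz / 2))
    eeg <- t(apply(eeg, 1, function(ch) signal::filtfilt(aa, ch)))
    idx <- seq(1, ncol(eeg), by = fac)
    eeg <- eeg[, idx, drop = FALSE]
    rec$events$sample_index <- pmax(1L, pmin(
      as.integer(round((rec$events$sample_index - 1) / fac) + 1), ncol(eeg)))
    rec$rate_hz <- EPOCH_RATE
  }
  m <- colMeans(eeg[match(mastoids, rec$channel_names), , drop = FALSE])
  eeg <- sweep(eeg, 2, m)
  rownames(eeg) <- rec$channel_names
  rec$eeg <- eeg
  rec
}

#' Band-pass and notch filter a standardized recording
#'
#' Zero-phase (forward-backward Butterworth) 0.1-80 Hz band-pass, applied as
#' a second-order high-pass at 0.1 Hz cascaded with a fourth-order low-pass
#' at 80 Hz, plus a second-order 48-52 Hz band-stop notch for line noise.
#'
#' @param rec A `continuous_recording` at 256 Hz.
#' @param band Pass band in Hz.
#' @param notch Stop band of the line-noise notch in Hz (`NULL` disables it).
#' @return The filtered recording.
#' @export
filter_eeg <- function(rec, band = c(0.1, 80), notch = c(48, 52)) {
  nyq <- rec$rate_hz / 2
  if (nyq < band[2]) {
    abort("configuration error: sampling rate must be at least twice the upper band edge")
  }
  hp <- signal::butter(2, band[1] / nyq, type = "high")
  lp <- signal::butter(4, band[2] / nyq, type = "low")
  bs <- if (!is.null(notch)) signal::butter(2, notch / nyq, type = "stop")
  rec$eeg <- t(apply(rec$eeg, 1, function(ch) {
    ch <- signal::filtfilt(hp, ch)
    ch <- signal::filtfilt(lp, ch)
    if (!is.null(bs)) ch <- signal::filtfilt(bs, ch)
    ch
  }))
  rownames(rec$eeg) <- rec$channel_names
  rec
}

#' Select ocular components by the saccade/fixation variance ratio
#'
#' Given component activations from any standard decomposition of the
#' recording (e.g., ICA), computes for each component the ratio of its mean
#' variance in -20..+10 ms windows around saccade onsets to its variance
#' during fixation periods, and flags components whose ratio exceeds 1.1
#' (strictly) as ocular. A component at exactly the 10% margin is kept.
#'
#' @param activations components x samples matrix.
#' @param saccade_onsets_s Saccade onset times in seconds (cued saccades and
#'   microsaccades alike).
#' @param fixation_spans Tibble with `start_s`, `end_s` of fixation periods
#'   (see [fixation_spans()]); by convention these exclude all detected
#'   eye-movement spans, microsaccades included.
#' @param rate_hz Sampling rate of the activations.
#' @param ratio_threshold Rejection threshold on the variance ratio.
#' @return List with `rejected` (component indices) and `ratios` (tibble:
#'   component, saccade_var, fixation_var, ratio).
#' @export
select_ocular_components <- function(activations, saccade_onsets_s,
                                     fixation_spans, rate_hz = EPOCH_RATE,
                                     ratio_threshold = 1.1) {
  if (!length(saccade_onsets_s)) {
    warn("no saccades in record; ocular-component criterion inapplicable")
    return(list(rejected = integer(0), ratios = tibble::tibble()))
  }
  n <- ncol(activations)
  win <- function(on) {
    i0 <- max(1L, round((on - 0.020) * rate_hz) + 1L)
    i1 <- min(n, round((on + 0.010) * rate_hz) + 1L)
    seq(i0, i1)
  }
  sac_idx <- lapply(saccade_onsets_s, win)
  fix_idx <- unlist(purrr::map2(fixation_spans$start_s, fixation_spans$end_s,
                                function(a, b) {
                                  seq(max(1L, round(a * rate_hz) + 1L),
                                      min(n, round(b * rate_hz) + 1L))
                                }))
  ratios <- purrr::map_dfr(seq_len(nrow(activations)), function(k) {
    sv <- mean(vapply(sac_idx, function(ii) var(activations[k, ii]), numeric(1)))
    fv <- var(activations[k, fix_idx])
    tibble::tibble(component = k, saccade_var = sv, fixation_var = fv,
                   ratio = sv / fv)
  })
  list(rejected = ratios$component[ratios$ratio > ratio_threshold],
       ratios = ratios)
}

#' Fixation spans of a recording
#'
#' Complements the detected eye-movement events (padded by `pad_s`) and blink
#' spans over the recording span, returning the periods of steady fixation
#' used as the reference variance in [select_ocular_components()].
#'
#' @param events Saccade events from [detect_saccades()].
#' @param span_s Total duration of the recording, s.
#' @param blink_spans Optional tibble with `start_s`, `end_s` of blinks.
#' @param pad_s Padding added around each event, s.
#' @return Tibble with `start_s`, `end_s`.
#' @export
fixation_spans <- function(events, span_s, blink_spans = NULL, pad_s = 0.02) {
  occ <- tibble::tibble(start_s = events$onset_s - pad_s,
                        end_s = events$offset_s + pad_s)
  if (!is.null(blink_spans) && nrow(blink_spans)) {
    occ <- dplyr::bind_rows(occ, blink_spans)
  }
  occ <- occ[order(occ$start_s), ]
  cur <- 0
  out <- list()
  for (i in seq_len(nrow(occ))) {
    if (occ$start_s[i] > cur) {
      out[[length(out) + 1]] <- tibble::tibble(start_s = cur,
                                               end_s = occ$start_s[i])
    }
    cur <- max(cur, occ$end_s[i])
  }
  if (cur < span_s) {
    out[[length(out) + 1]] <- tibble::tibble(start_s = cur, end_s = span_s)
  }
  dplyr::bind_rows(out)
}
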