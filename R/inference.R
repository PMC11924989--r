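#' JZS one-sample Bayes factor
#'
#' Computes the Jeffreys-Zellner-Siow Bayes factor BF10 for a one-sample
#' t-test of `samples` against `null_value`: point null (standardized effect
#' delta = 0) versus a symmetric Cauchy prior with scale `r` on delta
#' (medium width r = sqrt(2)/2 by default, covering effects in both
#' directions so above- and below-chance decoding count as evidence alike).
#' Evaluated through the inverse-gamma mixture representation of the Cauchy
#' prior by adaptive quadrature over the mixing variable.
#'
#' @param samples Numeric vector of per-subject values (n >= 2, finite).
#' @param null_value The null location (0.5 for decoding accuracy, 0 for
#'   paired differences).
#' @param r Cauchy prior scale on the standardized effect size.
#' @return BF10 (scalar, > 0). Values above 3 are conventionally read as
#'   substantial evidence for an effect, below 1/3 as substantial evidence
#'   for the null.
#' @export
#' @examples
#' bf_ttest(c(0.61, 0.55, 0.64, 0.58, 0.66, 0.57, 0.62, 0.59, 0.6, 0.63), 0.5)
bf_ttest <- function(samples, null_value = 0.5, r = sqrt(2) / 2) {
  samples <- as.numeric(samples)
  if (length(samples) < 2 || !all(is.finite(samples))) {
    abort("need at least 2 finite samples")
  }
  s <- sd(samples)
  if (s == 0) abort("degenerate input: zero variance across samples")
  n <- length(samples)
  t <- (mean(samples) - null_value) / (s / sqrt(n))
  jzs_bf10(t, n, r)
}

# BF10 from the t statistic: Rouder et al. style inverse-gamma mixture,
# delta | g ~ N(0, g), g ~ InvGamma(1/2, r^2/2) <=> delta ~ Cauchy(0, r)
jzs_bf10 <- function(t, n, r = sqrt(2) / 2) {
  nu <- n - 1
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    exp(-0.5 * log1p(n * g) -
          (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) - log_null) *
      invgamma_half(g, r)
  }
  alt <- integrate(integrand, 0, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  alt
}

# InvGamma(shape 1/2, scale r^2/2) density
invgamma_half <- function(g, r) {
  (r^2 / 2)^(1 / 2) / gamma(1 / 2) * g^(-3 / 2) * exp(-r^2 / (2 * g))
}

#' Per-timepoint Bayes-factor time course across subjects
#'
#' Applies [bf_ttest()] at every timepoint to the across-subject accuracy
#' (or difference) values, classifying each timepoint's evidence as
#' `"alternative"` (BF > 3), `"null"` (BF < 1/3) or `"inconclusive"`.
#'
#' @param series Subject-level decode series: tibble with `subject`,
#'   `time_ms`, `accuracy` (one value per subject and timepoint; a
#'   `condition` column, if present, must be constant).
#' @param null_value Null level, 0.5 for accuracies.
#' @param r Cauchy prior scale.
#' @return A `bf_series` tibble: `time_ms`, `bf10`, `mean_value` (the
#'   across-subject mean at each timepoint), `n_subjects`, `evidence`, with
#'   the null level stored in attribute `null_value`.
#' @export
bf_timecourse <- function(series, null_value = 0.5, r = sqrt(2) / 2) {
  if ("condition" %in% names(series) &&
      dplyr::n_distinct(series$condition) > 1) {
    abort("bf_timecourse expects a single condition; split beforehand")
  }
  ns <- dplyr::n_distinct(series$subject)
  if (ns < 2) abort("need at least 2 subjects")
  # a timepoint where every subject scores identically has no sample variance;
  # evidence is then unbounded (mean off the null) or, exactly at the null,
  # the t = 0 limit of the Bayes factor
  bf_safe <- function(x) {
    if (sd(x) == 0) {
      return(if (mean(x) == null_value) jzs_bf10(0, length(x), r) else Inf)
    }
    bf_ttest(x, null_value = null_value, r = r)
  }
  out <- series %>%
    group_by(.data$time_ms) %>%
    summarise(bf10 = bf_safe(.data$accuracy),
              mean_value = mean(.data$accuracy),
              n_subjects = dplyr::n(), .groups = "drop") %>%
    mutate(evidence = dplyr::case_when(
      .data$bf10 > 3 ~ "alternative",
      .data$bf10 < 1 / 3 ~ "null",
      TRUE ~ "inconclusive"
    ))
  attr(out, "null_value") <- null_value
  class(out) <- c("bf_series", class(out))
  out
}

#' Onset latency from a Bayes-factor time course
#'
#' The onset is the time of the first sample of the earliest run of at least
#' three consecutive timepoints with BF10 above threshold, searched inside
#' `window`; `NA` when no such run exists. The Cauchy prior is two-sided, so
#' a sustained below-chance excursion also drives BF10 above threshold; when
#' the question is the onset of above-chance decoding specifically, set
#' `direction = "above"` to additionally require the across-subject mean to
#' lie above the null level (needs the `mean_value` column produced by
#' [bf_timecourse()]).
#'
#' @param bf A `bf_series` tibble (or any tibble with `time_ms`, `bf10`).
#' @param window Search window in ms (default 0-500).
#' @param threshold Evidence threshold (BF > 3).
#' @param run_length Required number of consecutive suprathreshold samples.
#' @param direction `"any"` applies the bare BF rule; `"above"` / `"below"`
#'   restrict to evidence in that direction relative to the null.
#' @return Onset time in ms, or `NA_real_`.
#' @export
detect_onset <- function(bf, window = c(0, 500), threshold = 3,
                         run_length = 3,
                         direction = c("any", "above", "below")) {
  direction <- match.arg(direction)
  sel <- bf$time_ms >= window[1] & bf$time_ms <= window[2]
  tm <- bf$time_ms[sel]
  above <- bf$bf10[sel] > threshold
  if (direction != "any") {
    if (!"mean_value" %in% names(bf)) {
      abort("directional onset detection needs the mean_value column from bf_timecourse()")
    }
    nv <- attr(bf, "null_value")
    if (is.null(nv)) nv <- 0.5
    dir_ok <- if (direction == "above") bf$mean_value[sel] > nv
              else bf$mean_value[sel] < nv
    above <- above & dir_ok
  }
  above[is.na(above)] <- FALSE
  if (length(above) < run_length) return(NA_real_)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= run_length)
  if (!length(hit)) return(NA_real_)
  tm[starts[hit[1]]]
}

#' Onset estimate with a leave-two-out jackknife confidence interval
#'
#' Recomputes the Bayes-factor time course and onset over every
#' leave-two-out subject subset (`choose(n, 2)` subsets; 45 for 10 subjects)
#' and reports the 2.5th and 97.5th percentiles of the resulting onset
#' distribution as the 95% confidence interval. Subsets in which no onset is
#' detected are excluded from the percentiles and counted in `n_absent`.
#'
#' @inheritParams bf_timecourse
#' @param window,threshold,run_length,direction Passed to [detect_onset()].
#' @return An `onset_estimate` tibble: `onset_ms` (full-sample onset),
#'   `ci_low_ms`, `ci_high_ms`, `n_subjects`, `n_permutations`, `n_absent`.
#' @export
jackknife_onset_ci <- function(series, null_value = 0.5, window = c(0, 500),
                               threshold = 3, run_length = 3,
                               direction = "any", r = sqrt(2) / 2) {
  subjects <- unique(series$subject)
  if (length(subjects) < 4) abort("need at least 4 subjects for a leave-two-out jackknife")
  full <- detect_onset(bf_timecourse(series, null_value, r = r),
                       window, threshold, run_length, direction)
  pairs <- combn(subjects, 2, simplify = FALSE)
  onsets <- vapply(pairs, function(pr) {
    sub <- series[!series$subject %in% pr, ]
    detect_onset(bf_timecourse(sub, null_value, r = r),
                 window, threshold, run_length, direction)
  }, numeric(1))
  present <- onsets[!is.na(onsets)]
  if (!length(present) && is.na(full)) {
    out <- tibble::tibble(onset_ms = NA_real_, ci_low_ms = NA_real_,
                          ci_high_ms = NA_real_,
                          n_subjects = length(subjects),
                          n_permutations = length(pairs),
                          n_absent = sum(is.na(onsets)))
  } else {
    ci <- if (length(present)) quantile(present, c(0.025, 0.975), names = FALSE)
          else c(NA_real_, NA_real_)
    out <- tibble::tibble(onset_ms = full, ci_low_ms = ci[1], ci_high_ms = ci[2],
                          n_subjects = length(subjects),
                          n_permutations = length(pairs),
                          n_absent = sum(is.na(onsets)))
  }
  class(out) <- c("onset_estimate", class(out))
  out
}

#' Bayes-factor time course of a paired condition difference
#'
#' Pairs two subject-level decode series by subject and timepoint and tests
#' the within-subject accuracy difference against zero at every timepoint
#' (used for saccade-vs-control and congruent-vs-incongruent contrasts).
#' Symmetric in its arguments under the two-sided prior.
#'
#' @param series_a,series_b Subject-level decode series sharing subjects and
#'   time grid.
#' @inheritParams bf_timecourse
#' @return A `bf_series` tibble.
#' @export
difference_bf <- function(series_a, series_b, r = sqrt(2) / 2) {
  joined <- inner_join(
    series_a[, c("subject", "time_ms", "accuracy")],
    series_b[, c("subject", "time_ms", "accuracy")],
    by = c("subject", "time_ms"), suffix = c("_a", "_b")
  )
  if (nrow(joined) != nrow(series_a) || nrow(joined) != nrow(series_b)) {
    abort("series are not paired: subjects/time grids differ")
  }
  joined %>%
    mutate(accuracy = .data$accuracy_a - .data$accuracy_b) %>%
    bf_timecourse(null_value = 0, r = r)
}
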