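# ---- shrinkage LDA primitives ------------------------------------------

# Pure-R reference implementation of the shrinkage discriminant: Ledoit-Wolf
# analytic shrinkage of the pooled covariance toward a scaled identity
# (64 channels vs tens of trials per class makes the plain pooled estimate
# unusable). The hot path uses the compiled equivalent (src/lda_stack.cpp);
# the test suite checks both give the same discriminants.
fit_lda <- function(X, y_high) {
  n <- nrow(X); p <- ncol(X)
  x1 <- X[y_high, , drop = FALSE]
  x0 <- X[!y_high, , drop = FALSE]
  if (!nrow(x1) || !nrow(x0)) abort("single-class input: cannot fit a discriminant")
  mu1 <- colMeans(x1); mu0 <- colMeans(x0)
  C <- rbind(sweep(x1, 2, mu1), sweep(x0, 2, mu0))
  S <- crossprod(C) / n
  m <- sum(diag(S)) / p
  d2 <- sum((S - diag(m, p))^2)
  if (d2 < .Machine$double.eps) {
    sigma <- diag(m + 1e-12, p)
  } else {
    q <- rowSums(C^2)
    b2bar <- (sum(q^2) - 2 * sum((C %*% S) * C) + n * sum(S^2)) / n^2
    rho <- min(1, max(0, b2bar / d2))
    sigma <- (1 - rho) * S + diag(rho * m, p)
  }
  w <- solve(sigma, mu1 - mu0)
  list(w = w, b = -sum(w * (mu1 + mu0) / 2))
}

# decision: strictly positive score -> "high"; boundary ties go to "low"
predict_lda <- function(fit, X) as.vector(X %*% fit$w + fit$b) > 0

# trials x channels matrix at one timepoint (keeps matrix form for 1 trial)
slice_t <- function(data, trials, t) {
  x <- data[trials, , t, drop = FALSE]
  dim(x) <- dim(x)[1:2]
  x
}

# balanced (seeded) subsample: majority class down to the minority count
balance_classes <- function(idx, y_high, seed) {
  i1 <- idx[y_high[idx]]; i0 <- idx[!y_high[idx]]
  m <- min(length(i1), length(i0))
  if (m < 1) abort("single-class input: cannot balance classes")
  withr::with_seed(seed, {
    sort(c(sample(i1, m), sample(i0, m)))
  })
}

# ---- classifier stacks --------------------------------------------------

#' Train a time-resolved classifier stack
#'
#' Fits, at every timepoint of the epoch grid, a two-class shrinkage-LDA
#' discriminant separating high from low spatial frequency on the 64-channel
#' amplitude vector, using the fixation trials at one (location, side) cell.
#' Class balance is enforced by seeded subsampling of the majority class.
#'
#' @param epochs An `epoch_set`.
#' @param location Training stimulus location (1-8).
#' @param side Fixation side of the training trials.
#' @param seed Seed for the balancing subsample.
#' @return A `classifier_stack`: list with `weights` (64 x timepoints),
#'   `bias`, `train_location`, `side`, `n_train_trials`, `train_idx`.
#' @export
train_stack <- function(epochs, location, side, seed = 1L) {
  idx <- which(epochs$meta$base_type == "fixation" &
                 epochs$meta$location_id == location &
                 epochs$meta$fixation_side == side)
  if (length(idx) < 4) abort("need at least 2 trials per class at the training cell")
  y <- epochs$meta$sf_class == "high"
  idx <- balance_classes(idx, y, seed)
  fit <- lda_fit_stack_cpp(epochs$data, idx - 1L, as.integer(y[idx]))
  W <- fit$weights
  b <- as.vector(fit$bias)
  if (!all(is.finite(W))) abort("non-finite discriminant weights")
  structure(list(weights = W, bias = b, times_ms = epochs$times_ms,
                 train_location = location, side = side,
                 n_train_trials = length(idx), train_idx = idx),
            class = "classifier_stack")
}

#' @export
print.classifier_stack <- function(x, ...) {
  cat(sprintf("<classifier_stack> location %d (%s fixation), %d training trials, %d timepoints\n",
              x$train_location, x$side, x$n_train_trials, length(x$bias)))
  invisible(x)
}

decode_series_row <- function(epochs, condition, train_location, side,
                              test_location, time_ms, accuracy, n_test) {
  tibble::tibble(subject = epochs$subject_id, condition = condition,
                 side = side, train_location = train_location,
                 test_location = test_location, time_ms = time_ms,
                 accuracy = accuracy, n_test = n_test)
}

#' Same-location decoding by stratified five-fold cross-validation
#'
#' Trains and tests on the fixation trials of one (location, side) cell with
#' stratified k-fold cross-validation, evaluating each fold on the time
#' diagonal (train timepoint t tested at t) and averaging fold accuracies.
#'
#' @inheritParams train_stack
#' @param k Number of folds.
#' @return A decode-series tibble (`subject`, `condition = "same"`, `side`,
#'   `train_location`, `test_location`, `time_ms`, `accuracy`, `n_test`).
#' @export
crossval_same <- function(epochs, location, side, k = 5, seed = 1L) {
  idx <- which(epochs$meta$base_type == "fixation" &
                 epochs$meta$location_id == location &
                 epochs$meta$fixation_side == side)
  y <- epochs$meta$sf_class == "high"
  idx <- balance_classes(idx, y, seed)
  m <- sum(y[idx])
  if (k > m) abort("k exceeds the per-class trial count")
  folds <- withr::with_seed(seed + 1L, {
    f <- integer(length(idx))
    f[y[idx]] <- sample(rep_len(seq_len(k), m))
    f[!y[idx]] <- sample(rep_len(seq_len(k), m))
    f
  })
  nt <- length(epochs$times_ms)
  correct <- numeric(nt)
  for (fold in seq_len(k)) {
    tr <- idx[folds != fold]; te <- idx[folds == fold]
    fit <- lda_fit_stack_cpp(epochs$data, tr - 1L, as.integer(y[tr]))
    sc <- lda_score_stack_cpp(epochs$data, te - 1L, fit$weights,
                              as.vector(fit$bias))
    correct <- correct + colSums((sc > 0) == y[te])
  }
  decode_series_row(epochs, "same", location, side, location,
                    epochs$times_ms, correct / length(idx), length(idx))
}

#' Cross-test a trained stack on selected trials
#'
#' Evaluates a classifier stack on an arbitrary selection of test trials,
#' strictly on the time diagonal. The caller is responsible for the selection
#' being disjoint from the training trials (it always is for cross-location
#' and cross-condition tests).
#'
#' @param stack A `classifier_stack`.
#' @param epochs An `epoch_set` (same time grid).
#' @param trials Integer indices into `epochs$meta` of the test trials.
#' @param condition Condition label stored in the output.
#' @return A decode-series tibble.
#' @export
cross_test <- function(stack, epochs, trials, condition = NA_character_) {
  if (!length(trials)) {
    abort(sprintf("empty test selection for condition '%s' (train location %d, %s)",
                  condition, stack$train_location, stack$side))
  }
  stopifnot(length(stack$bias) == length(epochs$times_ms))
  y <- epochs$meta$sf_class[trials] == "high"
  sc <- lda_score_stack_cpp(epochs$data, trials - 1L, stack$weights, stack$bias)
  acc <- colMeans((sc > 0) == y)
  test_loc <- unique(epochs$meta$location_id[trials])
  decode_series_row(epochs, condition, stack$train_location, stack$side,
                    if (length(test_loc) == 1) test_loc else NA_integer_,
                    epochs$times_ms, acc, length(trials))
}

# ---- condition mapping and aggregation ---------------------------------

#' Map a (train, test) location pair to its condition label
#'
#' Fixation and control test trials are labelled `"same"` (train = test) or
#' by the test location's eccentricity group from current fixation
#' (`"near"`, `"mid"`, `"far"`). Peripheral-saccade test trials are labelled
#' `"congruent"` when the test location is the train location's partner
#' across the saccade (pairs 1-5, 2-6, 3-7, 4-8 and their right-fixation
#' mirror images), `"incongruent"` for the mirror partner's congruent
#' location, and by eccentricity group otherwise.
#'
#' @param train_location,test_location Location ids (1-8).
#' @param trial_type Test trial type (`fixation`, `control`,
#'   `saccade_peripheral`).
#' @param side Fixation side of the classifier.
#' @param geometry See [default_geometry()].
#' @return A condition label (character scalar).
#' @export
map_condition <- function(train_location, test_location, trial_type,
                          side = "left", geometry = default_geometry()) {
  if (!all(c(train_location, test_location) %in% geometry$locations$location_id)) {
    abort("unknown location id")
  }
  if (trial_type %in% c("fixation", "control")) {
    if (train_location == test_location) return("same")
    return(eccentricity_group(test_location, side, geometry))
  }
  if (trial_type == "saccade_peripheral") {
    if (test_location == congruent_location(train_location)) return("congruent")
    if (test_location == incongruent_location(train_location)) return("incongruent")
    return(eccentricity_group(test_location, side, geometry))
  }
  abort(sprintf("no condition mapping for trial type '%s'", trial_type))
}

#' Average decode series within conditions, then across sides
#'
#' Unweighted mean accuracy in the stated order: first over (train, test)
#' pairs within a (condition, side), then over the two fixation sides,
#' producing one series per subject and condition. Across-subject averaging
#' is left to reporting; inference consumes the subject-level series.
#'
#' @param series A decode-series tibble (rows from [crossval_same()] /
#'   [cross_test()] with conditions filled in).
#' @return Tibble: `subject`, `condition`, `time_ms`, `accuracy`, `n_test`.
#' @export
aggregate_series <- function(series) {
  if (dplyr::n_distinct(purrr::map_int(split(series$time_ms, interaction(
    series$condition, series$side, series$train_location, series$test_location,
    drop = TRUE)), length)) > 1) {
    abort("series do not share a common time grid")
  }
  if (!"scheme" %in% names(series)) series$scheme <- NA_character_
  series %>%
    group_by(.data$subject, .data$scheme, .data$condition, .data$side,
             .data$time_ms) %>%
    summarise(accuracy = mean(.data$accuracy), n_test = sum(.data$n_test),
              .groups = "drop") %>%
    group_by(.data$subject, .data$scheme, .data$condition, .data$time_ms) %>%
    summarise(accuracy = mean(.data$accuracy), n_test = sum(.data$n_test),
              .groups = "drop")
}

#' Cross-test separately within saccade-latency bins
#'
#' Splits peripheral-saccade test trials by their stimulus-to-saccade latency
#' and evaluates [cross_test()] within each bin. Empty bins are dropped with
#' a message.
#'
#' @param stack A `classifier_stack`.
#' @param epochs An `epoch_set`.
#' @param trials Candidate test-trial indices (peripheral saccade trials).
#' @param edges Bin edges in ms (default 100 ms bins over the inclusion
#'   window).
#' @return A decode-series tibble with one condition label per bin
#'   (`"lat100-200"`, ...).
#' @export
bin_by_saccade_latency <- function(stack, epochs, trials,
                                   edges = c(100, 200, 300, 400)) {
  lat <- epochs$meta$stim_to_saccade_ms[trials]
  out <- list()
  for (b in seq_len(length(edges) - 1)) {
    sel <- trials[!is.na(lat) & lat >= edges[b] & lat < edges[b + 1]]
    lab <- sprintf("lat%g-%g", edges[b], edges[b + 1])
    if (!length(sel)) {
      message(sprintf("latency bin %s empty; dropped", lab))
      next
    }
    out[[lab]] <- cross_test(stack, epochs, sel, condition = lab)
  }
  dplyr::bind_rows(out)
}

# ---- per-subject scheme orchestrators ----------------------------------

#' Run decoding schemes for one subject
#'
#' Orchestrates classifier training and testing for one subject's epochs,
#' returning per-condition aggregated decode series. Schemes:
#' `"fixation-cross"` (same-location five-fold cross-validation plus
#' cross-location tests on fixation and control trials, labelled
#' same/near/mid/far), `"saccade-congruency"` (fixation-trained classifiers
#' tested on congruent and incongruent peripheral-saccade trials, and on
#' control trials at the congruent location, labelled
#' congruent/incongruent/control), `"saccade-eccentricity"` (saccade tests
#' grouped near/mid/far) and `"latency-bins"`. Several schemes can be run in
#' one call; trained stacks are shared across them. Peripheral-saccade tests
#' only use trials with stimulus-to-saccade latency inside
#' `latency_range_ms`.
#'
#' @param epochs An `epoch_set`.
#' @param scheme Scheme name(s), see above.
#' @param train_locations Training locations to use (default: every
#'   parafoveal location with enough trials on its side).
#' @param k Cross-validation folds for the `"same"` condition.
#' @param latency_range_ms Saccade-latency inclusion window, ms.
#' @param edges Latency-bin edges (only for `"latency-bins"`).
#' @param seed Seed for balancing and fold assignment.
#' @return Aggregated decode-series tibble (`subject`, `scheme`,
#'   `condition`, `time_ms`, `accuracy`, `n_test`).
#' @export
decode_subject <- function(epochs,
                           scheme = c("fixation-cross", "saccade-congruency",
                                      "saccade-eccentricity", "latency-bins"),
                           train_locations = NULL, k = 5,
                           latency_range_ms = c(100, 400),
                           edges = c(100, 200, 300, 400), seed = 1L) {
  schemes <- match.arg(scheme, several.ok = TRUE)
  meta <- epochs$meta
  cells <- meta %>%
    filter(.data$base_type == "fixation") %>%
    count(.data$fixation_side, .data$location_id) %>%
    filter(.data$n >= 2 * k)
  if (!is.null(train_locations)) {
    cells <- cells[cells$location_id %in% train_locations, ]
  }
  if (!nrow(cells)) abort("no trainable (location, side) cells in these epochs")

  sacc_ok <- meta$base_type == "saccade_peripheral" &
    !is.na(meta$stim_to_saccade_ms) &
    meta$stim_to_saccade_ms >= latency_range_ms[1] &
    meta$stim_to_saccade_ms <= latency_range_ms[2]

  rows <- purrr::pmap(cells, function(fixation_side, location_id, n) {
    side <- fixation_side; loc <- location_id
    stack <- train_stack(epochs, loc, side, seed = seed)
    pieces <- list()
    for (sc in schemes) {
      if (sc == "fixation-cross") {
        pc <- list(crossval_same(epochs, loc, side, k = k, seed = seed))
        test_cells <- meta %>%
          mutate(row = dplyr::row_number()) %>%
          filter(.data$fixation_side == side,
                 .data$base_type %in% c("fixation", "control"),
                 !(.data$base_type == "fixation" & .data$location_id == loc))
        for (L in unique(test_cells$location_id)) {
          sel <- test_cells$row[test_cells$location_id == L]
          ty <- test_cells$base_type[test_cells$location_id == L][1]
          cond <- map_condition(loc, L, ty, side)
          pc[[length(pc) + 1]] <- cross_test(stack, epochs, sel, cond)
        }
      } else if (sc == "saccade-congruency") {
        pc <- list()
        csel <- which(sacc_ok & meta$fixation_side == side &
                        meta$location_id == congruent_location(loc))
        isel <- which(sacc_ok & meta$fixation_side == side &
                        meta$location_id == incongruent_location(loc))
        ctrl <- which(meta$base_type == "control" &
                        meta$fixation_side == side &
                        meta$location_id == congruent_location(loc))
        if (length(csel)) pc$con <- cross_test(stack, epochs, csel, "congruent")
        if (length(isel)) pc$inc <- cross_test(stack, epochs, isel, "incongruent")
        if (length(ctrl)) pc$ctl <- cross_test(stack, epochs, ctrl, "control")
      } else if (sc == "saccade-eccentricity") {
        pc <- list()
        sel_all <- which(sacc_ok & meta$fixation_side == side)
        for (L in unique(meta$location_id[sel_all])) {
          sel <- sel_all[meta$location_id[sel_all] == L]
          pc[[length(pc) + 1]] <- cross_test(stack, epochs, sel,
                                             eccentricity_group(L, side))
        }
      } else { # latency-bins
        pc <- list()
        sel <- which(sacc_ok & meta$fixation_side == side &
                       meta$location_id == congruent_location(loc))
        if (length(sel)) {
          pc$bins <- bin_by_saccade_latency(stack, epochs, sel, edges)
        }
      }
      if (length(pc)) {
        pieces[[sc]] <- dplyr::bind_rows(pc) %>% mutate(scheme = sc)
      }
    }
    dplyr::bind_rows(pieces)
  })
  aggregate_series(dplyr::bind_rows(rows))
}
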