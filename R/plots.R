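#' Plot subject-averaged decoding accuracy over time
#'
#' One line per condition, averaged across subjects, with a chance-level
#' reference line.
#'
#' @param series A decode-series tibble (`subject`, `condition`, `time_ms`,
#'   `accuracy`).
#' @param chance Chance level (0.5 for two-class decoding).
#' @return A ggplot object.
#' @export
plot_decode_series <- function(series, chance = 0.5) {
  avg <- series %>%
    group_by(.data$condition, .data$time_ms) %>%
    summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(.data$time_ms, .data$accuracy,
                                    colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from stimulus onset (ms)",
                  y = "classification accuracy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_decode_series Autoplot method for Bayes-factor series:
#'   log10 BF over time with the substantial-evidence thresholds (BF = 3,
#'   BF = 1/3) marked.
#' @param object A `bf_series`.
#' @param ... Unused.
#' @export
autoplot.bf_series <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      log_bf = log10(pmin(.data$bf10, 1e12)))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$log_bf)) +
    ggplot2::geom_hline(yintercept = log10(c(1 / 3, 3)),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$evidence), size = 0.8) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "time from stimulus onset (ms)",
                  y = "log10 Bayes factor", colour = "evidence") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_decode_series Autoplot method for cohort results:
#'   condition-wise accuracy curves with recovered (solid) and embedded
#'   (dashed) onsets.
#' @export
autoplot.cohort_result <- function(object, ...) {
  p <- plot_decode_series(object$series)
  ons <- object$onsets[!is.na(object$onsets$onset_ms), ]
  if (nrow(ons)) {
    p <- p +
      ggplot2::geom_vline(data = ons,
                          ggplot2::aes(xintercept = .data$onset_ms,
                                       colour = .data$condition),
                          linetype = "solid", alpha = 0.6) +
      ggplot2::geom_vline(data = ons,
                          ggplot2::aes(xintercept = .data$embedded_ms,
                                       colour = .data$condition),
                          linetype = "dashed", alpha = 0.6)
  }
  p
}
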