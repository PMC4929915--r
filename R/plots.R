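# ggplot2 views of the main result types. These mirror the figures a
# damage report usually shows: the moded length histogram with its
# exponential tail, the terminal misincorporation curves, the upstream
# composition profile, and lambda against age with the fitted decay rate.

#' Plot a fragment-length distribution
#'
#' @param dist histogram from [length_distribution()].
#' @param fit optional `decay_fit`; when given, the fitted exponential is
#'   drawn over its window and the y axis is log-scaled.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(dist, fit = NULL) {
  p <- ggplot2::ggplot(dist, ggplot2::aes(x = .data$length, y = .data$n)) +
    ggplot2::geom_col(width = 1, fill = "grey55") +
    ggplot2::labs(x = "fragment length (bp)", y = "reads")
  if (!is.null(fit)) {
    win <- tibble(length = seq(fit$window[1], fit$window[2]))
    win$n <- exp(fit$log_F0 - fit$lambda_hat * win$length)
    p <- p +
      ggplot2::geom_line(data = win, colour = "red") +
      ggplot2::scale_y_log10() +
      ggplot2::labs(subtitle = sprintf("lambda = %.3g per bond", fit$lambda_hat))
  }
  p
}

#' Plot terminal misincorporation frequencies
#'
#' C-to-T from the 5' end and G-to-A from the 3' end, the canonical
#' deamination signature.
#'
#' @param profile output of [misincorporation_profile()].
#' @return A ggplot object.
#' @export
plot_misincorporation <- function(profile) {
  d <- dplyr::filter(
    profile,
    (.data$end == "5p" & .data$ref == "C" & .data$read == "T") |
      (.data$end == "3p" & .data$ref == "G" & .data$read == "A")
  ) |>
    dplyr::mutate(type = ifelse(.data$end == "5p", "5' C>T", "3' G>A"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$freq,
                                  colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "position from read end", y = "substitution frequency",
                  colour = NULL)
}

#' Plot the upstream base-composition profile
#'
#' @param profile output of [composition_profile()].
#' @return A ggplot object.
#' @export
plot_composition <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$position, y = .data$freq,
                                        colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "position relative to 5' read start",
                  y = "base frequency", colour = NULL)
}

#' Plot lambda against age with the fitted decay rate
#'
#' @param samples data frame with `age` and `lambda_hat`.
#' @param fit optional `decay_rate_fit` whose through-origin and
#'   free-intercept lines are drawn.
#' @return A ggplot object.
#' @export
plot_decay_rate <- function(samples, fit = NULL) {
  p <- ggplot2::ggplot(samples, ggplot2::aes(x = .data$age, y = .data$lambda_hat)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sample age (years)", y = "damage fraction per site (lambda)")
  if (!is.null(fit)) {
    p <- p +
      ggplot2::geom_abline(slope = fit$through_origin$slope, intercept = 0,
                           colour = "red") +
      ggplot2::geom_abline(slope = fit$free_intercept$slope,
                           intercept = fit$free_intercept$intercept,
                           colour = "blue", linetype = 2) +
      ggplot2::labs(subtitle = sprintf("k = %.3g per site per year", fit$k))
  }
  p
}

#' Autoplot methods
#'
#' `autoplot()` dispatches to the matching `plot_*()` function.
#'
#' @param object a `decay_fit` is not plottable alone; supported classes
#'   are `decay_rate_fit` (lambda vs age) and `cohort_report` (same, from
#'   its analysis table).
#' @param ... unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.decay_rate_fit <- function(object, ...) {
  d <- object$through_origin$fit$model
  names(d) <- c("lambda_hat", "age")
  plot_decay_rate(d, object)
}

#' @rdname autoplot.decay_rate_fit
#' @export
autoplot.cohort_report <- function(object, ...) {
  comp <- names(object$decay)[1]
  d <- object$table
  if ("compartment" %in% names(d)) d <- d[d$compartment == comp, ]
  plot_decay_rate(d, object$decay[[comp]])
}
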