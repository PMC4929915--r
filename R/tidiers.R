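#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidy_herbdecay
#' @title Broom-style tidiers for herbdecay fit objects
#' @description `tidy()` returns one row per estimated quantity;
#'   `glance()` returns a one-row model summary.
#' @param x a fitted object from this package.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.lognormal_fit <- function(x, ...) {
  tibble(
    term = c("log_mean", "log_sd", "median"),
    estimate = c(x$log_mean, x$log_sd, x$median)
  )
}

#' @rdname tidy_herbdecay
#' @export
glance.lognormal_fit <- function(x, ...) {
  tibble(log_mean = x$log_mean, log_sd = x$log_sd, median = x$median, n = x$n)
}

#' @rdname tidy_herbdecay
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(
    term = c("lambda", "log_F0"),
    estimate = c(x$lambda_hat, x$log_F0)
  )
}

#' @rdname tidy_herbdecay
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(lambda_hat = x$lambda_hat, log_F0 = x$log_F0,
         window_lo = x$window[1], window_hi = x$window[2],
         r_squared = x$r_squared, n_bins = x$n_bins, quality = x$quality)
}

#' @rdname tidy_herbdecay
#' @export
tidy.herb_regression <- function(x, ...) {
  td <- tibble(
    term = c(if (!x$through_origin) "(Intercept)", x$covariate),
    estimate = c(if (!x$through_origin) x$intercept, x$slope)
  )
  sm <- summary(x$fit)$coefficients
  td$std_error <- sm[, 2]
  td$p_value <- sm[, 4]
  td
}

#' @rdname tidy_herbdecay
#' @export
glance.herb_regression <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         p_value = x$p_value, n = x$n, df_residual = x$df_residual)
}

#' @rdname tidy_herbdecay
#' @export
tidy.decay_rate_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$through_origin), mode = "through_origin"),
    dplyr::mutate(glance(x$free_intercept), mode = "free_intercept")
  ) |>
    dplyr::relocate("mode")
}

#' @rdname tidy_herbdecay
#' @export
glance.decay_rate_fit <- function(x, ...) {
  tibble(k = x$k, mode = x$mode, n = x$n,
         r_squared = x$through_origin$r_squared,
         p_value = x$through_origin$p_value,
         free_intercept = x$free_intercept$intercept)
}

#' @rdname tidy_herbdecay
#' @export
tidy.ancova_fit <- function(x, ...) {
  x$table
}

#' @rdname tidy_herbdecay
#' @export
glance.ancova_fit <- function(x, ...) {
  tibble(interaction_p = x$interaction_p,
         additive_factor_p = x$additive_factor_p,
         conclusion = x$conclusion, alpha = x$alpha, n = x$n)
}
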