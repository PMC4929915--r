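#' Simple linear regression with an optional through-origin mode
#'
#' Thin, typed wrapper around [stats::lm()] for the cohort-level
#' regressions (damage summaries on collection year or age). With an
#' intercept it reports the centred R-squared and the F-test p-value of
#' the slope; through the origin it omits the intercept and reports the
#' uncentred R-squared, as is standard for forced-origin fits.
#'
#' @param data data frame holding the variables.
#' @param response,covariate column names (tidy-eval, unquoted or strings).
#' @param through_origin force the line through the origin.
#' @return Object of class `herb_regression` wrapping the `lm` fit with
#'   fields `slope`, `intercept` (`NA` through origin), `r_squared`,
#'   `p_value`, `n`, `df_residual`. Supports `tidy()`/`glance()`.
#' @examples
#' d <- tibble::tibble(x = 1:10, y = 2e-4 * (1:10))
#' regress(d, y, x)$slope
#' @export
regress <- function(data, response, covariate, through_origin = FALSE) {
  yname <- as_name(enquo(response))
  xname <- as_name(enquo(covariate))
  d <- data[stats::complete.cases(data[, c(xname, yname)]), , drop = FALSE]
  n <- nrow(d)
  min_n <- if (through_origin) 2L else 3L
  if (n < min_n) stop_bad_arg(paste0("need at least ", min_n, " points"))
  x <- d[[xname]]
  if (length(unique(x)) < 2) stop_bad_arg("covariate is constant")
  fml <- if (through_origin) {
    stats::as.formula(paste(yname, "~", xname, "+ 0"))
  } else {
    stats::as.formula(paste(yname, "~", xname))
  }
  fit <- lm(fml, data = d)
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[[xname]])
  p <- unname(sm$coefficients[xname, 4])
  r2 <- sm$r.squared
  # a constant response carries no signal: define R^2 = 0 rather than
  # letting floating-point noise in the residuals decide
  if (!through_origin && stats::var(d[[yname]]) < .Machine$double.eps) {
    r2 <- 0
    p <- NA_real_
  }
  structure(
    list(fit = fit, slope = slope,
         intercept = if (through_origin) NA_real_ else unname(coef(fit)[1]),
         r_squared = r2,
         p_value = p, n = n, df_residual = fit$df.residual,
         response = yname, covariate = xname,
         through_origin = through_origin),
    class = "herb_regression"
  )
}

#' @export
print.herb_regression <- function(x, ...) {
  cat(sprintf(
    "<herb_regression> %s ~ %s%s: slope %.4g, R2 = %.3f, p = %.3g, n = %d\n",
    x$response, x$covariate, if (x$through_origin) " (through origin)" else "",
    x$slope, x$r_squared, x$p_value, x$n
  ))
  invisible(x)
}

#' Estimate the per-site per-year decay rate k
#'
#' Regresses per-sample damage fractions \eqn{\lambda} on sample age. The
#' model \eqn{\lambda = k \times age} has no intercept, so the headline
#' estimate is the through-origin slope; a free-intercept fit is computed
#' alongside as a sensitivity check (its intercept should be consistent
#' with zero when the model holds). Samples with a flagged low-quality
#' \eqn{\lambda} or non-positive age are excluded with a message.
#'
#' @param samples data frame with columns `age` and `lambda_hat` (optional
#'   `quality`, rows not `"ok"` dropped).
#' @param mode `"through_origin"` (default) or `"free_intercept"` headline.
#' @return Object of class `decay_rate_fit`: `k` (headline slope, per site
#'   per year), `mode`, `through_origin` and `free_intercept` (both
#'   `herb_regression` objects), `n`.
#' @examples
#' d <- tibble::tibble(age = c(50, 150, 278),
#'                     lambda_hat = 1.66e-4 * c(50, 150, 278))
#' estimate_decay_rate(d)$k
#' @export
estimate_decay_rate <- function(samples,
                                mode = c("through_origin", "free_intercept")) {
  mode <- match.arg(mode)
  d <- samples
  if ("quality" %in% names(d)) {
    bad <- !is.na(d$quality) & d$quality != "ok"
    if (any(bad)) {
      inform(paste0("excluding ", sum(bad), " sample(s) with flagged lambda"))
      d <- d[!bad, , drop = FALSE]
    }
  }
  zero <- !is.na(d$age) & d$age <= 0
  if (any(zero)) {
    inform(paste0("excluding ", sum(zero), " sample(s) with age <= 0"))
    d <- d[!zero, , drop = FALSE]
  }
  d <- d[stats::complete.cases(d[, c("age", "lambda_hat")]), , drop = FALSE]
  if (nrow(d) < 3) stop_bad_arg("fewer than 3 usable samples for the decay rate")
  to <- regress(d, lambda_hat, age, through_origin = TRUE)
  fi <- regress(d, lambda_hat, age, through_origin = FALSE)
  k <- if (mode == "through_origin") to$slope else fi$slope
  structure(
    list(k = k, mode = mode, through_origin = to, free_intercept = fi,
         n = nrow(d)),
    class = "decay_rate_fit"
  )
}

#' @export
print.decay_rate_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_rate_fit> k = %.4g per site per year (%s, n = %d)\n",
    x$k, x$mode, x$n
  ))
  cat(sprintf("  through-origin: k = %.4g (R2 = %.3f, p = %.3g)\n",
              x$through_origin$slope, x$through_origin$r_squared,
              x$through_origin$p_value))
  cat(sprintf("  free-intercept: k = %.4g, intercept = %.3g\n",
              x$free_intercept$slope, x$free_intercept$intercept))
  invisible(x)
}

#' Join per-sample damage statistics with metadata
#'
#' Builds the cohort analysis table: one row per sample (or per sample and
#' compartment when the statistics are split), carrying collection year,
#' age, lognormal length summaries, lambda, first-base C-to-T percentage,
#' purine folds and any factor columns. Every metadata row appears exactly
#' once per compartment — samples missing a statistic keep their row with
#' `NA` and are excluded only from the analyses that need that statistic.
#'
#' @param stats per-sample statistics tibble with a `sample_id` column
#'   (e.g. rows from [run_profile()]).
#' @param metadata sample table from [load_sample_table()].
#' @return Tibble, one row per sample (x compartment).
#' @export
cohort_table <- function(stats, metadata) {
  unmatched <- setdiff(stats$sample_id, metadata$sample_id)
  if (length(unmatched)) {
    stop_bad_arg(paste0("stats carry unknown sample id(s): ",
                        paste(unmatched, collapse = ", ")))
  }
  dplyr::left_join(metadata, stats, by = "sample_id")
}

#' Analysis of covariance for damage-versus-time regressions
#'
#' Fits `response ~ covariate * factor` by [stats::aov()] and reports the
#' sequential (Type I) ANOVA table, then tests the interaction by comparing
#' the full model against the additive `response ~ covariate + factor`.
#' A significant interaction means the factor levels differ in slope (e.g.
#' different decay rates); otherwise a significant factor term in the
#' additive model means the levels differ in intercept only (e.g. equal
#' deamination rate but different extent).
#'
#' @param data cohort table.
#' @param response,covariate,factor column names (tidy-eval).
#' @param alpha significance level for the interpretation flags
#'   (default 0.05).
#' @return Object of class `ancova_fit`: `table` (sequential ANOVA tibble),
#'   `comparison` (F-test of full vs additive), `additive_factor_p`,
#'   `conclusion` (`"slopes_differ"`, `"intercepts_differ"`, or
#'   `"no_difference"`), plus the two `lm`/`aov` fits.
#' @export
ancova <- function(data, response, covariate, factor, alpha = 0.05) {
  yname <- as_name(enquo(response))
  xname <- as_name(enquo(covariate))
  fname <- as_name(enquo(factor))
  d <- data[stats::complete.cases(data[, c(yname, xname, fname)]), , drop = FALSE]
  d[[fname]] <- base::factor(d[[fname]])
  lv <- levels(d[[fname]])
  if (length(lv) < 2) stop_bad_arg("factor needs at least 2 levels")
  counts <- table(d[[fname]])
  if (any(counts < 3)) stop_bad_arg("each factor level needs n >= 3")
  for (l in lv) {
    if (length(unique(d[[xname]][d[[fname]] == l])) < 2) {
      stop_bad_arg(paste0("covariate is constant within level ", l))
    }
  }
  full_fml <- stats::as.formula(paste(yname, "~", xname, "*", fname))
  add_fml <- stats::as.formula(paste(yname, "~", xname, "+", fname))
  full <- aov(full_fml, data = d)
  additive <- aov(add_fml, data = d)

  st <- summary(full)[[1]]
  tab <- tibble(
    term = trimws(rownames(st)),
    df = st[["Df"]],
    sum_sq = st[["Sum Sq"]],
    f_value = st[["F value"]],
    p_value = st[["Pr(>F)"]]
  )
  cmp <- anova(additive, full)
  interaction_p <- cmp[["Pr(>F)"]][2]
  st_add <- summary(additive)[[1]]
  additive_factor_p <- st_add[["Pr(>F)"]][trimws(rownames(st_add)) == fname]

  conclusion <- if (interaction_p < alpha) {
    "slopes_differ"
  } else if (additive_factor_p < alpha) {
    "intercepts_differ"
  } else {
    "no_difference"
  }
  structure(
    list(table = tab,
         comparison = tibble(
           f_value = cmp[["F"]][2], df = cmp[["Df"]][2],
           df_residual = cmp[["Res.Df"]][2], p_value = interaction_p
         ),
         interaction_p = interaction_p,
         additive_factor_p = additive_factor_p,
         conclusion = conclusion, alpha = alpha,
         full = full, additive = additive,
         response = yname, covariate = xname, factor = fname,
         n = nrow(d)),
    class = "ancova_fit"
  )
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf("<ancova_fit> %s ~ %s * %s (n = %d)\n",
              x$response, x$covariate, x$factor, x$n))
  print(as.data.frame(x$table), row.names = FALSE)
  cat(sprintf("full vs additive: F = %.3f, p = %.3g -> %s (alpha = %g)\n",
              x$comparison$f_value, x$interaction_p, x$conclusion, x$alpha))
  invisible(x)
}
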