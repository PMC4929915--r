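#' Fragment-length distribution
#'
#' Tallies fragment lengths (`end - start`) into a histogram, optionally
#' split by genomic compartment via a contig map. With merged reads the
#' read length equals the original molecule length, so this histogram is
#' the empirical \eqn{F(L)} of the exponential-decay model.
#'
#' @param reads alignment tibble with `start`, `end` (and `contig` when a
#'   compartment map is supplied).
#' @param compartments optional tibble (`contig`, `compartment`); when
#'   given, the result carries a `compartment` column and the per-
#'   compartment histograms sum to the pooled one.
#' @return Tibble with columns `length`, `n` (and `compartment` when
#'   requested), sorted by length.
#' @examples
#' r <- tibble::tibble(start = c(0, 0, 10), end = c(50, 50, 70))
#' length_distribution(r)
#' @export
length_distribution <- function(reads, compartments = NULL) {
  if (nrow(reads) == 0) stop_bad_arg("no reads: cannot build a length distribution")
  lens <- reads$end - reads$start
  if (is.null(compartments)) {
    out <- dplyr::count(tibble(length = lens), .data$length, name = "n")
  } else {
    comp <- setNames(compartments$compartment, compartments$contig)
    out <- tibble(length = lens, compartment = unname(comp[reads$contig])) |>
      dplyr::count(.data$compartment, .data$length, name = "n") |>
      dplyr::arrange(.data$compartment, .data$length)
  }
  out
}

#' Lognormal summary of a length distribution
#'
#' Closed-form maximum-likelihood fit of a lognormal to the histogram: the
#' count-weighted mean and (uncorrected) standard deviation of log lengths.
#' The distribution's median is `exp(log_mean)` exactly — the summary used
#' to regress fragment length on collection year, with the median reported
#' because it is the more intuitive scale.
#'
#' @param dist length histogram from [length_distribution()] (columns
#'   `length`, `n`).
#' @param min_n minimum number of reads required (default 30).
#' @return Object of class `lognormal_fit` with fields `log_mean`,
#'   `log_sd`, `median`, `n`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @examples
#' d <- tibble::tibble(length = c(40, 50, 60), n = c(100, 200, 100))
#' fit_lognormal(d, min_n = 10)$median
#' @export
fit_lognormal <- function(dist, min_n = 30) {
  n <- sum(dist$n)
  if (n < min_n) {
    stop_bad_arg(paste0("only ", n, " reads; need at least ", min_n,
                        " for a lognormal summary"))
  }
  if (any(dist$length < 1)) stop_bad_arg("all lengths must be >= 1")
  lx <- log(dist$length)
  w <- dist$n
  log_mean <- sum(w * lx) / n
  log_sd <- sqrt(sum(w * (lx - log_mean)^2) / n)
  structure(
    list(log_mean = log_mean, log_sd = log_sd,
         median = exp(log_mean), n = n),
    class = "lognormal_fit"
  )
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("<lognormal_fit> log-mean %.4f (sd %.4f), median %.1f bp, n = %d\n",
              x$log_mean, x$log_sd, x$median, x$n))
  invisible(x)
}

#' Select the exponential-tail window of a length histogram
#'
#' The empirical length distribution has a mode created by length-dependent
#' recovery; only lengths beyond it decline exponentially. The window runs
#' from the global mode plus `mode_offset` (ties across modes resolve to
#' the smallest modal length, with a warning) up to the largest length whose
#' count still reaches `min_count`. `min_start` forces the lower edge
#' further right, e.g. past a known recovery-filter region.
#'
#' @param dist length histogram (`length`, `n`).
#' @param min_count minimum count for the upper window edge (default 10).
#' @param mode_offset bp added to the modal length (default 5).
#' @param min_start optional hard lower bound for the window start.
#' @return Integer vector `c(L_lo, L_hi)`.
#' @export
select_tail_window <- function(dist, min_count = 10, mode_offset = 5,
                               min_start = NULL) {
  modes <- dist$length[dist$n == max(dist$n)]
  if (length(modes) > 1) {
    warn(paste0("length histogram has ", length(modes),
                " modal lengths; using the smallest (", min(modes), " bp)"))
  }
  l_lo <- min(modes) + mode_offset
  if (!is.null(min_start)) l_lo <- max(l_lo, min_start)
  heavy <- dist$length[dist$n >= min_count]
  if (!length(heavy)) stop_bad_arg("no length reaches min_count")
  l_hi <- max(heavy)
  n_bins <- sum(dist$length >= l_lo & dist$length <= l_hi)
  if (n_bins < 10) {
    stop_bad_arg(paste0(
      "tail window [", l_lo, ", ", l_hi, "] holds only ", n_bins,
      " populated bins; supply a window manually via fit_decay(window = ...)"
    ))
  }
  c(as.integer(l_lo), as.integer(l_hi))
}

#' Fit the exponential decline of the length distribution
#'
#' Ordinary least squares of log count on length over the tail window:
#' `log F(L) = log F0 - lambda * L`. The magnitude of the slope is the
#' per-bond damage fraction `lambda_hat` for the sample. Zero-count bins
#' are absent from the histogram and therefore dropped (log undefined);
#' the number of populated bins used is recorded. The default fit is
#' unweighted; `weighting = "count"` weights bins by their counts as a
#' sensitivity option.
#'
#' @param dist length histogram (`length`, `n`).
#' @param window integer `c(L_lo, L_hi)`; defaults to
#'   [select_tail_window()] on `dist`.
#' @param weighting `"none"` (default) or `"count"`.
#' @return Object of class `decay_fit`: `lambda_hat`, `log_F0`, `window`,
#'   `r_squared`, `n_bins`, `quality` (`"ok"` or `"nonpositive_slope"`).
#'   Supports [generics::tidy()] and [generics::glance()].
#' @examples
#' d <- tibble::tibble(length = 40:140,
#'                     n = round(1e6 * exp(-0.02 * (40:140))))
#' fit_decay(d, window = c(40, 140))$lambda_hat
#' @export
fit_decay <- function(dist, window = NULL, weighting = c("none", "count")) {
  weighting <- match.arg(weighting)
  if (is.null(window)) window <- select_tail_window(dist)
  if (window[1] >= window[2]) stop_bad_arg("window must satisfy L_lo < L_hi")
  sub <- dist[dist$length >= window[1] & dist$length <= window[2] & dist$n > 0, ]
  if (nrow(sub) < 10) {
    stop_bad_arg(paste0("only ", nrow(sub), " usable bins in window; need >= 10"))
  }
  w <- if (weighting == "count") sub$n else NULL
  fit <- lm(log(n) ~ length, data = sub, weights = w)
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  lambda <- -slope
  quality <- "ok"
  if (lambda <= 0) {
    warn("non-negative slope in tail window: lambda_hat <= 0, flagged")
    quality <- "nonpositive_slope"
  }
  structure(
    list(lambda_hat = lambda,
         log_F0 = unname(coef(fit)[1]),
         window = as.integer(window),
         r_squared = sm$r.squared,
         n_bins = nrow(sub),
         quality = quality),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> lambda = %.3g per bond (window %d-%d bp, %d bins, R2 = %.3f%s)\n",
    x$lambda_hat, x$window[1], x$window[2], x$n_bins, x$r_squared,
    if (x$quality != "ok") paste0(", ", x$quality) else ""
  ))
  invisible(x)
}
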