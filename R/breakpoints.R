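#' Base composition upstream of 5' break points
#'
#' Tallies the reference base at positions -10..-1 relative to each read's
#' first aligned base, in read orientation (minus-strand contexts are
#' reverse-complemented by [annotate_alignments()], so position -1 is
#' always the base immediately 5' of the break). Depurination leaves an
#' excess of A/G at -1 relative to the background positions. Context-
#' truncated reads are skipped; non-ACGT characters are excluded from that
#' position's tally only.
#'
#' @param reads annotated alignment tibble (needs `upstream_context`,
#'   `context_truncated`).
#' @param compartments optional contig-to-compartment tibble; adds a
#'   `compartment` column with per-compartment profiles.
#' @return Tibble with `position` (-10..-1), `base`, `count`, `freq`
#'   (frequencies over A/C/G/T sum to 1 at each position); attribute
#'   `n_reads_used`.
#' @export
composition_profile <- function(reads, compartments = NULL) {
  if (!"upstream_context" %in% names(reads)) {
    stop_bad_arg("reads lack upstream_context; run annotate_alignments() first")
  }
  use <- reads[!reads$context_truncated, , drop = FALSE]
  if (nrow(use) == 0) stop_bad_arg("all reads are context-truncated")

  if (!is.null(compartments)) {
    comp <- setNames(compartments$compartment, compartments$contig)
    grp <- unname(comp[use$contig])
    parts <- lapply(split(seq_len(nrow(use)), grp), function(i) {
      composition_tally(use$upstream_context[i])
    })
    out <- dplyr::bind_rows(parts, .id = "compartment")
  } else {
    out <- composition_tally(use$upstream_context)
  }
  attr(out, "n_reads_used") <- nrow(use)
  out
}

# context strings all share length K; character j corresponds to position
# -(K - j + 1), i.e. the last character is position -1
composition_tally <- function(contexts) {
  K <- unique(nchar(contexts))
  if (length(K) != 1) stop_bad_arg("upstream contexts have unequal lengths")
  raw <- charToRaw(paste(contexts, collapse = ""))
  code <- raw_to_code(raw)
  posj <- rep_len(seq_len(K), length(raw))
  keep <- !is.na(code)
  tab <- tabulate((posj[keep] - 1L) * 4L + code[keep], nbins = 4L * K)
  out <- tibble(
    position = rep(seq_len(K) - K - 1L, each = 4L),
    base = rep(DNA_BASES, K),
    count = tab
  )
  out |>
    dplyr::group_by(.data$position) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}

#' Purine fold enrichment at the break point
#'
#' The relative enrichment of adenine and of guanine immediately 5' of the
#' break: frequency at position -1 divided by the frequency at a background
#' position (default -5, far enough from the break to be unaffected).
#' Standard errors come from the delta method on the binomial ratio, for
#' use in downstream regressions on collection year.
#'
#' @param profile output of [composition_profile()] (a single profile; run
#'   per compartment for split data).
#' @param background background position (default -5).
#' @return Tibble with one row per purine: `base`, `fold`, `se`,
#'   `freq_target`, `freq_background`, `n_target`, `n_background`.
#' @export
purine_enrichment <- function(profile, background = -5) {
  needed <- c(-1, background)
  if (!all(needed %in% profile$position)) {
    stop_bad_arg("profile lacks position -1 or the background position")
  }
  per_base <- function(b) {
    p1 <- profile[profile$position == -1 & profile$base == b, ]
    p5 <- profile[profile$position == background & profile$base == b, ]
    n1 <- sum(profile$count[profile$position == -1])
    n5 <- sum(profile$count[profile$position == background])
    if (p5$freq == 0) {
      stop_bad_arg(paste0("zero ", b, " frequency at background position ",
                          background, ": fold undefined"))
    }
    fold <- p1$freq / p5$freq
    # delta method on log fold of two independent binomial proportions
    v <- (1 - p1$freq) / (n1 * p1$freq) + (1 - p5$freq) / (n5 * p5$freq)
    tibble(base = b, fold = fold, se = fold * sqrt(v),
           freq_target = p1$freq, freq_background = p5$freq,
           n_target = n1, n_background = n5)
  }
  dplyr::bind_rows(per_base("A"), per_base("G"))
}
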