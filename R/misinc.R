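#' Position-wise nucleotide misincorporation profile
#'
#' For the first `P` positions from each read end, counts every ref-to-read
#' base change conditional on the reference base at that position (the
#' mapDamage convention, which makes the statistic independent of depth and
#' base composition). Position 1 at the 5' end is the read's first base;
#' position 1 at the 3' end is its last. Reads shorter than `P` contribute
#' to positions up to their length. `N` in read or reference is skipped.
#'
#' @param reads annotated alignment tibble (needs `read_bases`,
#'   `ref_bases`).
#' @param P positions profiled from each end (default 25).
#' @param compartments optional contig-to-compartment tibble for split
#'   profiles.
#' @return Tibble with `end` (`"5p"`/`"3p"`), `position`, `ref`, `read`,
#'   `count`, `denominator` (reference-base occurrences at that position),
#'   `freq`, restricted to the 12 substitution types. Rows with a zero
#'   denominator carry `freq = NA` and are flagged implicitly.
#' @export
misincorporation_profile <- function(reads, P = 25L, compartments = NULL) {
  if (!all(c("read_bases", "ref_bases") %in% names(reads))) {
    stop_bad_arg("reads lack read_bases/ref_bases; run annotate_alignments() first")
  }
  if (!is.null(compartments)) {
    comp <- setNames(compartments$compartment, compartments$contig)
    grp <- unname(comp[reads$contig])
    parts <- lapply(split(seq_len(nrow(reads)), grp), function(i) {
      misinc_tally(reads$read_bases[i], reads$ref_bases[i], P)
    })
    return(dplyr::bind_rows(parts, .id = "compartment"))
  }
  misinc_tally(reads$read_bases, reads$ref_bases, P)
}

# flat tally over (end, position, ref, read) via integer encoding
misinc_tally <- function(read_bases, ref_bases, P) {
  lens <- nchar(read_bases)
  stopifnot(all(lens == nchar(ref_bases)))
  n <- length(read_bases)
  raw_read <- charToRaw(paste(read_bases, collapse = ""))
  raw_ref <- charToRaw(paste(ref_bases, collapse = ""))
  offsets <- cumsum(lens) - lens
  k <- pmin(lens, as.integer(P))
  within <- sequence(k)
  idx5 <- rep.int(offsets, k) + within
  idx3 <- rep.int(offsets + lens, k) - within + 1L

  tally_one <- function(idx, pos) {
    rc <- raw_to_code(raw_ref[idx])
    qc <- raw_to_code(raw_read[idx])
    keep <- !is.na(rc) & !is.na(qc)
    cell <- (pos[keep] - 1L) * 16L + (rc[keep] - 1L) * 4L + qc[keep]
    tabulate(cell, nbins = 16L * P)
  }
  t5 <- tally_one(idx5, within)
  t3 <- tally_one(idx3, within)

  grid <- tibble(
    position = rep(seq_len(P), each = 16L),
    ref = rep(rep(DNA_BASES, each = 4L), P),
    read = rep(DNA_BASES, 4L * P)
  )
  build <- function(tab, end_label) {
    g <- grid
    g$count <- tab
    g$end <- end_label
    g |>
      dplyr::group_by(.data$position, .data$ref) |>
      dplyr::mutate(denominator = sum(.data$count)) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$ref != .data$read) |>
      dplyr::mutate(freq = ifelse(.data$denominator > 0,
                                  .data$count / .data$denominator, NA_real_))
  }
  dplyr::bind_rows(build(t5, "5p"), build(t3, "3p")) |>
    dplyr::select("end", "position", "ref", "read", "count",
                  "denominator", "freq") |>
    dplyr::arrange(dplyr::desc(.data$end), .data$position, .data$ref, .data$read)
}

#' First-base C-to-T percentage
#'
#' The deamination proxy: the percentage of reads whose reference base at
#' 5' position 1 is C but which read T there, on the 0-100 scale. This is
#' the quantity regressed on collection year to date deamination damage.
#'
#' @param profile output of [misincorporation_profile()] (single profile).
#' @return Object of class `deamination_stat`: `ct_first_pct`,
#'   `denominator`.
#' @export
first_base_ct <- function(profile) {
  row <- profile[profile$end == "5p" & profile$position == 1 &
                   profile$ref == "C" & profile$read == "T", ]
  if (nrow(row) != 1) {
    stop_bad_arg("profile lacks the (5p, position 1, C->T) cell")
  }
  if (row$denominator == 0) {
    stop_bad_arg("no reference C at 5' position 1: percentage undefined")
  }
  structure(
    list(ct_first_pct = 100 * row$freq, denominator = row$denominator),
    class = "deamination_stat"
  )
}

#' @export
print.deamination_stat <- function(x, ...) {
  cat(sprintf("<deamination_stat> C->T at first base: %.2f%% (n = %d)\n",
              x$ct_first_pct, x$denominator))
  invisible(x)
}
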