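#' Simulate a cohort of damaged samples
#'
#' Runs [generate_reference()] once and [simulate_sample()] once per age in
#' the config, deriving each sample's ground truth `lambda_true = k_true *
#' age` and its RNG substream from the master seed by a stable offset. When
#' `outdir` is given, also writes the reference FASTA, one coordinate-sorted
#' SAM per sample, a sample-metadata TSV (`sample_id`, `collection_year`,
#' `path`, plus a compartment map TSV), and a ground-truth JSON.
#'
#' @param config a [sim_config()] with at least two distinct ages.
#' @param outdir optional output directory (created if missing).
#' @return A list of class `sim_cohort`: `reference` (`sim_reference`),
#'   `reads` (named list of per-sample alignment tibbles), `truth`
#'   ([sample_truth()] tibble), `samples` (sample-metadata tibble), and
#'   `paths` (named file paths when `outdir` was given).
#' @examples
#' cfg <- sim_config(ages = c(50, 250), n_reads = 300, reference_length = 20000)
#' coh <- simulate_cohort(cfg)
#' coh$truth$lambda_true
#' @export
simulate_cohort <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(unique(config$ages)) < 2) {
    stop_bad_arg("a cohort needs at least two distinct ages")
  }
  truth <- sample_truth(config)
  if (anyDuplicated(truth$sample_id)) stop_bad_arg("duplicate sample ids")
  reference <- generate_reference(config)

  reads <- vector("list", nrow(truth))
  names(reads) <- truth$sample_id
  for (i in seq_len(nrow(truth))) {
    reads[[i]] <- simulate_sample(reference, truth[i, ], config,
                                  seed = config$seed + 1009L * i)
  }

  samples <- tibble(
    sample_id = truth$sample_id,
    collection_year = truth$collection_year,
    path = NA_character_
  )

  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fasta <- file.path(outdir, "reference.fasta")
    write_reference_fasta(reference, fasta)
    sam_paths <- file.path(outdir, paste0(truth$sample_id, ".sam"))
    for (i in seq_along(reads)) {
      write_sam(reads[[i]], reference, sam_paths[i])
    }
    samples$path <- sam_paths
    comp_path <- file.path(outdir, "compartments.tsv")
    readr::write_tsv(compartment_map(reference), comp_path)
    table_path <- file.path(outdir, "samples.tsv")
    readr::write_tsv(samples, table_path)
    truth_path <- file.path(outdir, "truth.json")
    jsonlite::write_json(truth, truth_path, digits = NA, auto_unbox = FALSE)
    paths <- list(fasta = fasta, sample_table = table_path,
                  compartments = comp_path, truth = truth_path,
                  alignments = setNames(sam_paths, truth$sample_id))
  }

  structure(
    list(reference = reference, reads = reads, truth = truth,
         samples = samples, paths = paths),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", length(x$reads), " samples, ages ",
      paste(range(x$truth$age), collapse = "-"), " yr\n", sep = "")
  invisible(x)
}

#' Write simulated alignments to a SAM file
#'
#' Emits a coordinate-sorted SAM with a proper header; all records are
#' full-match CIGARs (the simulator produces no indels) with constant base
#' quality. Minus-strand records carry flag 16 and plus-strand bases, per
#' the SAM convention.
#'
#' @param reads alignment tibble from [simulate_sample()].
#' @param reference the `sim_reference` the reads were drawn from.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, reference, path) {
  ord <- order(match(reads$contig, names(reference$seq)), reads$start)
  r <- reads[ord, ]
  len <- r$end - r$start
  hdr <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(reference$seq), nchar(reference$seq))
  )
  rec <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
    r$qname, ifelse(r$strand == "-", 16L, 0L), r$contig, r$start + 1L,
    r$mapq, len, r$seq, strrep("I", len)
  )
  writeLines(c(hdr, rec), path)
  invisible(path)
}
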