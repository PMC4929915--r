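#' Generate a random reference genome
#'
#' Draws i.i.d. bases at the configured G+C content for each contig and
#' attaches the contig-to-compartment map. Deterministic for a fixed
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return An object of class `sim_reference`: a list with `seq` (named
#'   character vector of contig sequences) and `compartment` (named
#'   character vector, `"nuclear"`/`"organelle"` per contig).
#' @examples
#' cfg <- sim_config(ages = 100, reference_length = 10000)
#' ref <- generate_reference(cfg)
#' nchar(ref$seq)
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gc <- config$gc_content
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- vapply(config$reference_length, function(len) {
    paste(sample(DNA_BASES, len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  names(seqs) <- names(config$contig_compartments)
  structure(
    list(seq = seqs, compartment = config$contig_compartments),
    class = "sim_reference"
  )
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("<sim_reference> ", length(x$seq), " contig(s), ",
      sum(nchar(x$seq)), " bp total\n", sep = "")
  invisible(x)
}

#' Write a reference to FASTA
#'
#' @param reference a `sim_reference`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  stopifnot(inherits(reference, "sim_reference"))
  dss <- Biostrings::DNAStringSet(reference$seq)
  Biostrings::writeXStringSet(dss, path, width = 70L)
  invisible(path)
}

#' Compartment map as a tibble
#'
#' @param reference a `sim_reference`.
#' @return tibble with columns `contig`, `compartment`.
#' @export
compartment_map <- function(reference) {
  tibble(
    contig = names(reference$compartment),
    compartment = unname(reference$compartment)
  )
}
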