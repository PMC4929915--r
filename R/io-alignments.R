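#' Load merged-read alignments from SAM/BAM
#'
#' Reads a SAM or BAM file (SAM is converted on the fly via
#' [Rsamtools::asBam()]), drops unmapped, secondary and supplementary
#' records, records below `min_mapq`, and records whose CIGAR contains
#' anything but a single match run (indels and clips would break the
#' end-anchored positional damage statistics). Counts of dropped records
#' are reported as a message and attached as attribute `filter_counts`.
#'
#' @param alignment_path SAM or BAM file.
#' @param fasta_path reference FASTA (contig names must match).
#' @param min_mapq minimum mapping quality (default 25).
#' @param compartment_filter optional compartment label; with a
#'   `compartments` map supplied, only contigs of that compartment are kept.
#' @param compartments optional tibble (`contig`, `compartment`) used by
#'   `compartment_filter`.
#' @param annotate if `TRUE` (default) the result is passed through
#'   [annotate_alignments()] so each record carries read-oriented bases and
#'   upstream context.
#' @return Alignment tibble: `qname`, `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `seq`, `mapq`, plus annotation columns when
#'   `annotate = TRUE`.
#' @export
load_alignments <- function(alignment_path, fasta_path, min_mapq = 25,
                            compartment_filter = NULL, compartments = NULL,
                            annotate = TRUE) {
  if (!file.exists(alignment_path)) {
    stop_bad_arg(paste0("alignment file not found: ", alignment_path))
  }
  bam <- alignment_path
  if (grepl("\\.sam$", alignment_path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(alignment_path, dest, overwrite = TRUE,
                       indexDestination = FALSE)
    )
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar", "seq")
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n0 <- length(rec$qname)
  if (n0 == 0) stop_bad_arg("no mapped primary alignments in file")

  mapq_ok <- !is.na(rec$mapq) & rec$mapq >= min_mapq
  cigar_ok <- grepl("^\\d+M$", rec$cigar)
  keep <- mapq_ok & cigar_ok
  counts <- c(
    total = n0,
    dropped_mapq = sum(!mapq_ok),
    dropped_cigar = sum(mapq_ok & !cigar_ok),
    kept = sum(keep)
  )
  if (counts[["kept"]] == 0) stop_bad_arg("no alignments survive the filters")

  out <- tibble(
    qname = rec$qname[keep],
    contig = as.character(rec$rname)[keep],
    start = rec$pos[keep] - 1L,
    end = rec$pos[keep] - 1L +
      as.integer(sub("M$", "", rec$cigar[keep])),
    strand = as.character(rec$strand)[keep],
    seq = as.character(rec$seq)[keep],
    mapq = rec$mapq[keep]
  )
  if (!is.null(compartment_filter)) {
    if (is.null(compartments)) {
      stop_bad_arg("compartment_filter requires a `compartments` map")
    }
    keep_contigs <- compartments$contig[compartments$compartment == compartment_filter]
    out <- dplyr::filter(out, .data$contig %in% keep_contigs)
  }
  inform(sprintf(
    "loaded %d/%d alignments (%d below mapq %s, %d with indel/clip CIGARs)",
    nrow(out), n0, counts[["dropped_mapq"]], format(min_mapq),
    counts[["dropped_cigar"]]
  ))
  attr(out, "filter_counts") <- counts
  if (annotate) out <- annotate_alignments(out, fasta_path)
  attr(out, "filter_counts") <- counts
  out
}

#' Annotate alignments with read-oriented bases and upstream context
#'
#' Adds, per record: `length`; `read_bases` and `ref_bases` in read
#' orientation (minus-strand records reverse-complemented, so position 1 is
#' always the 5' first base of the original molecule); `upstream_context`,
#' the `context_size` reference bases immediately 5' of the read's first
#' base in read orientation (for minus-strand reads the reverse complement
#' of the reference just 3' of the mapped interval, so position -1 is the
#' last character); and `context_truncated`, flagged when the context would
#' run off the contig.
#'
#' @param reads alignment tibble (`contig`, `start`, `end`, `strand`, `seq`).
#' @param reference a `sim_reference`, a named character vector, a
#'   [Biostrings::DNAStringSet], or a FASTA path.
#' @param context_size upstream context length (default 10).
#' @return The input tibble with annotation columns appended.
#' @export
annotate_alignments <- function(reads, reference, context_size = 10L) {
  seqs <- reference_as_strings(reference)
  missing <- setdiff(unique(reads$contig), names(seqs))
  if (length(missing)) {
    stop_bad_arg(paste0("contig(s) absent from reference: ",
                        paste(missing, collapse = ", ")))
  }
  clen <- nchar(seqs)[reads$contig]
  full <- unname(seqs[reads$contig])
  start <- reads$start
  end <- reads$end

  ref_seg <- substring(full, start + 1L, end)
  minus <- reads$strand == "-"
  read_bases <- reads$seq
  ref_bases <- ref_seg
  if (any(minus)) {
    read_bases[minus] <- revcomp(read_bases[minus])
    ref_bases[minus] <- revcomp(ref_bases[minus])
  }

  up <- character(nrow(reads))
  trunc <- logical(nrow(reads))
  plus <- !minus
  trunc[plus] <- start[plus] < context_size
  up[plus] <- substring(full[plus], pmax(start[plus] - context_size, 0L) + 1L,
                        start[plus])
  trunc[minus] <- end[minus] + context_size > clen[minus]
  if (any(minus)) {
    up_plus <- substring(full[minus], end[minus] + 1L,
                         pmin(end[minus] + context_size, clen[minus]))
    up[minus] <- revcomp(up_plus)
  }

  reads$length <- end - start
  reads$read_bases <- unname(read_bases)
  reads$ref_bases <- unname(ref_bases)
  reads$upstream_context <- unname(up)
  reads$context_truncated <- unname(trunc)
  reads
}

# Normalise the many acceptable reference representations to a named
# character vector of contig sequences.
reference_as_strings <- function(reference) {
  if (inherits(reference, "sim_reference")) return(reference$seq)
  if (inherits(reference, "DNAStringSet")) {
    s <- as.character(reference)
    names(s) <- sub("\\s.*$", "", names(reference))
    return(s)
  }
  if (is.character(reference) && length(reference) == 1 && file.exists(reference)) {
    dss <- Biostrings::readDNAStringSet(reference)
    s <- as.character(dss)
    names(s) <- sub("\\s.*$", "", names(dss))
    return(s)
  }
  if (is.character(reference) && !is.null(names(reference))) return(reference)
  stop_bad_arg("unsupported reference representation")
}
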