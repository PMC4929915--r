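#' Collapse coordinate duplicates to consensus reads
#'
#' PCR duplicates are identified by identical (contig, start, end, strand)
#' and each cluster is replaced by a single consensus record: at every
#' position the majority base wins, and ties become `'N'`. The cluster size
#' is recorded in `cluster_size`. Deduplication is idempotent and an empty
#' input returns an empty output. Annotation columns (read-oriented bases,
#' context) are dropped if present — re-annotate after deduplication.
#'
#' @param reads alignment tibble with `qname`, `contig`, `start`, `end`,
#'   `strand`, `seq`, `mapq`.
#' @return Tibble with one record per coordinate cluster plus
#'   `cluster_size`.
#' @examples
#' r <- tibble::tibble(
#'   qname = c("a", "b", "c"), contig = "c1", start = 0L, end = 4L,
#'   strand = "+", seq = c("ACGT", "ACGT", "ACAT"), mapq = 60L
#' )
#' deduplicate(r)$seq  # majority consensus "ACGT"
#' @export
deduplicate <- function(reads) {
  core <- c("qname", "contig", "start", "end", "strand", "seq", "mapq")
  if (nrow(reads) == 0) {
    out <- reads[, intersect(core, names(reads)), drop = FALSE]
    out$cluster_size <- integer(0)
    return(as_tibble(out))
  }
  reads <- reads[, intersect(core, names(reads)), drop = FALSE]
  key <- paste(reads$contig, reads$start, reads$end, reads$strand, sep = "\r")
  sizes <- table(key)
  dup_keys <- names(sizes)[sizes > 1]

  first <- !duplicated(key)
  out <- reads[first, , drop = FALSE]
  out$cluster_size <- as.integer(sizes[key[first]])

  if (length(dup_keys)) {
    idx_by_key <- split(seq_len(nrow(reads)), key)
    for (k in dup_keys) {
      members <- idx_by_key[[k]]
      cons <- consensus_seq(reads$seq[members])
      out$seq[match(k, key[first])] <- cons
    }
  }
  out <- out[order(out$contig, out$start, out$end, out$strand), , drop = FALSE]
  as_tibble(out)
}

# Majority base per column; ties -> 'N'. All sequences in a coordinate
# cluster share one length by construction.
consensus_seq <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  cons <- apply(mat, 2, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) "N" else names(tab)[1]
  })
  paste(cons, collapse = "")
}
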