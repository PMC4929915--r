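# 60 bp hand-built reference: every coordinate convention is checked
# against positions placed by hand.
make_toy <- function() {
  b <- rep("A", 60)
  b[11:20] <- strsplit("CCCCCCTTGA", "")[[1]]  # context of the plus read
  b[21:30] <- strsplit("ACGTACGTAC", "")[[1]]  # plus read body
  b[31:40] <- strsplit("GGTTCCAAGT", "")[[1]]  # minus read body
  b[41] <- "G"                                  # -1 of the minus read = C
  b[42:51] <- strsplit("ATATATATAT", "")[[1]]
  ref <- toy_reference(c(c1 = paste(b, collapse = "")))
  ref
}

test_that("annotation applies the stated coordinate conventions", {
  ref <- make_toy()
  reads <- toy_alignments(
    contig = "c1",
    start = c(20, 30, 5),
    end = c(30, 40, 15),
    strand = c("+", "-", "+"),
    seq = c("ACGTACGTAC", "GGTTCCAAGT", substring(ref$seq, 6, 15))
  )
  ann <- annotate_alignments(reads, ref)

  # plus-strand read: upstream context ends "TTGA", so position -1 is 'A'
  expect_identical(ann$upstream_context[1], "CCCCCCTTGA")
  expect_identical(substring(ann$upstream_context[1], 10, 10), "A")
  expect_identical(ann$read_bases[1], ann$ref_bases[1])

  # minus-strand read: position -1 is the complement of the reference base
  # immediately 3' of the mapped interval (ref[41] = 'G' -> 'C')
  expect_identical(substring(ann$upstream_context[2], 10, 10), "C")
  expect_identical(ann$read_bases[2], as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("GGTTCCAAGT"))
  ))

  # read too close to the contig start is context-truncated
  expect_true(ann$context_truncated[3])
  expect_false(any(ann$context_truncated[1:2]))

  expect_error(
    annotate_alignments(dplyr::mutate(reads, contig = "nope"), ref),
    "absent"
  )
})

test_that("SAM loading filters unmapped/secondary/low-mapq/clipped records", {
  ref <- make_toy()
  fasta <- write_toy_fasta(ref)
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:c1\tLN:60",
    "keep1\t0\tc1\t21\t60\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
    "keep2\t16\tc1\t31\t60\t10M\t*\t0\t0\tGGTTCCAAGT\tIIIIIIIIII",
    "lowq\t0\tc1\t21\t5\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
    "clip\t0\tc1\t21\t60\t5S5M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
    "indel\t0\tc1\t21\t60\t5M1D5M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
    "second\t256\tc1\t21\t60\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
    "unmap\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII"
  ), sam)
  reads <- suppressMessages(load_alignments(sam, fasta, min_mapq = 25))
  expect_setequal(reads$qname, c("keep1", "keep2"))
  counts <- attr(reads, "filter_counts")
  expect_identical(unname(counts["dropped_mapq"]), 1L)
  expect_identical(unname(counts["dropped_cigar"]), 2L)
  expect_identical(reads$start[reads$qname == "keep1"], 20L)
  expect_identical(reads$end[reads$qname == "keep1"], 30L)
  expect_identical(reads$strand[reads$qname == "keep2"], "-")
  expect_error(suppressMessages(load_alignments(sam, fasta, min_mapq = 99)),
               "survive")
})

test_that("deduplication takes majority consensus with ties as N", {
  r0 <- toy_alignments("c1", c(0, 5), c(4, 9), "+", c("ACGT", "ACGT"))
  expect_identical(deduplicate(r0)$seq, r0$seq)  # no shared coordinates

  r3 <- toy_alignments("c1", rep(0, 3), rep(4, 3), "+",
                       c("ACTT", "ACTT", "ACCT"))
  d3 <- deduplicate(r3)
  expect_identical(nrow(d3), 1L)
  expect_identical(d3$seq, "ACTT")      # {T,T,C} majority at site 3
  expect_identical(d3$cluster_size, 3L)

  r2 <- toy_alignments("c1", rep(0, 2), rep(4, 2), "+", c("ACTT", "ACCT"))
  expect_identical(deduplicate(r2)$seq, "ACNT")  # 1-1 tie

  # idempotence, and strand separates clusters
  rs <- toy_alignments("c1", rep(0, 2), rep(4, 2), c("+", "-"),
                       c("ACTT", "ACCT"))
  once <- deduplicate(rs)
  expect_identical(deduplicate(once), once)
  expect_identical(nrow(once), 2L)

  empty <- deduplicate(r0[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("simulator output round-trips through SAM byte-faithfully", {
  cfg <- sim_config(ages = 120, k_true = 1e-4, n_reads = 1500,
                    reference_length = 40000, seed = 77)
  ref <- generate_reference(cfg)
  reads <- simulate_sample(ref, sample_truth(cfg)[1, ], cfg)
  dir <- tempfile(); dir.create(dir)
  fasta <- file.path(dir, "ref.fasta")
  write_reference_fasta(ref, fasta)
  sam <- file.path(dir, "s.sam")
  write_sam(reads, ref, sam)

  back <- suppressMessages(load_alignments(sam, fasta, min_mapq = 0,
                                           annotate = FALSE))
  expect_identical(nrow(back), nrow(reads))
  ord <- order(back$qname); ord0 <- order(reads$qname)
  expect_identical(back$start[ord], reads$start[ord0])
  expect_identical(back$end[ord], reads$end[ord0])
  expect_identical(back$seq[ord], reads$seq[ord0])
  expect_identical(back$strand[ord], reads$strand[ord0])

  # fragment lengths exactly equal the simulator's internal tally
  tal <- attr(reads, "length_tally")
  obs <- table(back$end - back$start)
  expect_identical(as.integer(obs), unname(tal))
  expect_identical(names(obs), names(tal))
})

test_that("sample tables derive age and reject malformed input", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcollection_year\textraction_method",
               "s1\t1737\tCTAB", "s2\t1993\tPTB", "s3\tNA\tCTAB"), tsv)
  tab <- suppressMessages(load_sample_table(tsv, reference_year = 2015))
  expect_identical(nrow(tab), 2L)            # missing year rejected
  expect_identical(tab$age[tab$sample_id == "s1"], 278)
  expect_identical(tab$extraction_method, c("CTAB", "PTB"))

  writeLines(c("sample_id\tcollection_year", "s1\t2015"), tsv)
  expect_warning(load_sample_table(tsv, reference_year = 2015), "age 0")

  writeLines(c("sample_id\tcollection_year", "s1\t2020"), tsv)
  expect_error(load_sample_table(tsv, reference_year = 2015), "later")

  writeLines(c("sample_id\tcollection_year", "s1\t1900", "s1\t1901"), tsv)
  expect_error(load_sample_table(tsv, reference_year = 2015), "duplicate")
})
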