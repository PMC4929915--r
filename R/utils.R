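# Shared low-level helpers. Sequences are plain uppercase character strings
# internally; Biostrings is used at file boundaries (FASTA/BAM) and for
# reverse complements.

DNA_BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

#' Reverse-complement character sequences
#' @param x character vector of DNA strings (ACGTN).
#' @return character vector of the same length.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# complement without reversal, single characters vectorised
comp_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
}

# raw byte codes for the four bases, used by the flat-vector engines
RAW_A <- charToRaw("A")
RAW_C <- charToRaw("C")
RAW_G <- charToRaw("G")
RAW_T <- charToRaw("T")
RAW_BASES <- charToRaw(paste(DNA_BASES, collapse = ""))

# map raw bytes to 1..4 (A,C,G,T), NA otherwise
raw_to_code <- function(r) {
  code <- match(r, RAW_BASES)
  code
}

stop_bad_arg <- function(msg) rlang::abort(msg, class = "herbdecay_bad_arg")

`%||%` <- function(a, b) if (is.null(a)) b else a
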