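#' Simulate damaged reads for one sample
#'
#' Generates `config$n_reads` merged-read alignments from `reference` under
#' the post-mortem damage model: fragment lengths are geometric with
#' per-bond break probability `lambda_true` (truncated by redraw to
#' `[min_len, max_len]`), retention is logistic in length (the recovery
#' filter), candidate fragments are accepted with probability proportional
#' to the break-point weight of the base immediately 5' of each end in
#' fragment orientation (`purine_break_weight` for A/G, 1 for C/T, applied
#' at both ends), cytosines at 0-based 5' distance `i` deaminate to T with
#' probability `d1 * r^i` (guanines mirrored from the 3' end), and uniform
#' sequencing miscalls are applied last. Strand of origin is uniform.
#'
#' @param reference a `sim_reference` from [generate_reference()].
#' @param truth one row of [sample_truth()] (data frame or list with
#'   `sample_id`, `age`, `lambda_true`).
#' @param config the [sim_config()].
#' @param seed integer seed for this sample's substream; defaults to
#'   `config$seed + 1009`.
#' @return A tibble of alignment records with columns `qname`, `contig`,
#'   `start`, `end` (0-based half-open), `strand`, `seq` (bases in
#'   plus-strand/SAM orientation), `mapq`; attributes `truth` (ground-truth
#'   list) and `length_tally` (named integer vector of retained fragment
#'   lengths).
#' @examples
#' cfg <- sim_config(ages = 150, n_reads = 500, reference_length = 20000)
#' ref <- generate_reference(cfg)
#' reads <- simulate_sample(ref, sample_truth(cfg)[1, ], cfg)
#' nrow(reads)
#' @export
simulate_sample <- function(reference, truth, config, seed = NULL) {
  stopifnot(inherits(reference, "sim_reference"), inherits(config, "sim_config"))
  truth <- as.list(truth)
  lambda <- truth$lambda_true
  if (is.null(lambda) || lambda <= 0 || lambda >= 1) {
    stop_bad_arg("truth$lambda_true must lie strictly in (0, 1)")
  }
  set.seed(seed %||% (config$seed + 1009L))

  frags <- draw_fragments(reference, lambda, config)
  n <- config$n_reads
  ci <- frags$ci[seq_len(n)]
  start0 <- frags$start0[seq_len(n)]
  L <- frags$L[seq_len(n)]
  contig_names <- names(reference$seq)

  frag_seq <- substring(reference$seq[ci], start0 + 1L, start0 + L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  read <- frag_seq
  minus <- strand == "-"
  if (any(minus)) read[minus] <- revcomp(read[minus])

  # per-read first-base deamination probability, compartment-dependent
  d1 <- truth$age * config$deam_rate_per_year +
    ifelse(reference$compartment[ci] == "organelle",
           config$deam_offset_organelle, 0)
  d1 <- pmin(pmax(d1, 0), 1)
  read <- damage_reads(read, d1, config$deam_decline, config$seq_error)

  seq_sam <- read
  if (any(minus)) seq_sam[minus] <- revcomp(read[minus])

  out <- tibble(
    qname = sprintf("%s_r%07d", truth$sample_id %||% "s", seq_len(n)),
    contig = contig_names[ci],
    start = start0,
    end = start0 + L,
    strand = strand,
    seq = unname(seq_sam),
    mapq = 60L
  )
  tal <- table(L)
  attr(out, "truth") <- list(
    sample_id = truth$sample_id %||% "s",
    age = truth$age,
    lambda_true = lambda,
    deam_first_nuclear = pmin(pmax(truth$age * config$deam_rate_per_year, 0), 1),
    deam_first_organelle = pmin(pmax(truth$age * config$deam_rate_per_year +
                                       config$deam_offset_organelle, 0), 1),
    purine_break_weight = config$purine_break_weight
  )
  attr(out, "length_tally") <- setNames(as.integer(tal), names(tal))
  out
}

# Rejection-sample fragment coordinates: geometric length, logistic
# retention, purine-weighted acceptance at both break points. Fragments
# within 10 bp of a contig boundary are rejected so every read carries
# full upstream context on both strands.
draw_fragments <- function(reference, lambda, config) {
  clens <- nchar(reference$seq)
  nc <- length(clens)
  wp <- config$purine_break_weight
  wmax <- max(wp, 1)
  margin <- 10L
  need <- config$n_reads

  acc_ci <- integer(0); acc_s <- integer(0); acc_L <- integer(0)
  batch <- max(20000L, 2L * need)
  for (attempt in seq_len(60L)) {
    m <- min(batch, 2000000L)
    ci <- if (nc == 1L) rep(1L, m) else sample.int(nc, m, replace = TRUE, prob = clens)
    L <- rgeom(m, lambda) + 1L
    ok <- L >= config$min_len & L <= config$max_len
    # logistic recovery filter
    if (config$recovery_filter) {
      ok <- ok & runif(m) < plogis((L - config$recovery_L50) / config$recovery_scale)
    }
    room <- clens[ci] - L - 2L * margin
    ok <- ok & room >= 0L
    ci <- ci[ok]; L <- L[ok]; room <- room[ok]
    if (length(L)) {
      start0 <- margin + as.integer(floor(runif(length(L)) * (room + 1)))
      b5 <- substring(reference$seq[ci], start0, start0)
      b3 <- substring(reference$seq[ci], start0 + L + 1L, start0 + L + 1L)
      w5 <- base_break_weight(b5, wp)
      # weight of the base 5' of the opposite strand's start =
      # weight(complement of the base just 3' of the interval)
      w3 <- base_break_weight_complement(b3, wp)
      acc <- runif(length(L)) < (w5 * w3) / wmax^2
      acc_ci <- c(acc_ci, ci[acc])
      acc_s <- c(acc_s, start0[acc])
      acc_L <- c(acc_L, L[acc])
    }
    if (length(acc_L) >= need) {
      return(list(ci = acc_ci, start0 = acc_s, L = acc_L))
    }
    if (attempt >= 5L && length(acc_L) == 0L) break
    rate <- max(length(acc_L) / (attempt * batch), 1e-4)
    batch <- as.integer(min(2e6, max(batch, 1.5 * (need - length(acc_L)) / rate)))
  }
  rlang::abort(paste0(
    "fragment acceptance failed after bounded attempts (",
    length(acc_L), "/", need, " accepted); check purine_break_weight ",
    "and length bounds against the reference composition"
  ), class = "herbdecay_sim_failure")
}

base_break_weight <- function(b, wp) {
  w <- ifelse(b %in% PURINES, wp, ifelse(b %in% c("C", "T"), 1, 0))
  w
}

base_break_weight_complement <- function(b, wp) {
  # complement of a pyrimidine is a purine
  ifelse(b %in% c("C", "T"), wp, ifelse(b %in% PURINES, 1, 0))
}

# Apply 5' C->T / 3' G->A deamination and uniform miscalls to reads given
# in read orientation. Positions where d1 * r^i < 1e-12 are numerically
# immune and skipped. Operates on one flat raw vector for speed.
damage_reads <- function(read, d1, r, seq_error) {
  lens <- nchar(read)
  n <- length(read)
  if (n == 0) return(read)
  raw <- charToRaw(paste(read, collapse = ""))
  offsets <- cumsum(lens) - lens

  d1max <- max(d1)
  if (d1max > 0) {
    W <- ceiling(log(1e-12 / d1max) / log(r))
    W <- min(W, max(lens))
    k <- pmin(lens, W)
    ridx <- rep.int(seq_len(n), k)
    within <- sequence(k)              # 1-based distance from the end
    p <- d1[ridx] * r^(within - 1)
    idx5 <- rep.int(offsets, k) + within
    idx3 <- rep.int(offsets + lens, k) - within + 1L
    hit5 <- raw[idx5] == RAW_C & runif(length(idx5)) < p
    hit3 <- raw[idx3] == RAW_G & runif(length(idx3)) < p
    raw[idx5[hit5]] <- RAW_T
    raw[idx3[hit3]] <- RAW_A
  }
  if (seq_error > 0) {
    hits <- which(runif(length(raw)) < seq_error)
    if (length(hits)) {
      code <- match(raw[hits], RAW_BASES)
      known <- !is.na(code)
      hits <- hits[known]; code <- code[known]
      shift <- sample.int(3L, length(hits), replace = TRUE)
      raw[hits] <- RAW_BASES[((code - 1L + shift) %% 4L) + 1L]
    }
  }
  big <- rawToChar(raw)
  substring(big, offsets + 1L, offsets + lens)
}
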