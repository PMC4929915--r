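# Fixtures are built in code: tiny hand-written references/SAM records for
# coordinate conventions, and memoised small simulations shared across
# tests so each is generated once per run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# a sim_reference built by hand (bypasses the 10 kb floor of
# generate_reference, which only applies to generated genomes)
toy_reference <- function(seqs, compartment = NULL) {
  if (is.null(names(seqs))) names(seqs) <- paste0("c", seq_along(seqs))
  comp <- compartment %||% setNames(rep("nuclear", length(seqs)), names(seqs))
  structure(list(seq = seqs, compartment = comp), class = "sim_reference")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_alignments <- function(contig, start, end, strand, seq,
                           qname = NULL, mapq = 60L) {
  tibble::tibble(
    qname = qname %||% sprintf("r%03d", seq_along(start)),
    contig = contig, start = as.integer(start), end = as.integer(end),
    strand = strand, seq = seq, mapq = mapq
  )
}

write_toy_fasta <- function(ref, path = tempfile(fileext = ".fasta")) {
  herbdecay::write_reference_fasta(ref, path)
  path
}

# mid-sized damaged sample reused by misinc/breakpoint tests:
# strong deamination (d1 = 0.3, r = 0.5), no sequencing error
damage_sim <- function() {
  memo("damage_sim", {
    cfg <- sim_config(
      ages = 100, k_true = 1e-4, n_reads = 30000,
      reference_length = 100000, deam_rate_per_year = 0.003,
      deam_decline = 0.5, seq_error = 0, seed = 301
    )
    ref <- generate_reference(cfg)
    reads <- simulate_sample(ref, sample_truth(cfg)[1, ], cfg)
    list(cfg = cfg, ref = ref,
         reads = annotate_alignments(reads, ref), raw = reads)
  })
}

# undamaged, unbiased sample on a 50% GC genome
neutral_sim <- function() {
  memo("neutral_sim", {
    cfg <- sim_config(
      ages = 100, k_true = 1e-4, n_reads = 20000,
      reference_length = 100000, deam_rate_per_year = 0,
      seq_error = 0, seed = 302
    )
    ref <- generate_reference(cfg)
    reads <- simulate_sample(ref, sample_truth(cfg)[1, ], cfg)
    list(cfg = cfg, ref = ref,
         reads = annotate_alignments(reads, ref), raw = reads)
  })
}

# independent OLS oracle: normal equations solved directly
ols_oracle <- function(x, y, intercept = TRUE) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}

# independent sequential (Type I) sum-of-squares oracle: RSS drops along
# the nested sequence 1 -> +covariate -> +factor -> +interaction, with
# each RSS computed from the normal equations, not lm
seq_ss_oracle <- function(y, x, f) {
  f <- factor(f)
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  Xf <- stats::model.matrix(~f)
  Xi <- stats::model.matrix(~ x * f)
  m0 <- rss(cbind(rep(1, length(y))))
  m1 <- rss(cbind(1, x))
  m2 <- rss(cbind(1, x, Xf[, -1, drop = FALSE]))
  m3 <- rss(Xi)
  c(covariate = m0 - m1, factor = m1 - m2, interaction = m2 - m3,
    residual = m3)
}
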