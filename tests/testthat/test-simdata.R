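test_that("reference generation honours composition, length and seed", {
  cfg0 <- sim_config(ages = 10, reference_length = 10000, gc_content = 0,
                     seed = 5)
  ref0 <- generate_reference(cfg0)
  expect_identical(nchar(ref0$seq[[1]]), 10000L)
  expect_false(grepl("[GC]", ref0$seq[[1]]))

  cfg <- sim_config(ages = 10, reference_length = 100000, gc_content = 0.5,
                    seed = 6)
  ref <- generate_reference(cfg)
  gc <- sum(strsplit(ref$seq[[1]], "")[[1]] %in% c("G", "C"))
  # binomial oracle: 4 SD band around 0.5
  sd4 <- 4 * sqrt(0.25 * 100000)
  expect_lt(abs(gc - 50000), sd4)

  # same seed twice: byte-identical FASTA
  f1 <- write_toy_fasta(generate_reference(cfg))
  f2 <- write_toy_fasta(generate_reference(cfg))
  expect_identical(readLines(f1), readLines(f2))

  expect_error(sim_config(ages = 10, gc_content = 1.2), "0, 1")
  expect_error(sim_config(ages = 10, reference_length = 500), "10 kb")
})

test_that("simulated lengths follow the truncated geometric law", {
  cfg <- sim_config(ages = 100, k_true = 1e-4, n_reads = 100000,
                    reference_length = 200000, recovery_filter = FALSE,
                    deam_rate_per_year = 0, seq_error = 0,
                    min_len = 20, max_len = 500, seed = 41)
  ref <- generate_reference(cfg)
  reads <- simulate_sample(ref, sample_truth(cfg)[1, ], cfg)
  lens <- reads$end - reads$start
  expect_identical(length(lens), 100000L)
  expect_true(all(lens >= 20 & lens <= 500))

  # closed-form mean of geometric(p = 0.01) conditioned on [20, 500]
  p <- 0.01
  l <- 20:500
  pm <- stats::dgeom(l - 1, p)
  mean_oracle <- sum(l * pm) / sum(pm)
  expect_lt(abs(mean(lens) - mean_oracle) / mean_oracle, 0.02)
})

test_that("simulator is deterministic and honours the no-damage limit", {
  cfg <- sim_config(ages = 50, k_true = 2e-4, n_reads = 2000,
                    reference_length = 50000, deam_rate_per_year = 0,
                    seq_error = 0, seed = 17)
  ref <- generate_reference(cfg)
  tr <- sample_truth(cfg)[1, ]
  r1 <- simulate_sample(ref, tr, cfg)
  r2 <- simulate_sample(ref, tr, cfg)
  expect_identical(r1, r2)

  # no mutation process active: reads match the reference exactly
  ann <- annotate_alignments(r1, ref)
  expect_identical(ann$read_bases, ann$ref_bases)
})

test_that("purine break-point bias matches the acceptance-probability algebra", {
  cfg <- sim_config(ages = 100, k_true = 1e-4, n_reads = 20000,
                    reference_length = 100000, purine_break_weight = 2,
                    deam_rate_per_year = 0, seq_error = 0, seed = 23)
  ref <- generate_reference(cfg)
  reads <- simulate_sample(ref, sample_truth(cfg)[1, ], cfg)
  ann <- annotate_alignments(reads, ref)
  m1 <- substring(ann$upstream_context, 10, 10)
  obs <- mean(m1 %in% c("A", "G"))

  # w_pur = 2 on a uniform genome: P(purine at -1) = 2/3; brute-force
  # rejection-sampling oracle over the same acceptance process
  set.seed(1)
  bases <- sample(c("A", "C", "G", "T"), 200000, replace = TRUE)
  acc <- runif(200000) < ifelse(bases %in% c("A", "G"), 2, 1) / 2
  oracle <- mean(bases[acc] %in% c("A", "G"))
  expect_lt(abs(oracle - 2 / 3), 0.01)
  sd3 <- 3 * sqrt((2 / 3) * (1 / 3) / nrow(ann))
  expect_lt(abs(obs - 2 / 3), sd3)
})

test_that("deaminated base fractions follow d1 * r^i at the 5' end", {
  s <- damage_sim()  # d1 = 0.3, r = 0.5, no sequencing error
  mp <- misincorporation_profile(s$reads)
  ct <- mp[mp$end == "5p" & mp$ref == "C" & mp$read == "T" &
             mp$position %in% 1:3, ]
  ct <- ct[order(ct$position), ]
  expected <- 0.3 * 0.5^(0:2)
  sd3 <- 3 * sqrt(expected * (1 - expected) / ct$denominator)
  expect_true(all(abs(ct$freq - expected) < sd3))
})

test_that("cohort construction wires ground truth and guards its inputs", {
  cfg <- sim_config(ages = c(100, 200), k_true = 1e-4, n_reads = 500,
                    reference_length = 20000, seed = 3)
  expect_equal(sample_truth(cfg)$lambda_true, c(0.01, 0.02))

  expect_error(sim_config(ages = c(0, 100)), "age 0")
  expect_error(sim_config(ages = 100, k_true = 0.02), "< 1")

  cfg5 <- sim_config(ages = c(30, 60, 120, 200, 278), k_true = 1e-4,
                     n_reads = 200, reference_length = 20000, seed = 9)
  coh <- simulate_cohort(cfg5)
  expect_length(coh$reads, 5)
  expect_identical(nrow(coh$truth), 5L)
  expect_true(all(diff(coh$truth$lambda_true[order(coh$truth$age)]) > 0))
  expect_equal(coh$truth$collection_year, 2015 - coh$truth$age)
  expect_true(all(vapply(coh$reads, nrow, integer(1)) == 200L))
})

test_that("impossible acceptance fails after bounded attempts", {
  cfg <- sim_config(ages = 100, k_true = 1e-4, n_reads = 100,
                    reference_length = 12000, purine_break_weight = 0,
                    seed = 4)
  # purine-free all-T genome with w_pur = 0: the 3' break point always
  # needs a purine weight, so every candidate is rejected
  ref <- toy_reference(c(c1 = strrep("T", 12000)))
  expect_error(simulate_sample(ref, sample_truth(cfg)[1, ], cfg),
               class = "herbdecay_sim_failure")
})
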