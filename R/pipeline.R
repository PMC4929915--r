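#' Profile one sample's damage statistics
#'
#' End-to-end per-sample stage: load and filter alignments, optionally
#' collapse coordinate duplicates to consensus, annotate with reference
#' bases and upstream context, then compute the fragment-length summary
#' (lognormal log-mean/median), the exponential-tail damage fraction
#' lambda, the first-base C-to-T percentage and the purine fold
#' enrichments, per compartment when a map is given.
#'
#' @param alignment_path SAM/BAM for the sample.
#' @param fasta_path reference FASTA.
#' @param sample_id sample identifier carried into the output.
#' @param compartments optional tibble (`contig`, `compartment`).
#' @param min_mapq mapping-quality filter (default 25).
#' @param dedup collapse coordinate duplicates first (default TRUE).
#' @param P misincorporation window from each end (default 25).
#' @param tail_min_count,tail_mode_offset,tail_min_start arguments passed
#'   to [select_tail_window()].
#' @param min_n minimum reads for the lognormal summary.
#' @return Tibble with one row per compartment (`"all"` when no map):
#'   `sample_id`, `compartment`, `n_reads`, `log_mean`, `log_sd`, `median`,
#'   `lambda_hat`, `window_lo`, `window_hi`, `r_squared`, `lambda_quality`,
#'   `ct_first_pct`, `ct_denominator`, `fold_A`, `fold_G`.
#' @export
run_profile <- function(alignment_path, fasta_path, sample_id,
                        compartments = NULL, min_mapq = 25, dedup = TRUE,
                        P = 25L, tail_min_count = 10, tail_mode_offset = 5,
                        tail_min_start = NULL, min_n = 30) {
  reads <- load_alignments(alignment_path, fasta_path, min_mapq = min_mapq,
                           annotate = FALSE)
  if (dedup) reads <- deduplicate(reads)
  reads <- annotate_alignments(reads, fasta_path)
  profile_reads(reads, sample_id, compartments = compartments, P = P,
                tail_min_count = tail_min_count,
                tail_mode_offset = tail_mode_offset,
                tail_min_start = tail_min_start, min_n = min_n)
}

#' Profile damage statistics from an in-memory alignment tibble
#'
#' Same computation as [run_profile()] but starting from annotated reads,
#' which is the natural entry point for simulated data.
#'
#' @param reads annotated alignment tibble ([annotate_alignments()]).
#' @param sample_id sample identifier.
#' @inheritParams run_profile
#' @return See [run_profile()].
#' @export
profile_reads <- function(reads, sample_id, compartments = NULL, P = 25L,
                          tail_min_count = 10, tail_mode_offset = 5,
                          tail_min_start = NULL, min_n = 30) {
  groups <- if (is.null(compartments)) {
    list(all = seq_len(nrow(reads)))
  } else {
    comp <- setNames(compartments$compartment, compartments$contig)
    split(seq_len(nrow(reads)), unname(comp[reads$contig]))
  }
  rows <- lapply(names(groups), function(g) {
    sub <- reads[groups[[g]], , drop = FALSE]
    dist <- length_distribution(sub)
    ln <- fit_lognormal(dist, min_n = min_n)
    dec <- tryCatch({
      win <- select_tail_window(dist, min_count = tail_min_count,
                                mode_offset = tail_mode_offset,
                                min_start = tail_min_start)
      fit_decay(dist, window = win)
    }, error = function(e) NULL)
    mp <- misincorporation_profile(sub, P = P)
    ct <- tryCatch(first_base_ct(mp), error = function(e) NULL)
    enr <- tryCatch(purine_enrichment(composition_profile(sub)),
                    error = function(e) NULL)
    tibble(
      sample_id = sample_id,
      compartment = g,
      n_reads = nrow(sub),
      log_mean = ln$log_mean,
      log_sd = ln$log_sd,
      median = ln$median,
      lambda_hat = if (is.null(dec)) NA_real_ else dec$lambda_hat,
      window_lo = if (is.null(dec)) NA_integer_ else dec$window[1],
      window_hi = if (is.null(dec)) NA_integer_ else dec$window[2],
      r_squared = if (is.null(dec)) NA_real_ else dec$r_squared,
      lambda_quality = if (is.null(dec)) "unavailable" else dec$quality,
      ct_first_pct = if (is.null(ct)) NA_real_ else ct$ct_first_pct,
      ct_denominator = if (is.null(ct)) NA_integer_ else ct$denominator,
      fold_A = if (is.null(enr)) NA_real_ else enr$fold[enr$base == "A"],
      fold_G = if (is.null(enr)) NA_real_ else enr$fold[enr$base == "G"]
    )
  })
  dplyr::bind_rows(rows)
}

#' Run the cohort analysis
#'
#' Profiles every sample listed in the metadata table, joins statistics
#' with metadata, estimates the decay rate k from lambda versus age
#' (through the origin, with the free-intercept sensitivity fit), runs the
#' damage-versus-collection-year regressions, and, when at least two
#' compartments are profiled, the compartment ANCOVAs for lambda and for
#' first-base deamination.
#'
#' @param samples sample table ([load_sample_table()]) with a `path` column
#'   naming each sample's SAM/BAM.
#' @param fasta_path reference FASTA shared by the cohort.
#' @param compartments optional contig-to-compartment tibble.
#' @param outdir optional directory for TSV/JSON report files.
#' @inheritParams run_profile
#' @param alpha significance level used by the ANCOVA conclusions.
#' @return Object of class `cohort_report`: `table` (analysis table),
#'   `decay` (named list of `decay_rate_fit` per compartment),
#'   `regressions` (tibble of year regressions), `ancova` (named list or
#'   `NULL`).
#' @export
run_cohort <- function(samples, fasta_path, compartments = NULL,
                       outdir = NULL, min_mapq = 25, dedup = TRUE, P = 25L,
                       tail_min_count = 10, tail_mode_offset = 5,
                       tail_min_start = NULL, min_n = 30, alpha = 0.05) {
  if (nrow(samples) < 3) stop_bad_arg("a cohort analysis needs >= 3 samples")
  if (!"path" %in% names(samples)) stop_bad_arg("sample table lacks a `path` column")
  missing_files <- samples$sample_id[!file.exists(samples$path)]
  if (length(missing_files)) {
    stop_bad_arg(paste0("alignment file missing for sample(s): ",
                        paste(missing_files, collapse = ", ")))
  }
  stats <- purrr::map2_dfr(samples$path, samples$sample_id, function(p, id) {
    run_profile(p, fasta_path, id, compartments = compartments,
                min_mapq = min_mapq, dedup = dedup, P = P,
                tail_min_count = tail_min_count,
                tail_mode_offset = tail_mode_offset,
                tail_min_start = tail_min_start, min_n = min_n)
  })
  analyse_cohort(stats, samples, alpha = alpha, outdir = outdir)
}

#' Cohort-level inference from per-sample statistics
#'
#' The inference half of [run_cohort()], reusable when per-sample profiles
#' were computed in memory (e.g. from simulated reads).
#'
#' @param stats per-sample statistics ([profile_reads()] rows).
#' @param samples sample metadata with `sample_id`, `collection_year`,
#'   `age`.
#' @param alpha ANCOVA significance level.
#' @param outdir optional report directory.
#' @return `cohort_report`, see [run_cohort()].
#' @export
analyse_cohort <- function(stats, samples, alpha = 0.05, outdir = NULL) {
  tab <- cohort_table(stats, samples)

  decay <- lapply(split(tab, tab$compartment), function(d) {
    tryCatch(
      estimate_decay_rate(dplyr::rename(d, quality = "lambda_quality")),
      error = function(e) NULL
    )
  })
  decay <- decay[!vapply(decay, is.null, logical(1))]

  reg_spec <- list(
    c("log_mean", "collection_year"),
    c("ct_first_pct", "collection_year"),
    c("fold_A", "collection_year"),
    c("fold_G", "collection_year")
  )
  regressions <- purrr::map_dfr(split(tab, tab$compartment), function(d) {
    purrr::map_dfr(reg_spec, function(rs) {
      fit <- tryCatch(
        regress(d, !!rlang::sym(rs[1]), !!rlang::sym(rs[2])),
        error = function(e) NULL
      )
      if (is.null(fit)) return(tibble())
      tibble(compartment = d$compartment[1], response = rs[1],
             covariate = rs[2], slope = fit$slope,
             intercept = fit$intercept, r_squared = fit$r_squared,
             p_value = fit$p_value, n = fit$n)
    })
  })

  anc <- NULL
  if (length(unique(tab$compartment)) >= 2) {
    anc <- list(
      lambda = tryCatch(
        ancova(tab, lambda_hat, age, compartment, alpha = alpha),
        error = function(e) NULL),
      deamination = tryCatch(
        ancova(tab, ct_first_pct, age, compartment, alpha = alpha),
        error = function(e) NULL)
    )
  }

  report <- structure(
    list(table = tab, decay = decay, regressions = regressions, ancova = anc),
    class = "cohort_report"
  )
  if (!is.null(outdir)) write_cohort_report(report, outdir)
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report> ", nrow(x$table), " sample-compartment rows\n", sep = "")
  for (g in names(x$decay)) {
    cat(sprintf("  [%s] k = %.4g per site per year (through origin, n = %d)\n",
                g, x$decay[[g]]$k, x$decay[[g]]$n))
  }
  if (!is.null(x$ancova)) {
    for (nm in names(x$ancova)) {
      if (!is.null(x$ancova[[nm]])) {
        cat(sprintf("  ancova[%s]: %s\n", nm, x$ancova[[nm]]$conclusion))
      }
    }
  }
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Emits `cohort_table.tsv`, `regressions.tsv`, `decay_rates.json` and
#' (when computed) `ancova.json` under `outdir`.
#'
#' @param report a `cohort_report`.
#' @param outdir output directory, created if missing.
#' @return `outdir`, invisibly.
#' @export
write_cohort_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$table, file.path(outdir, "cohort_table.tsv"))
  readr::write_tsv(report$regressions, file.path(outdir, "regressions.tsv"))
  decay <- lapply(report$decay, function(d) {
    list(k = d$k, mode = d$mode, n = d$n,
         r_squared = d$through_origin$r_squared,
         p_value = d$through_origin$p_value,
         free_intercept_k = d$free_intercept$slope,
         free_intercept = d$free_intercept$intercept)
  })
  jsonlite::write_json(decay, file.path(outdir, "decay_rates.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$ancova)) {
    anc <- lapply(report$ancova, function(a) {
      if (is.null(a)) return(NULL)
      list(table = a$table, interaction_p = a$interaction_p,
           additive_factor_p = a$additive_factor_p,
           conclusion = a$conclusion)
    })
    jsonlite::write_json(anc, file.path(outdir, "ancova.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(outdir)
}
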