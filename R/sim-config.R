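#' Simulation configuration
#'
#' Bundles every parameter of the damaged-read simulator. The defaults
#' describe a plausible herbarium cohort: a per-nucleotide decay rate of
#' 1.66e-4 per year, 5'-terminal deamination growing by 2e-4 per year of age
#' and declining geometrically inwards, a mild purine preference at break
#' points, and a logistic length-dependent recovery filter (library prep +
#' sequencing + mapping jointly disfavour very short fragments) that gives
#' the empirical length distribution its lognormal-looking mode while
#' leaving the right tail exponential.
#'
#' @param ages numeric vector of sample ages in years, one per sample; all
#'   must be > 0 (a zero age makes the per-bond damage fraction degenerate).
#' @param reference_length integer vector, bp per contig (each >= 10000).
#' @param contig_compartments character vector, `"nuclear"` or `"organelle"`
#'   per contig; names become contig names (defaults `contig1`, ...).
#' @param gc_content target G+C fraction of the reference, in \[0, 1\].
#' @param k_true per-site per-year decay rate; per-sample ground truth is
#'   `lambda_true = k_true * age`, which must stay below 1.
#' @param n_reads retained reads per sample.
#' @param purine_break_weight relative weight `w_pur >= 0` given to A/G at
#'   position -1 when accepting fragment break points (pyrimidines weigh 1);
#'   applied symmetrically at both fragment ends in fragment orientation.
#' @param deam_rate_per_year first-base C-to-T probability gained per year
#'   of age.
#' @param deam_decline geometric decline factor `r` in (0, 1): a C at 0-based
#'   5' distance `i` deaminates with probability `d1 * r^i` where
#'   `d1 = age * deam_rate_per_year` (plus the organelle offset when the
#'   contig is organellar); G-to-A mirrored from the 3' end.
#' @param deam_offset_organelle additive shift of first-base deamination for
#'   organellar reads (may be negative).
#' @param seq_error per-base uniform miscall probability, applied last.
#' @param min_len,max_len hard fragment-length bounds (truncation by redraw,
#'   so the retained tail stays geometric).
#' @param recovery_L50,recovery_scale midpoint and scale (bp) of the logistic
#'   recovery probability `1 / (1 + exp(-(L - L50) / scale))`.
#' @param recovery_filter logical; disable to retain every drawn length.
#' @param reference_year calendar year subtracted from age to obtain each
#'   sample's collection year (no implicit "today").
#' @param seed integer seed; every stream of randomness in the simulator
#'   derives from it, so identical configs give byte-identical outputs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(ages = c(100, 200), n_reads = 1000)
#' cfg$k_true * cfg$ages   # per-sample lambda_true
#' @export
sim_config <- function(ages,
                       reference_length = 200000L,
                       contig_compartments = "nuclear",
                       gc_content = 0.5,
                       k_true = 1.66e-4,
                       n_reads = 50000L,
                       purine_break_weight = 1,
                       deam_rate_per_year = 2e-4,
                       deam_decline = 0.5,
                       deam_offset_organelle = 0,
                       seq_error = 1e-3,
                       min_len = 20L,
                       max_len = 500L,
                       recovery_L50 = 35,
                       recovery_scale = 5,
                       recovery_filter = TRUE,
                       reference_year = 2015L,
                       seed = 1L) {
  if (missing(ages) || length(ages) < 1) {
    stop_bad_arg("`ages` must contain at least one sample age")
  }
  if (any(!is.finite(ages)) || any(ages <= 0)) {
    stop_bad_arg("all `ages` must be finite and > 0 (age 0 gives a degenerate lambda = 0)")
  }
  n_contig <- max(length(reference_length), length(contig_compartments))
  reference_length <- rep_len(as.integer(reference_length), n_contig)
  contig_compartments <- rep_len(contig_compartments, n_contig)
  if (is.null(names(contig_compartments))) {
    names(contig_compartments) <- paste0("contig", seq_len(n_contig))
  }
  if (!all(contig_compartments %in% c("nuclear", "organelle"))) {
    stop_bad_arg("contig_compartments must be 'nuclear' or 'organelle'")
  }
  if (any(reference_length < 10000L)) {
    stop_bad_arg("each contig must be at least 10 kb long")
  }
  if (gc_content < 0 || gc_content > 1) stop_bad_arg("gc_content must lie in [0, 1]")
  probs <- c(gc_content, deam_decline, seq_error)
  if (any(probs < 0 | probs > 1)) stop_bad_arg("all probabilities must lie in [0, 1]")
  if (deam_decline <= 0 || deam_decline >= 1) {
    stop_bad_arg("deam_decline must lie strictly in (0, 1)")
  }
  if (purine_break_weight < 0) stop_bad_arg("purine_break_weight must be >= 0")
  if (k_true * max(ages) >= 1) stop_bad_arg("k_true * max(ages) must be < 1")
  if (min_len < 1) stop_bad_arg("min_len must be >= 1")
  if (max_len <= min_len) stop_bad_arg("max_len must exceed min_len")
  d1_max <- max(ages) * deam_rate_per_year + max(0, deam_offset_organelle)
  if (d1_max > 1) stop_bad_arg("age * deam_rate_per_year (+ offset) exceeds 1")

  structure(
    list(
      ages = as.numeric(ages),
      reference_length = reference_length,
      contig_compartments = contig_compartments,
      gc_content = gc_content,
      k_true = k_true,
      n_reads = as.integer(n_reads),
      purine_break_weight = purine_break_weight,
      deam_rate_per_year = deam_rate_per_year,
      deam_decline = deam_decline,
      deam_offset_organelle = deam_offset_organelle,
      seq_error = seq_error,
      min_len = as.integer(min_len),
      max_len = as.integer(max_len),
      recovery_L50 = recovery_L50,
      recovery_scale = recovery_scale,
      recovery_filter = isTRUE(recovery_filter),
      reference_year = as.integer(reference_year),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  samples:", length(x$ages), " ages", paste(range(x$ages), collapse = "-"), "yr\n")
  cat("  contigs:", length(x$reference_length), " (",
      paste0(names(x$contig_compartments), "=", x$contig_compartments, collapse = ", "),
      ")\n", sep = "")
  cat("  k_true:", x$k_true, " deam_rate/yr:", x$deam_rate_per_year,
      " w_pur:", x$purine_break_weight, "\n")
  cat("  reads/sample:", x$n_reads, " seed:", x$seed, "\n")
  invisible(x)
}

#' Ground-truth table for a configured cohort
#'
#' One row per simulated sample: id, age, collection year, the true
#' per-bond damage fraction `lambda_true = k_true * age`, and the true
#' first-base deamination probability per compartment.
#'
#' @param config a [sim_config()].
#' @return A tibble with columns `sample_id`, `age`, `collection_year`,
#'   `lambda_true`, `deam_first_nuclear`, `deam_first_organelle`,
#'   `purine_break_weight`.
#' @export
sample_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  age <- config$ages
  d1 <- age * config$deam_rate_per_year
  tibble(
    sample_id = sprintf("sim%02d", seq_along(age)),
    age = age,
    collection_year = config$reference_year - age,
    lambda_true = config$k_true * age,
    deam_first_nuclear = pmin(pmax(d1, 0), 1),
    deam_first_organelle = pmin(pmax(d1 + config$deam_offset_organelle, 0), 1),
    purine_break_weight = config$purine_break_weight
  )
}
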