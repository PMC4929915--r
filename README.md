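# herbdecay

DNA damage profiling and decay kinetics for herbarium and other historical
specimens.

DNA in dried plant specimens degrades by two dominant chemical routes.
Depurination-driven strand breakage shortens fragments: the surviving
fragment-length distribution has an exponential tail
`F(L) = F0 · e^(−λL)`, whose log-linear slope `−λ` is the per-bond damage
fraction of a sample, and across a dated cohort `λ = k × age` gives the
per-nucleotide, per-year decay rate `k`. Hydrolytic cytosine deamination
accumulates C→T substitutions at the 5′ terminus roughly linearly with
specimen age, declining geometrically with distance into the read — the
standard authenticity signal for historical DNA. Breakage also leaves a
purine (A/G) excess at the reference position immediately 5′ of read
starts (position −1), quantified as a fold enrichment against a background
position (−5).

`herbdecay` computes these statistics per sample from merged-read SAM/BAM
alignments, then performs the cross-sample inference: the through-origin
regression of λ on age (with a free-intercept sensitivity fit), damage
regressions on collection year, and ANCOVA comparisons of genomic
compartments (nuclear vs organellar) or protocol factors — a significant
covariate×factor interaction means the groups differ in rate (slope), a
significant factor term in the additive model means they differ in extent
(intercept) only.

A seeded simulator generates reference genomes and damaged-read alignments
with known ground truth (geometric fragment lengths, logistic
length-dependent recovery, purine-weighted break points, age-scaled
deamination, uniform sequencing error), so every estimator is validated by
parameter recovery.

For whom: anyone quantifying DNA degradation in herbarium/museum
collections, planning sequencing of historical material, or needing a
verifiable re-implementation of mapDamage-style fragmentation and
misincorporation summaries with cohort-level kinetics on top.

## Worked example

Simulate a five-sample cohort spanning 40–270 years at the herbarium decay
rate, write SAM/FASTA/metadata to disk, and run the full analysis back off
those files:

```r
library(herbdecay)

cfg <- sim_config(ages = c(40, 90, 140, 200, 270), k_true = 1.66e-4,
                  n_reads = 10000, reference_length = 100000, seed = 42)
outdir <- file.path(tempdir(), "cohort")
coh <- simulate_cohort(cfg, outdir = outdir)

samples <- load_sample_table(file.path(outdir, "samples.tsv"),
                             reference_year = 2015)
samples$path <- coh$paths$alignments[samples$sample_id]

report <- run_cohort(samples, coh$paths$fasta, tail_min_start = 75)
report$table[, c("sample_id", "age", "median", "lambda_hat", "ct_first_pct")]
#> # A tibble: 5 × 5
#>   sample_id   age median lambda_hat ct_first_pct
#>   <chr>     <dbl>  <dbl>      <dbl>        <dbl>
#> 1 sim01        40  130.     0.00682         1.05
#> 2 sim02        90   84.4    0.0155          1.58
#> 3 sim03       140   66.8    0.0244          3.30
#> 4 sim04       200   56.6    0.0330          3.83
#> 5 sim05       270   49.9    0.0450          6.20
report$decay$all
#> <decay_rate_fit> k = 0.0001676 per site per year (through_origin, n = 5)
#>   through-origin: k = 0.0001676 (R2 = 1.000, p = 5.5e-08)
#>   free-intercept: k = 0.0001644, intercept = 0.000618
```

Older samples have shorter median fragments, larger per-bond damage
fractions λ, and more first-base C→T — and the through-origin slope of λ
on age recovers the simulated decay rate `k_true = 1.66e-4` within a few
percent. `autoplot(report)` draws λ against age with both fitted lines;
`plot_misincorporation()`, `plot_composition()` and
`plot_length_distribution()` show the per-sample damage profiles. Fitted
objects support `tidy()` and `glance()`.

The `tail_min_start = 75` argument starts the exponential-tail fit beyond
the simulator's logistic recovery region (L50 = 35 bp, scale = 5 bp, so
retention exceeds 0.999 past ~75 bp); see the methods vignette
(`vignettes/herbarium-dna-decay.Rmd`) for how to choose it for real
libraries.

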