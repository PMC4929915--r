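Package: herbdecay
Title: DNA Damage Profiling and Decay Kinetics for Herbarium Specimens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Profiles post-mortem DNA damage in shotgun-sequenced herbarium
    (and other historical) specimens and estimates decay kinetics across a
    dated cohort. Per sample it computes fragment-length distributions with
    a lognormal summary (median = exp(log-mean)), fits the exponential tail
    of the length distribution to obtain the per-bond damage fraction
    lambda, profiles reference base composition upstream of 5' read ends
    (depurination signal) and position-wise nucleotide misincorporation
    (cytosine deamination, C-to-T at the 5' terminus). Across samples it
    regresses lambda on specimen age through the origin (lambda = k * age)
    to estimate the per-nucleotide per-year decay rate k, regresses damage
    summaries on collection year, and compares genomic compartments or
    protocol factors by analysis of covariance. A seeded simulator of
    damaged merged-read alignments with known ground truth makes every
    estimator verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
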