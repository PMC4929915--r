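---
title: "Methods: DNA damage and decay kinetics in herbarium specimens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNA damage and decay kinetics in herbarium specimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models behind `herbdecay`, the choices made
where the methodology was genuinely open, and what the simulation-based
validation does and does not establish about real data.

## The damage model

Post-mortem DNA fragmentation is modelled as independent, identically
distributed breakage of phosphodiester bonds. If each bond has broken with
probability $\lambda$ in a given specimen, surviving fragment lengths are
geometric, and the frequency of fragments of length $L$ declines
exponentially:

$$F(L) = F_0\, e^{-\lambda L}, \qquad
  \log F(L) = \log F_0 - \lambda L .$$

$\lambda$ is the **per-bond damage fraction** of the sample. One published
gloss calls the same slope a "fraction of bond survival"; that reading is
inconsistent with the direction of the decline, and this package fixes
$\lambda$ as the breakage fraction, i.e. the magnitude of the fitted
log-linear slope. If breakage accrues at a constant per-site, per-year rate
$k$, then across a dated cohort

$$\lambda = k \times \mathrm{age},$$

so $k$ is the slope of $\lambda$ against age. Cytosine deamination is
modelled separately: the probability that a read's cytosine at 0-based
distance $i$ from the 5$'$ end is read as thymine is $d_1 r^i$, with the
first-base probability $d_1$ growing linearly with age and $r \in (0,1)$
the geometric decline into the read. Depurination biases where breaks
occur, leaving an excess of A/G at the reference position immediately 5$'$
of read starts (position $-1$).

## Estimators

**Fragment lengths.** The empirical length distribution of merged reads is
summarised two ways. (1) A closed-form lognormal fit: the count-weighted
mean and uncorrected standard deviation of log lengths (the maximum-
likelihood estimates), with the distribution's median equal to
$e^{\text{log-mean}}$ *exactly* — the identity is carried through the code,
not re-derived numerically. (2) The exponential-tail fit: ordinary least
squares of log count on length over a tail window, with
$\hat\lambda = -\text{slope}$. Zero-count bins are dropped (their log is
undefined) rather than pseudo-counted; the number of bins used is recorded.
The default fit is unweighted, mirroring the simple linear fit of the
original methodology; a count-weighted option exists for sensitivity
checks.

**Tail window.** The empirical distribution is moded, not exponential,
at short lengths, because short fragments are lost during library
preparation, sequencing and mapping. Only the region beyond the mode
declines exponentially. The default window runs from the modal length plus
5 bp (ties across equal-count modes resolve to the smallest, with a
warning) to the largest length whose count still reaches 10, and must
contain at least 10 populated bins. When the recovery process is known —
as for simulated data with its logistic filter — `tail_min_start` should
push the lower edge past it: retention under a logistic with midpoint
$L_{50}$ and scale $s$ exceeds 0.999 beyond $L_{50} + 8s$ (75 bp at the
defaults), at which point the residual distortion of the slope is
negligible against $\lambda \ge 3\times10^{-3}$. For real libraries the
mode-plus-offset default is the pragmatic choice, and the fitted window is
always reported so it can be overridden.

**Decay rate.** $\lambda = k\,\mathrm{age}$ has no intercept, so the
headline $k$ is the through-origin OLS slope (uncentred $R^2$). Because a
forced origin silently absorbs any offset, the free-intercept fit is always
computed alongside; on well-behaved data its intercept is consistent with
zero, and on data with a genuine offset it recovers both parameters while
the through-origin slope is biased — a property covered by a test. Samples
whose $\lambda$ is quality-flagged (non-decaying tail, unusable window) are
excluded with a message, never silently.

**Misincorporation and break-point composition.** Substitution frequencies
are conditional on the reference base at each position from each read end
(the mapDamage convention), which makes them independent of depth and
composition; `N` bases are skipped, and positions past a short read's
length receive no contribution. The first-base C→T percentage is the
deamination proxy regressed on collection year. Upstream composition is
tallied at positions $-10..-1$ in read orientation; the purine enrichment
is the *fold* ratio of the frequency at $-1$ over position $-5$ — far
enough from the break to serve as background — with delta-method standard
errors. The profile does not condition on the read's first base, matching
the dnacomp-style tally. Both profiles are computed after duplicate
consensus; computing them before would change denominators slightly, and
the post-consensus order is the one that treats PCR copies as one molecule.

**Duplicates.** Reads sharing (contig, start, end, strand) are collapsed
to a consensus: majority base per column, ties as `N`. This is idempotent,
and the cluster size is kept.

**ANCOVA.** Compartment and protocol comparisons fit
`y ~ covariate * factor` with sequential (Type I) sums of squares via
`aov`, then test the interaction by comparing against the additive model.
Interaction significant → slopes (rates) differ; otherwise a significant
additive factor term → intercepts (extent) differ. The sequential table is
cross-checked in the tests against an independent projection oracle built
from normal equations.

## The simulator

`simulate_cohort()` emulates the data-generating process the inference
assumes, with known ground truth for recovery testing:

- **Reference**: i.i.d. bases at a configurable GC content (default 0.5),
  contigs labelled nuclear or organellar. At least 10 kb per contig.
- **Lengths**: geometric with parameter $\lambda_{\text{true}} = k\,
  \mathrm{age}$, truncated to `[min_len, max_len]` (defaults 20–500 bp) by
  *redraw*, not clamping, so the retained tail stays exactly geometric —
  clamping would pile mass at the bounds and corrupt the tail slope that
  the estimator consumes.
- **Recovery filter**: logistic retention $1/(1+e^{-(L-L_{50})/s})$,
  defaults $L_{50} = 35$ bp, $s = 5$ bp. This reproduces the moded,
  lognormal-looking body of real length distributions while leaving the
  right tail exponential. The mechanistic origin of the lognormal body in
  real data is not established; the logistic filter is a modelling device,
  not a claim about chemistry.
- **Break-point bias**: candidate fragments are accepted with probability
  proportional to the weight of the base immediately 5$'$ of each end in
  fragment orientation (`purine_break_weight` for A/G, 1 for C/T; the
  minus-strand end uses the complement of the base just 3$'$ of the
  interval). On a uniform-composition genome a weight of 2 gives a purine
  fraction of exactly $2/3$ at position $-1$ — the closed-form check used
  in the tests alongside a brute-force rejection-sampling oracle.
  Fragments within 10 bp of a contig edge are rejected so every simulated
  read carries full upstream context.
- **Deamination**: 5$'$ C→T with probability $d_1 r^i$ and the
  double-strand mirror 3$'$ G→A with $d_1 r^j$, where
  $d_1 = \mathrm{age} \times$ `deam_rate_per_year` (default
  $2\times10^{-4}$ per year) plus an optional additive organellar offset;
  $r$ defaults to 0.5. Positions where $d_1 r^i < 10^{-12}$ are numerically
  immune and skipped — exact to below $10^{-12}$ per base.
- **Sequencing error**: uniform miscalls at `seq_error` (default
  $10^{-3}$), applied after deamination; a miscall lands on each of the
  three other bases with equal probability, so the modern-sample C→T
  baseline is `seq_error`/3.
- **Determinism**: all randomness flows from one integer seed; per-sample
  substreams are derived by a fixed offset (1009 × sample index), so
  identical configs give byte-identical outputs, including the FASTA and
  SAM files.

Defaults are chosen to represent a realistic herbarium cohort: a decay
rate of $1.66\times10^{-4}$ per site per year, ages up to ~280 years (the
age range of documented herbarium material), 50 000 retained reads per
sample, and a 2015 reference year for converting ages to collection years
(explicit, never an implicit "today").

### What the simulator does *not* emulate

Indels, mappability artifacts and repeat structure, contamination and
microbial fractions, unmerged read pairs, base-quality variation beyond a
uniform error rate, nick chemistry (purine bias is a phenomenological
weight, not a mechanistic overhang model), and species mixtures. Passing
parameter recovery here therefore shows the estimators are correct *under
the stated model*; it does not show the model captures every property of
real herbarium libraries. In particular, on real data the tail window must
be inspected, and mapping filters (default `min_mapq = 25`, pure-match
CIGARs only) discard reads the profiles cannot use safely.

## Validation problem sizes

The recovery experiments use one deep sample
($\lambda_{\text{true}} = 0.01$, $2\times10^5$ reads, 200 kb reference)
for $\lambda$; 30 samples of $5\times10^4$ reads spanning ages 20–278
years for $k$ and for the deamination-age slope; $10^5$ reads for the
purine-fold oracle comparison; 100 small replicate cohorts for the
fold-versus-year null slope; and 200 replicates for the ANCOVA type-I
calibration (expected in the 2–9 % band at $\alpha = 0.05$) and the
5-residual-SD intercept-shift power design. These sizes give sampling
errors comfortably below the assertion tolerances (5 % for $\lambda$,
10 % for $k$, 15 % for the deamination slope, 5 % for the folds).

## Known limitations

- $\hat\lambda$ estimates $-\ln(1-\lambda)$, the continuous-slope
  equivalent of the per-bond probability; for $\lambda \le 0.05$ the
  difference is under 2.5 % and is absorbed by the recovery tolerances,
  but at much higher damage levels the distinction would matter.
- The through-origin $k$ inherits a small upward bias from the same
  convexity; the free-intercept fit is reported alongside precisely so
  this is visible.
- Dating uses collection year as the age origin; storage-condition
  covariates, species effects and within-specimen heterogeneity are not
  modelled (no species term is included in the cohort regressions).
- The ANCOVA assumes Gaussian residuals and a common variance across
  factor levels; with per-sample statistics of very unequal precision a
  weighted model would be preferable.
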