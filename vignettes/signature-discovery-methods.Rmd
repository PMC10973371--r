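---
title: "Methods: prognostic signature discovery and evaluation in sigforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prognostic signature discovery and evaluation in sigforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigforge)
```

# Overview

`sigforge` implements a complete prognostic-signature workflow for bulk
RNA-seq cohorts of the kind seen in localized (non-metastatic) osteosarcoma:
a few dozen patients, a minority of whom die or relapse within the study
window. The workflow derives differential-expression signatures for the
death and relapse endpoints, intersects them, selects hub genes on a
protein-interaction network by dual centrality, scores every patient with a
z-score activity score, and evaluates the score with tertile
Kaplan-Meier/log-rank read-outs, IPCW time-dependent ROC, co-expression
modules and enrichment statistics. Because the motivating cohorts are
controlled-access, the package ships a synthetic-cohort generator with
planted ground truth; every statistical claim the test suite makes is made
against that generator or against exact oracles.

# The statistical pipeline

## Differential expression

The DE stage is deliberately simple and transparent: counts are normalized
with median-of-ratios size factors (geometric-mean reference over genes
with all-positive counts; factors rescaled to geometric mean 1), and each
gene is tested with a Welch t-test on `log2(normalized + 1)`. The
pseudocount enters only at the log transform, never in size-factor
estimation. A gene is called `up` when `log2FC > log2(1.5)` *strictly* and
its Benjamini-Hochberg q-value is below 0.05 (symmetric for `down`). This
is not a negative-binomial GLM: there is no dispersion shrinkage and no
information sharing across genes, so at very small group sizes (fewer than
about ten samples in an arm) it is markedly less powerful than count-model
alternatives. The package's contract for this stage is planted-truth
recovery at balanced group sizes, which the test suite verifies (true
positive rate above 0.8 at one log2 unit of effect with 30 vs 30 samples),
together with type-I control under the global null.

## Signature overlap

Two DEG lists are intersected per direction and the overlap size is tested
against an upper-tail hypergeometric null. The computation runs in log
space (`phyper(..., log.p = TRUE)`), so overlaps whose p-values underflow
double precision (around 1e-300) keep a finite `log10_p`. The background
universe is a required argument — the recommended choice is the number of
genes tested for differential expression — because overlap significance is
meaningless without an explicit universe.

## Hub selection

The interaction graph is built from a STRING-style edge list (confidence
0-1000; default ingestion cutoff 400, the conventional medium-confidence
threshold), restricted to the overlap genes; genes absent from the network
stay as isolated nodes. Confidences are used only as an ingestion filter —
shortest paths are unweighted, matching common hub-selection practice.
Two centralities are computed per connected component:

* **betweenness** — exact shortest-path betweenness, unnormalized
  pair-count form with fractional credit across tied shortest paths;
* **radiality** — for a component with diameter $\Delta$ and $m$ nodes,
  $\mathrm{rad}(v) = \sum_{u \ne v} (\Delta + 1 - d(v,u)) / (m - 1)$.

Hubs are the union of the top-$k$ genes by each score (default $k = 10$,
so 10-20 hubs). Ties at the $k$-th rank are broken by the other centrality
and then by gene ID, so selection is deterministic. Both scores are pinned
against brute-force path-enumeration and BFS oracles in the tests.

## Activity score and risk strata

Expression is z-scored per gene across samples using the population
(divide-by-$n$) standard deviation — a documented convention the tests
pin. A patient's activity score for a signature is the raw sum of the
z-scores of its up genes minus those of its down genes; a `--mean`-style
`average` flag exists for cross-signature comparability but is off by
default because the raw sum is the reference definition. Z-scores are
computed on `log2(normalized + 1)` values; the expression unit feeding the
z-score is configurable in the sense that any matrix flavor can be
supplied, but the pipeline default is the log scale, where NB counts are
closest to additive. Patients are ranked (ties broken by patient ID) and
the bottom and top `floor(n/3)` form the low- and high-risk strata; the
middle stratum is kept but excluded from two-group survival contrasts.
Stratification is invariant to monotone transforms of the score.

## Survival read-outs

Kaplan-Meier curves and two-group log-rank tests delegate to the
`survival` package (the product-limit and risk-table conventions are
re-verified against from-definition oracles in the tests). The
time-dependent cumulative/dynamic AUC at horizon $t$ is implemented in the
package: cases are events with time $\le t$, controls are subjects still
event-free strictly beyond $t$, each case weighted by $1/\hat G(T_i^-)$
and each control by $1/\hat G(t)$, where $\hat G$ is the Kaplan-Meier
estimate of the censoring survival curve. Without censoring this reduces
exactly to the rank AUC, which is how the tests pin it. Horizons given in
years use 365.25 days per year. Only point estimates are reported, no
confidence bands.

## Co-expression modules

The module stage is a self-contained implementation of the familiar
weighted co-expression workflow: unsigned adjacency $|\mathrm{cor}|^\beta$
(unsigned is the common default; the sign of a correlation is deliberately
ignored), scale-free fit scan over powers 1-12 (R-squared of the binned
log-log connectivity regression, at least 8 bins; chosen power = smallest
reaching 0.8, with an explicit override — the pipeline default is 4), the
topological overlap matrix
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$,
average-linkage clustering on $1-\mathrm{TOM}$ with a *static* cut
(default height 0.99), a minimum module size of 30, and iterative merging
of modules whose eigengenes correlate above 0.75. The dynamic tree-cut
algorithm is intentionally not reproduced; the contract is planted-module
recovery (adjusted Rand index above 0.8 on the default synthetic blocks),
not bit-compatibility with any particular implementation. Module labels
follow the conventional color vocabulary by decreasing size (turquoise,
blue, brown, yellow, green, ...), with size ties broken by smallest member
gene so labels are invariant to gene order. The eigengene is the first
principal component of the standardized module submatrix, unit norm, sign
chosen to correlate positively with mean module expression; module
membership is a gene's correlation with its eigengene. Module-trait
correlation uses Pearson r with t-distribution p-values against
vital status, first event, the metastatic flag and any extra numeric
traits; constant traits are flagged undefined rather than leaking NaN.
Outlier-sample removal before module detection is available upstream as an
explicit choice and is off by default, since any threshold is
cohort-specific.

## Enrichment

Over-representation uses the same log-space hypergeometric kernel as the
overlap test, with BH adjustment across sets, after intersecting each set
with the background. The preranked statistic is the weighted
Kolmogorov-Smirnov running sum (hits weighted by $|s|^p$, default
$p = 1$, normalized to sum 1; misses by $1/(N - n_\mathrm{set})$) whose
extremum is the enrichment score. The null is a *gene-label* permutation
(the correct null for preranked input, as opposed to phenotype
permutation), seeded and therefore reproducible; NES divides the ES by the
mean |ES| of same-sign permutations and q-values are BH across sets. The
conventional FDR < 0.25 reporting threshold is kept as the documented
default. The package's ES agrees with an independent implementation
(`fgsea::calcGseaStat`) to 1e-10 on random inputs, but permutation q
estimation here is BH-based, not the GSEA-specific estimator.

## Wet-lab arithmetic

Two small calculators mirror the validation math: ddCT relative
quantification, $FC = 2^{-\Delta\Delta C_T}$ with replicates averaged on
the Ct scale (which equals the geometric mean of per-replicate fold
changes), and percent viability as 100 x mean(treated)/mean(vehicle) with
the replicate SD reported on the same scale.

# The synthetic cohort generator

The generator emulates the structure of a localized-osteosarcoma cohort:

* **size and events** — default 65 patients; the Weibull baseline (shape
  1.2, scale 10000 days) is calibrated so that with a hazard link of 1 per
  SD about 15 patients die within the 10-year administrative window;
* **expression** — per-gene baseline means from a log-normal (meanlog 5,
  sdlog 1.5 on the natural scale, i.e. median ~150 counts), NB counts with
  variance $\mu + 0.1\mu^2$, resembling bulk RNA-seq;
* **planted signature** — 30 up and 30 down genes shifted by
  $\pm$ `log2_effect` (default 1) per SD of a standard-normal latent risk;
* **survival** — proportional hazards on the standardized latent risk
  (default coefficient 1 per SD); censoring by an administrative cutoff
  drawn uniformly on [0.5, 1] x 10 years plus a 15% chance of early random
  censoring; every deceased patient relapses an exponential lag (mean 180
  days) before death, survivors get an independent, faster relapse
  process — encoding the cohort fact that death implies prior relapse;
* **co-expression blocks** — two 40-gene blocks with intra-correlation
  0.8 via shared latent factors; the first block's factor correlates 0.7
  with the latent risk so that a survival-linked module exists;
* **determinism** — one seed feeds named sub-streams (risk, expression,
  survival, graph, gene sets), so each sub-process is independently
  reproducible.

Default `n_genes` is 1000: large enough for realistic size-factor
estimation and multiple-testing burden, small enough that the full test
suite runs in well under a minute of simulation time. Tests that only need
the survival machinery shrink to 150-250 genes; module-recovery tests use
the full 1000-gene default because median-of-ratios factors estimated from
very few genes leak a common factor into all pairwise correlations.

What the generator does *not* emulate: batch effects, library-size
outliers, gene-gene correlation beyond the planted blocks, competing
risks, and the DE power profile of negative-binomial GLMs. Passing
recovery tests therefore demonstrate that the pipeline's logic is correct
under its own assumptions, not that any particular real-data finding would
replicate.

# Numerical and design choices

* **Population vs sample SD** for z-scores: population; pinned by test.
* **Strict fold-change inequality**: `|log2FC| > log2(1.5)` — a gene at
  exactly 1.5-fold is not called.
* **Tie-breaks** are deterministic everywhere: patient ID for score ties,
  the other centrality then gene ID at the top-$k$ boundary, smallest
  member gene for equal-size modules, index order in clustering input.
* **Log-space p-values** wherever hypergeometric tails can underflow.
* **Zero-variance genes** z-score to zero with a logged count;
  zero-variance traits are flagged undefined; a DE gene with zero variance
  in both groups gets p = 1.
* **Death-contrast grouping**: deceased within 3 years versus alive at
  study end, with patients censored before 3 years excluded from the alive
  arm; both the window and the exclusion are parameters. The choice of
  window trades arm size against label purity and is the main power
  bottleneck at 15 deaths per 65 patients — with the Welch-t stage the
  deceased arm is simply small, and at a hazard link of 1 per SD the
  observed fold changes for outcome-derived contrasts sit near the 1.5-fold
  threshold, so end-to-end DEG lists on default synthetic cohorts are
  short or empty. `run_discovery()` therefore degrades gracefully
  (hub selection is skipped and the signature falls back to the overlap
  list, then to the strongest survival-contrast genes) instead of
  aborting. Balanced designed contrasts, or stronger planted effects, are
  the appropriate way to exercise the full chain on synthetic data; the
  strong-signal demonstration in the test suite uses a 2 log2-unit effect
  with a hazard link of 2.
* **Problem sizes** used by the test and acceptance runs: 60-65 patients,
  150-1000 genes, 50-200 replicate cohorts per calibration claim — chosen
  so each claim has narrow Monte-Carlo error while the whole suite stays
  fast.

# Known limitations

* The DE stage's power at realistic event counts is below count-model
  alternatives (by design, for transparency); its guarantees are stated
  for balanced contrasts.
* The static tree cut can merge correlated modules when inter-block
  correlations are high; the eigengene-merge step only merges further,
  never splits.
* The preranked q-value is a BH permutation estimate, not the
  GSEA-specific FDR.
* Time-dependent AUC is a point estimate; no asymptotic or bootstrap
  intervals are provided.
* ORA p-values are conservative for small sets because the hypergeometric
  distribution is discrete; the attained level at nominal 0.05 can be
  substantially below 0.05.
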