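# sigforge

Prognostic gene-signature discovery and survival evaluation for bulk
RNA-seq cohorts, modeled on the localized (non-metastatic) osteosarcoma
setting: small cohorts (~65 patients) in which a minority die or relapse,
and where the goal is a compact transcriptomic signature that stratifies
patients into high- and low-risk groups at diagnosis.

The package is aimed at computational biologists who want each stage of
such an analysis as a tested, reusable function rather than a one-off
script, together with a synthetic-cohort generator that makes every
statistical property of the pipeline checkable against planted ground
truth.

## What it implements

* **Differential expression (simplified)** — median-of-ratios
  normalization, per-gene Welch t-tests on `log2(normalized + 1)`,
  Benjamini–Hochberg FDR, and the standard filter
  `|FC| > 1.5` (strict) with `q < 0.05`.
* **Signature overlap** — intersection of death- and relapse-endpoint DEG
  lists with an upper-tail hypergeometric test computed in log space, so
  overlaps with p ~ 1e-300 stay representable.
* **Hub-gene selection** — betweenness and radiality centrality on a
  confidence-filtered STRING-style interaction network restricted to the
  overlap genes; hubs are the union of the top-*k* genes under each score.
  For a component with diameter Δ and m nodes,
  `rad(v) = Σ_u (Δ + 1 − d(v,u)) / (m − 1)`.
* **Activity scoring and risk strata** — per-gene z-scores across samples
  (population SD); a patient's score is
  `Σ z(up genes) − Σ z(down genes)`; top and bottom score tertiles form
  the high- and low-risk groups. The 13-gene hub signature (6 up: MYOM2,
  VEGFA, MUC1, IHH, GLI1, GRIA1; 7 down: VCAM1, EGFR, GPC3, IGF2, GNG12,
  GNGT1, C3) ships as a fixture (`hub13_signature()`).
* **Survival read-outs** — Kaplan–Meier curves and log-rank tests
  (via the `survival` package), Pearson correlation of scores with time to
  death, and an IPCW cumulative/dynamic time-dependent AUC with
  Kaplan–Meier censoring weights, implemented in the package.
* **Co-expression modules** — unsigned soft-threshold adjacency
  `|cor|^β`, scale-free fit scan, topological overlap matrix,
  average-linkage clustering with a static cut, minimum module size 30,
  eigengene merging, module membership, and module–trait correlation.
* **Enrichment** — hypergeometric over-representation and a preranked
  weighted Kolmogorov–Smirnov statistic with a seeded gene-label
  permutation null.
* **Assay arithmetic** — 2^−ΔΔCT fold changes and percent viability.
* **Synthetic cohorts** — negative-binomial expression with a planted
  up/down signature whose latent activity drives a Weibull
  proportional-hazards death/relapse process, planted co-expressed blocks,
  independent censoring, and full ground truth for recovery tests.

See the methods vignette
(`vignettes/signature-discovery-methods.Rmd`) for the model, parameter
defaults and numerical conventions.

## Worked example

A strong-signal synthetic cohort, end to end:

```r
library(sigforge)

spec  <- simulation_spec(n_patients = 65, n_genes = 400,
                         log2_effect = 2, hazard_beta = 2, seed = 6)
coh   <- generate_cohort(spec)
edges <- generate_edge_list(coh$truth, seed = 6)
res   <- run_discovery(coh$expr, coh$clinical, out_dir = "demo_run",
                       edges = edges, seed = 6)
```

This writes stage-numbered artifacts plus `manifest.json` under
`demo_run/` and returns the in-memory results. On this cohort it prints
(values from the run above):

```
survival-contrast DEGs: 86
relapse-contrast DEGs:  84
overlap: k = 49 of |A| = 56, |B| = 54 (N = 400); p = 2.74e-49
hubs selected: 11
OS log-rank p (high vs low tertile): 1.43e-09
time-dependent AUC (3y, 5y): 0.915, 0.908
score vs time-to-death: r = -0.63, p = 1.9e-4
modules: turquoise = 79, grey = 0
```

Reading: the two outcome contrasts each recover most of the 60 planted
signature genes; their overlap is overwhelmingly non-random; the
dual-centrality step selects 11 hubs (all 10 designated network hubs among
them); the resulting hub signature separates the score tertiles sharply on
overall survival; a higher activity score at diagnosis means earlier death
among deceased patients (negative correlation); and the overlap genes form
one survival-linked co-expression module, as planted. At the default
weaker coupling (`log2_effect = 1`, `hazard_beta = 1`, ~15 deaths per 65
patients) the outcome contrasts sit near the fold-change threshold and the
t-test stage is underpowered — the vignette discusses this regime and the
pipeline's graceful degradation.

A shell entry point with `simulate`, `run` and `score` subcommands is in
`inst/scripts/sigforge.R`.

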