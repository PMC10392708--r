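# tilscore

Immune cell scoring and survival analysis for merged targeted
expression panels.

Bulk tumor specimens profiled on targeted immune gene panels (a few
hundred immune-related genes plus a handful of reference genes) are a
practical way to assess the tumor immune microenvironment from minimal
RNA input. `tilscore` implements the complete analysis such a study
needs when a cohort is run on **two overlapping panels**:

- **Reference-gene normalization** — geNorm stability ranking
  ($M_j$ = mean SD of pairwise log-ratios; $V(n,n+1)$ pairwise
  variation to choose how many references to keep) and per-sample
  scaling to the reference geometric mean, with QC exclusion of
  low-count samples.
- **Panel merging** — the second panel is rescaled by the ratio of
  geometric means of all common probes,
  $r = \mathrm{geomean}(X^{(1)}_{\text{common}}) /
  \mathrm{geomean}(X^{(2)}_{\text{common}})$; common probes are
  averaged, unique probes carried through.
- **Cell type scores** — raw score = mean log2 expression of a cell
  type's marker genes; TIL composite = average raw score of B cells,
  T cells, CD45, macrophages, cytotoxic cells; relative scores =
  log2-space ratios (differences) against TIL or another subset;
  centered scores for display.
- **Differential expression** — per-gene Welch *t* on merged log2 data
  with Benjamini–Yekutieli FDR
  ($p^{BY}_{(i)} = \min(1,\, p_{(i)}\, m\, c(m)/i)$, step-up) and
  volcano classification (unadjusted $p<0.05$, $|\log_2FC|>1$).
- **Cohort statistics** — exact R×C Fisher tests by full fiber
  enumeration under the probability-mass two-sided rule (Monte-Carlo
  fallback for large tables), Wilcoxon rank-sum, Kruskal–Wallis with
  Dunn post-hoc comparisons, median/IQR summaries.
- **Survival analysis** — Kaplan–Meier curves, log-rank tests,
  univariate Cox fits (Efron ties), and marker dichotomization by
  sample median or by the maximum Youden index
  $J = \text{sens} + \text{spec} - 1$, reported three ways per marker.
- **Overrepresentation analysis** — hypergeometric tail tests of DE
  gene lists against GMT gene sets within a panel-restricted universe.
- **Synthetic cohorts** — a generator with planted ground truth (latent
  cell-type abundances, size factors, negative-binomial counts, and
  exponential survival endpoints whose hazards depend on chosen
  relative cell scores), so every stage is testable with no external
  data.

See the methods vignette (`vignettes/til-immune-profiling.Rmd`) for the
models, defaults, and design decisions.

## Worked example

Run the whole pipeline on the default synthetic cohort — 51 samples on
a 770+10 and a 730+40 gene panel sharing 300 probes, with one planted
survival effect (log-hazard −1 linking the mast-cell-vs-TIL score to
metastasis):

```r
library(tilscore)
run <- run_pipeline(synth_config(seed = 1))
run
#> tilscore pipeline run (seed 1)
#>   samples: 51 (51 post-QC), merged genes: 1250
#>   DE: 69 genes at raw p < 0.05, 0 at BY-adjusted < 0.05
#>   survival report rows: 28
```

With no planted expression difference between race groups, about 5% of
the 1,000 endogenous genes reach unadjusted p < 0.05 (69 here) and none
survive BY adjustment — the null behaves as it should. The planted
survival effect, however, is recovered from the expression-derived
score:

```r
subset(run$survival, endpoint == "metastasis" & marker == "mast cells|TIL")
#>            marker cox_beta    cox_hr        cox_p median_cutoff
#> 22 mast cells|TIL -0.75707 0.4690387 1.275761e-05       1.08437
#>    median_logrank_chi2 median_logrank_p youden_cutoff  youden_j
#> 22            12.59915     0.0003859216      1.077772 0.5320513
#>    youden_logrank_chi2 youden_logrank_p n_high_youden n_low_youden   endpoint
#> 22            21.25107     4.028855e-06            26           25 metastasis
```

The continuous Cox fit estimates the hazard ratio per unit of the
mast-vs-TIL score (here HR ≈ 0.47, i.e. low relative mast-cell content
predicts metastasis), and both the median and Youden dichotomizations
confirm the association by log-rank test — the same three-way report
the pipeline produces for every relative cell score and endpoint.

The package also reproduces the published cohort's summary-table
statistics from its printed counts:

```r
round(table1_fisher(), 3)
#>   age_group   psa_group     gleason grade_group         bcr  metastasis
#>       0.007       0.929       0.042       0.020       0.040       0.002
```

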