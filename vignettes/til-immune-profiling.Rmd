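---
title: "Immune cell scoring and survival analysis for merged expression panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune cell scoring and survival analysis for merged expression panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilscore)
```

## The analysis this package implements

Targeted immune expression panels measure a few hundred immune-related
genes plus a small set of reference ("housekeeping") genes per sample.
When a cohort is profiled on *two* overlapping panels, a complete
analysis has to (1) normalize each panel to stable reference genes,
(2) merge the panels onto a common scale, (3) summarize immune cell
content per sample from marker genes, and (4) relate genes and cell
scores to clinical groups and to time-to-event outcomes such as
biochemical recurrence (BCR) and metastasis. `tilscore` implements
this pipeline end-to-end, together with a synthetic cohort generator
with planted ground truth, so that every stage can be validated without
access to any patient-level data.

## Normalization and reference-gene selection

Reference genes are ranked by the geNorm stability measure: for
candidate $j$, $M_j$ is the mean over other candidates $k$ of the
sample standard deviation of the pairwise log-ratio
$A_{jk} = \log_2 x_j - \log_2 x_k$. A gene whose expression moves with
the others has a small $M$. Candidates are eliminated one at a time
(highest $M$ first), and the pairwise variation $V(n, n+1)$ — the SD of
the change in the log2 normalization factor when the $(n+1)$-th ranked
gene is added — decides how many references are kept: the smallest
$n \ge$ `min_refs` with $V(n, n+1) < 0.15$, the conventional geNorm
cutoff. We default `min_refs = 3`; with fewer than three references a
single unstable gene can dominate the factor.

Given references, each sample's scaling factor is
$f_s = \bar g / g_s$ where $g_s$ is the geometric mean of the reference
genes in sample $s$ (computed on counts $+\,0.5$) and $\bar g$ is the
cohort mean of those geometric means. A pseudocount of 0.5 is applied
before every log or geometric mean on raw counts, because zero counts
do occur on targeted panels; 0.5 is small relative to typical reference
counts (hundreds), so it perturbs non-zero values negligibly. Samples
whose reference geometric mean falls below `qc_min` (default 20 counts)
are flagged and excluded — low reference content indicates failed
hybridization, and any scaling factor computed from it would be noise.
The threshold is a parameter and every exclusion is reported.

## Merging two panels

The two panels are normalized independently and then merged through the
ratio of geometric means of their common probes: with
$r = \mathrm{geomean}(\text{panel 1 common block}) /
\mathrm{geomean}(\text{panel 2 common block})$ computed over all common
probes and samples, every value of the second panel is multiplied by
$r$, common probes are averaged entrywise across the two panels, and
unique probes are carried through (the second panel's rescaled by $r$).
Which panel is "second" (i.e. rescaled) is a run-configuration choice.
Two numerical details are worth stating. First, entries that are zero
in either panel's common block are excluded from the geometric means
(with a warning) rather than pseudocounted, so that exact scale
relationships between panels are preserved by the ratio. Second,
averaging of common probes is done on the normalized linear scale, not
after log transformation; the choice matters little for well-correlated
probes but is made explicit and tested.

## Cell type scores

The raw score of a cell type in a sample is the arithmetic mean of the
log2 expression of its marker genes. The total tumor-infiltrating
lymphocyte (TIL) score is the average of the raw scores of B cells,
T cells, CD45, macrophages, and cytotoxic cells. A relative score is
the log2-space ratio of a cell type to a denominator — the TIL
composite or another subset such as exhausted CD8 or Treg — implemented
as the *difference* of the two log2 scores. Since raw scores are log2
averages, this difference is the log2 of the ratio of marker geometric
means; dividing two log-scale numbers would depend on the arbitrary
location of the log scale and is not meaningful. The identity
$\text{relative}(c, d) + \text{score}(d) = \text{raw}(c)$ holds exactly
and is enforced by tests. Centered scores subtract each score's cohort
mean, the form used for cross-sample displays. Markers missing from the
merged matrix are dropped with a warning; a cell type losing all its
markers is an error, because a silently empty score would be worse than
a failure.

## Differential expression

Per-gene two-group comparisons use Welch's unequal-variance $t$ on the
merged log2 data, with the log2 fold change defined as the difference
of group means. The original instrument-vendor analysis software does
not document its test statistic, so a defensible closed-form test that
matches the log-scale fold-change definition was chosen; this choice is
deliberately prominent here, and the per-gene p-values should not be
expected to reproduce another tool's numerically. Multiplicity is
controlled with the Benjamini–Yekutieli procedure — the step-up
Benjamini–Hochberg adjustment inflated by the harmonic factor
$c(m) = \sum_{i=1}^m 1/i$ — which is valid under arbitrary dependence
between genes, the appropriate assumption for functionally related
immune genes. The FDR family is all endogenous genes on the merged
panel; housekeeping genes are excluded. Volcano classification flags
genes with unadjusted $p < 0.05$ and $|\log_2 \mathrm{FC}| > 1$;
headline significance uses BY-adjusted $p < 0.05$.

## Clinicopathologic group statistics

Categorical cohort comparisons use an exact Fisher test for general
R×C tables: the p-value is the total probability, under the
fixed-margins multivariate hypergeometric null, of all tables in the
margin fiber whose probability does not exceed the observed table's
(within relative tolerance $10^{-7}$ — the probability-mass two-sided
rule used by mainstream exact-test implementations). The fiber is
enumerated in full; a Monte-Carlo estimate over tables sampled with
`r2dtable` is available for totals beyond the enumeration budget.
Continuous and score variables use the Wilcoxon rank-sum test (normal
approximation with midranks, tie-corrected variance, and a 0.5
continuity correction, which can be disabled), the tie-corrected
Kruskal–Wallis test for three or more groups, and Dunn's post-hoc
pairwise $z$ tests with Bonferroni adjustment over all pairs — Dunn's
original proposal; the adjustment family is recorded in the output.
Quartiles are type-7 (linear interpolation), the most common default.

## Survival analysis

Each marker (a gene's log2 expression or a relative cell score) is
evaluated three ways against each endpoint, and the pipeline emits one
consistent report row per marker: as a continuous covariate in a
univariate Cox model (Efron tie handling; Wald p), dichotomized at the
sample median (values equal to the median go to "low" — a deterministic
convention), and dichotomized at the Youden-index cutoff. The Youden
search scans every midpoint between consecutive sorted distinct marker
values, evaluates $J = \text{sensitivity} + \text{specificity} - 1$ for
both orientations, and takes the maximizing cutoff, breaking ties
toward the lowest cutoff (deterministic, and favoring larger "high"
groups). Group differences are tested with the log-rank statistic and
survival is summarized with Kaplan–Meier product-limit curves.

One limitation is inherited from the ROC construction: under censoring
the "event" class is *event observed during follow-up*, so heavily
censored samples dilute the event class and the cutoff estimate. This
is the standard simplification when ROC analysis is applied to
censored endpoints without a landmark time, and it is the reason the
continuous Cox fit is reported alongside every dichotomized analysis.

## Overrepresentation analysis

Differentially expressed gene lists are tested against gene-set
collections (GMT format) with the one-sided hypergeometric tail, with
Benjamini–Hochberg adjustment across sets. The universe defaults to the
endogenous genes of the merged panel rather than the genome: a targeted
immune panel is already heavily enriched for immune pathways, and a
genome-wide null would declare nearly every immune set "enriched"
regardless of the data. The universe is configurable.

## The synthetic cohort generator

The generator emulates the data structure the pipeline consumes: two
panels with shared probes (default 770- and 730-gene panels with 10 and
40 housekeeping genes and 300 shared probes), 13 profiled cell types
with `markers_per_type = 3` disjoint marker genes each, latent
per-sample log2 cell-type abundances (SD 1), per-sample library size
factors (log2 SD 0.25), and negative-binomial counts around
$\mu = \text{baseline} \times 2^{\text{abundance}} \times
\text{size factor}$ with dispersion 0.1 (variance
$\mu + 0.1\mu^2$, i.e. ~32% biological CV; Poisson is recovered at
dispersion 0). Three variability sources are deliberately distinct:
marker genes vary through their cell type's abundance; background
endogenous genes carry independent per-sample biological variability
(`bio_sd`, default 0.8 log2 — typical inter-tumor variation for immune
genes); and housekeeping genes carry technical-level noise only
(`hk_dispersion`, default 0.01), which is what makes them usable as
references. Collapsing these (e.g. giving housekeeping genes full
biological dispersion) would make normalization error a shift shared by
all genes and visibly correlate downstream tests — a structure real
reference genes are selected to avoid.

Clinical covariates (race, age group, PSA group, Gleason, grade group)
are sampled from categorical distributions whose defaults match a
51-patient cohort's margins, independently of expression. Survival
times for BCR and metastasis are exponential with
$\log h_s = \log h_0 + \sum_j \beta_j \cdot \text{score}_j(s)$ over the
planted effects, where each score is the centered latent relative score
(e.g. mast cells vs TIL). The default plants a single effect,
$\beta = -1$ on mast cells vs TIL for metastasis, with baseline hazard
0.01 per month. Censoring is independent exponential; its rate is
calibrated by root finding so the expected censored fraction equals
`censor_rate` (default 0.3) given the realized hazards. The master seed
spawns a deterministic substream per generation step, so adding one
step never perturbs another, and identical configs yield byte-identical
cohorts.

What the generator does *not* emulate: instrument-level artifacts (no
RCC files, lane effects, or background counts), correlation between
cell-type abundances, covariate–expression dependence (race has no
expression effect unless planted), non-proportional hazards, and
informative censoring. QC-failing samples appear only if configured
(e.g. by zeroing a sample's references). Passing tests on this
generator therefore demonstrates that the pipeline's statistics recover
known planted structure under realistic panel noise — not that any
particular biological finding in real cohorts is correct.

## Problem sizes used by the test-suite

The packaged checks run at sizes chosen to exercise each claim
meaningfully: parameter recovery uses 100 cohorts of $n = 200$ samples
with reduced panels (120 + 120 endogenous genes, 60 shared) — large
enough that the planted $\beta = -1$ is detectable in nearly every
replicate; null calibration uses 50 cohorts of 51 samples with 1,000
merged endogenous genes; oracle equivalence for the exact Fisher test
enumerates every 2×2 table with total ≤ 20 and random 2×2 and 3×2
tables with totals up to 40. The published cohort's contingency table
ships as plain-text package data and its six Fisher p-values are
recomputed, not stored.

## Known limitations

The Welch-t DE model fits no covariates and no count-level dispersion
model; the Fisher enumeration is exponential in table size (use the
Monte-Carlo fallback beyond the budget); Youden cutpoints ignore
censoring time as noted; and the generator's exponential hazards make
the Cox model correctly specified, so recovery results say nothing
about robustness to hazard misspecification.
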