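---
title: "Methods: data-driven fatigue phenotyping with fatigueclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data-driven fatigue phenotyping with fatigueclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatigueclust)
```

## The analysis this package implements

`fatigueclust` implements an unsupervised phenotyping workflow for fatigue in
clinical cohorts — the motivating application is Marfan syndrome, where
fatigue is prevalent, heterogeneous, and shaped jointly by demographic,
anthropometric, psychological and sleep-related factors. The workflow is:

1. **Instrument scoring.** The Fatigue Severity Scale (FSS; 9 items, 1–7,
   item-mean score, clinical cut-off ≥ 4.67), the Patient Health
   Questionnaire-9 (PHQ-9; 9 items, 0–3, summed 0–27, banded at 5/10/15/20)
   and the Insomnia Severity Index (ISI; 7 items, 0–4, summed 0–28, banded
   at 8/15/22), plus BMI = weight / height².
2. **Embedding.** Age, BMI and the FSS score are z-scored and embedded in
   two dimensions with exact t-SNE (perplexity 20, 500 iterations,
   deterministic PCA initialization).
3. **Clustering.** Ward's minimum-variance hierarchical clustering on the
   embedding; solutions k = 2..10 scored by the mean silhouette width in the
   embedded space; the selected k may be overridden on interpretability
   grounds; clusters are relabeled by ascending mean FSS so "cluster 1" is
   always the lowest-fatigue phenotype.
4. **Profiling.** Per-cluster summaries with a normality-gated test battery
   (Shapiro–Wilk per group; classic ANOVA only when every group passes,
   otherwise Kruskal–Wallis; Pearson chi-square for categorical variables).
5. **Associations.** Spearman correlations over age, disease duration, BMI,
   FSS, PHQ-9 and ISI with Benjamini–Hochberg FDR control; partial Spearman
   correlations of fatigue with depression/insomnia controlling for age; and
   a Mann–Whitney comparison of low- versus high-fatigue participants within
   the upper age tertile.

Because cohort data of this kind are not generally shareable, the package
also ships a **synthetic cohort generator** and a **Monte Carlo sample-size
planner**, both first-class, tested components.

## The synthetic cohort generator

### What it emulates

The generator produces cohorts with three latent fatigue phenotypes. The
default parameters describe a 127-participant cohort split 49/32/46
(largest-remainder apportionment of the cluster weights, ties broken by
cluster order) with, across clusters 1→3: mean ± SD age 22.6 ± 3.1,
36.4 ± 5.9, 53.5 ± 6.1 years; median (q1–q3) BMI 20.0 (18.4–21.4),
21.8 (19.5–23.6), 23.9 (22.5–25.6) kg/m²; disease duration 8.6, 12.1,
15.6 years (median); PHQ-9 3.5 ± 2.6, 5.8 ± 3.7, 7.2 ± 3.6; ISI 4.3 ± 3.7,
6.7 ± 4.5, 8.8 ± 4.8; FSS 2.7 ± 0.8, 3.5 ± 1.1, 4.9 ± 1.0; male fractions
0.408, 0.531, 0.522. Within clusters, the rank-correlation targets are
FSS–PHQ-9 = 0.62, FSS–ISI = 0.41, age–BMI = 0.51 and 0 elsewhere.

### Marginal models

* **Age** is Gaussian (its bounds are never active at these parameters).
* **BMI and disease duration** are reported as median (IQR) — right-skewed,
  positive variables — and are modeled log-normal with parameters matched to
  the printed quartiles: `mu = log(median)`,
  `sigma = log(q3/q1) / (2 z_{0.75})`. Quantile matching is used rather than
  moment matching because quartiles are what per-cluster tables report; the
  fitted median is exact by construction.
* **Instrument scores** live on bounded scales, and for the lower clusters
  the reported SDs are large relative to the distance to the floor (PHQ-9
  3.5 ± 2.6 puts ~9% of a plain Gaussian below 0). Simply clipping Gaussian
  draws at the scale bounds would inflate the realized means by 3–5% and
  shrink the SDs, so bounded scores are drawn from a **moment-matched
  truncated normal**: the latent (mu, sigma) are solved numerically so that
  the mean and SD *after* truncation to the instrument range equal the
  configured values. FSS is kept continuous (an item-mean); PHQ-9 and ISI
  are rounded to integers (item sums), which perturbs their SDs by well
  under 1%.

### Dependence

Dependence is induced by a Gaussian copula. Spearman targets are converted
to latent Pearson correlations with `r = 2 sin(pi rho / 6)`, which is exact
for the Gaussian copula, so no iterative calibration is needed; the latent
matrix is factored by eigendecomposition so that comonotone (|rho| = 1)
targets are handled exactly, and a non-positive-definite target matrix is
an error unless the user opts into a nearest-positive-definite repair. Sex
is Bernoulli(male fraction), independent of all scores within cluster — no
sex effect is modeled.

Between-cluster correlation is *not* separately induced: the cluster means
themselves (older clusters have higher BMI, FSS, PHQ-9, ISI) already
produce pooled-cohort correlations of the observed sign, and at the default
parameters the pooled values overshoot the within-cluster targets (e.g.
pooled FSS–PHQ-9 ≈ 0.79 at n = 127). This is documented behavior, not
calibrated away: the within-cluster targets are the generator's contract.

### What the generator does not capture

The per-cluster parameters it reproduces are *conditional* summaries of
clusters that, in a real analysis, are carved out of the data by the
clustering itself. A partition drawn by Ward on an embedding has hard
boundaries; latent Gaussian clusters with the same conditional means and
SDs overlap more than such a partition does. Synthetic cohorts are
therefore intrinsically *harder* to recover than the clean cluster
separation a published scatter plot suggests: with the default parameters
the full pipeline recovers the latent labels at a median adjusted Rand
index of about 0.5, even though each stage is verified against independent
oracles, and Ward on age alone reaches about 0.78 (BMI and FSS add
between-cluster signal that is weak relative to their within-cluster
spread). Passing tests consequently demonstrate correctness of the
machinery and of the generator's distributional contract — not that real
cohorts cluster this cleanly or this poorly.

## Exact t-SNE

The embedding engine is an exact (dense) t-SNE implementation: per-point
Gaussian bandwidths found by 50 bisection steps to match log(perplexity)
Shannon entropy; symmetrized, normalized affinities; Student-t output
kernel; gradient descent with early exaggeration (factor 12 for the first
quarter of the iterations), momentum (0.5 switching to 0.8 at the same
point), learning rate 200 and adaptive per-coordinate gains. At the cohort
sizes this package targets (hundreds of rows) the O(n²) exact gradient is
fractions of a second; no tree approximation is warranted.

Three deliberate choices:

* **Inputs are z-scored first.** Feeding raw age (SD ≈ 14 years) next to a
  1–7 fatigue score would let age dominate every distance; standardization
  is what makes a mixed-scale embedding meaningful.
* **PCA initialization.** The embedding starts from the first two principal
  components scaled to SD 1e-4. This removes run-to-run sign flips and
  makes the embedding fully deterministic given the input matrix and
  configuration; a seeded random initialization is available as an option.
* **Canonical row ordering.** Rows are internally sorted lexicographically
  before the affinity and gradient computations and restored afterwards.
  Without this, permuting input rows changes floating-point summation
  order, and the gradient descent amplifies last-bit differences into
  visibly different (though statistically equivalent) embeddings. With it,
  the embedding is exactly permutation-equivariant.

The perplexity precondition `n >= 3 * perplexity + 2` is enforced; an
opt-in auto-shrink reduces perplexity to `floor((n - 1) / 3)` with a
warning for small cohorts.

## Clustering and model selection

Ward linkage is computed on Euclidean distances in the embedding
(`ward.D2` update: the merge height of two singletons at distance d is d;
in general the square root of twice the increase in within-cluster sum of
squares). Silhouette widths use Rousseeuw's conventions, including s = 0
for members of singleton clusters, and are computed **in the space that was
clustered** (the 2-D embedding); computing them on the standardized
features instead is available for sensitivity analysis by calling
`silhouette_scores()` on those features directly.

Model selection reports the silhouette-optimal k but never silently
overrides an explicit choice: the reference workflow selects k = 3 on
interpretability grounds even when k = 2 has the best silhouette, so
`evaluate_k_range(..., choose_k = 3)` is the default pipeline
configuration and the selection rationale is recorded in the output.
Dendrograms export to Newick with branch lengths equal to merge-height
differences, so the tree round-trips exactly.

## The Monte Carlo sample-size planner

The planner simulates k spherical unit-variance Gaussian clusters of
(largest-remainder) equal sizes whose centres sit at the vertices of a
regular simplex with every pairwise distance equal to Cohen's d — "every
pairwise separation equal" is the natural reading of uniformly "moderately
separated clusters"; placing clusters on a line with adjacent-only spacing
would make some pairs much closer than others. The default feature
dimension is 3, mirroring the three clustering inputs; when k − 1 exceeds
the dimension the simplex is truncated with a warning. Each (n, k) cell
runs `reps` independent simulate → Ward → silhouette iterations, each rep
on its own seed substream so any cell is reproducible in isolation.

Two numerical points discovered while validating the planner:

* The simulated features are already expressed in pooled within-cluster SD
  units, so they are clustered **as generated**. Re-standardizing by total
  column SDs would divide signal dimensions (signal + noise variance) more
  than pure-noise dimensions and thus shrink the realized effect size below
  the configured d — at d = 4, k = 3 it halves the recovered-partition
  silhouette and drops recovery from ARI ≈ 0.93 to ≈ 0.52.
* The mean silhouette of the *recovered* partition is an effect-size-like
  quantity: its expectation is flat to mildly decreasing in n (Ward can
  carve small noisy samples more cleanly than large ones), unlike a power
  curve. The plateau detector therefore smooths the silhouette-vs-n curve
  by isotonic regression and returns the smallest n within `plateau_tol`
  (default 0.01) of the smoothed maximum, maximized over the k of interest
  (default k ≤ 4, the regime where solutions stay interpretable at these
  cohort sizes). On a flat curve this recommends the smallest candidate n,
  which is the honest answer under this simulation model: beyond the point
  where the curve is flat, more participants do not buy more cluster
  cohesion. Simulated d is a design input; the planner does not estimate it
  from pilot data.

## Statistical battery choices

* **Normality gate** at α = 0.05 per group (Shapiro–Wilk); *every* group
  must pass for ANOVA — the conservative reading of "when assumptions were
  met". Groups with fewer than 3 observations force Kruskal–Wallis with a
  warning.
* **Chi-square** is plain Pearson, no continuity correction; expected
  counts below 5 in more than 20% of cells trigger a warning recommending
  an exact test rather than silently switching method.
* **Multiple testing**: BH-FDR is applied to the 15 unique off-diagonal
  pairs of the 6-variable Spearman matrix, and only there; per-variable
  profile p-values and the stratified comparisons are reported raw, as is
  conventional for descriptive cluster tables and follow-up analyses.
* **Partial Spearman** = Pearson partial correlation on mid-ranks via the
  inverse-correlation-matrix form (identical to correlating rank-regression
  residuals, which is the independent oracle in the tests); p-values from
  the t approximation on n − 2 − |controls| degrees of freedom.
* **Tertile rule**: the upper stratum is age ≥ the empirical 2/3 quantile
  (type-7 linear interpolation quantile). The threshold is recomputed from
  the data at hand, never hard-coded, and is reported alongside the rule.
* **Mann–Whitney U** counts first-group-exceeds pairs with mid-rank tie
  handling (so U + U′ = n₁n₂ always); the exact null distribution is used
  when both groups have ≤ 20 observations and no ties, otherwise the
  tie-corrected normal approximation.

## Determinism and seeds

A single master seed drives everything. Named substreams
(`substream_seed(master, "cohort")`, `"tsne"`, per-cell streams in the
planner) decouple the stages: changing one stage's stream cannot shift
another's draws. Two pipeline runs with the same master seed produce
byte-identical tables, and the JSON run manifest embeds the full
configuration so `rerun_from_manifest()` reproduces a run exactly.

## Problem sizes used by the test suite

The suite verifies oracle equivalence (Ward structure, silhouettes,
chi-square, BH, Mann–Whitney, partial Spearman) on 1000 random instances
of size ≤ 12 per statistic against brute-force references; generator
recovery at n = 10,000 per cluster (means/SDs and log-normal medians
within 2%, Spearman targets within ±0.03); the significance pattern of the
profile battery across 100 seeded default cohorts; and full-pipeline
determinism and recovery at the reference cohort size n = 127. These sizes
were chosen to make the distributional contracts sharp while keeping the
default test run comfortably interactive.

## Known limitations

* Latent-cluster emulation from conditional (per-cluster) summaries
  understates the separation of a partition carved by clustering, as
  discussed above; recovery metrics on synthetic cohorts are conservative.
* The generator does not model missing data, comorbidity/education
  structure beyond pass-through, or any sex effect on scores.
* The sample-size planner's Gaussian, equal-size, spherical clusters are a
  deliberately simple power surrogate; non-Gaussian shapes and unequal
  covariances are out of scope.
* Exact coordinate reproduction of any particular published embedding is
  impossible (it depends on the unavailable patient data and the optimizer
  run); embeddings are validated by neighborhood-structure preservation
  and downstream cluster agreement instead.
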