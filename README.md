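# fatigueclust

Data-driven phenotyping of fatigue in clinical cohorts. Fatigue in chronic
conditions such as Marfan syndrome is heterogeneous: severity, depressive
symptoms, insomnia, age and body composition combine into distinct patient
profiles that group-level averages hide. `fatigueclust` implements, as a
tested and fully reproducible pipeline, the unsupervised workflow used to
uncover such profiles:

* **Instrument scoring** — Fatigue Severity Scale (FSS: 9 items on 1–7,
  score = item mean, clinically significant fatigue at score ≥ 4.67),
  PHQ-9 (0–27, bands at 5/10/15/20) and Insomnia Severity Index (0–28,
  bands at 8/15/22), plus BMI, with strict validation (no imputation,
  item/total consistency checks).
* **Embedding** — z-scored age, BMI and FSS embedded in 2-D by exact t-SNE
  (perplexity 20, 500 iterations, deterministic PCA initialization).
* **Clustering** — Ward's minimum-variance linkage on the embedding;
  solutions k = 2..10 scored by mean silhouette width
  s(i) = (b−a)/max(a,b); clusters relabeled by ascending mean FSS;
  dendrograms exported as Newick.
* **Profiling** — normality-gated ANOVA / Kruskal–Wallis plus Pearson
  chi-square per-cluster comparison tables.
* **Associations** — Spearman correlation matrix with Benjamini–Hochberg
  FDR control, age-adjusted partial Spearman correlations, and
  Mann–Whitney comparisons of low- vs high-fatigue participants in the
  upper age tertile.
* **Synthetic cohorts** — a Gaussian-copula generator with three latent
  fatigue phenotypes (moment-matched truncated-normal instrument margins,
  quartile-matched log-normal BMI/disease duration, targeted within-cluster
  rank correlations) so the whole pipeline is testable without patient
  data.
* **Sample-size planning** — a Monte Carlo grid relating sample size and
  cluster count to the silhouette of the recovered Ward partition under a
  configurable Cohen's d separation, with a plateau-based recommendation.

See `vignettes/fatigue-phenotyping-methods.Rmd` for the model, the design
decisions, and the numerical choices.

## Worked example

```r
library(fatigueclust)

cohort <- generate_cohort(cohort_config(n = 127, seed = 20))
feats  <- standardize_features(cohort, c("age", "bmi", "fss_score"))
emb    <- tsne_embed(feats, embed_config(seed = 20))
keval  <- evaluate_k_range(emb$coords, k_min = 2, k_max = 10, choose_k = 3)
keval
#>   k mean_silhouette                       sizes
#>   2       0.5963435                       72/55
#>   3       0.5004702                    55/47/25
#>   4       0.4677358                 47/32/25/23
#>  ...
#>  10       0.3438721 21/18/16/15/12/11/11/10/7/6
#> k = 3 chosen by explicit override (silhouette-optimal k = 2)
```

The silhouette favours k = 2, but the three-cluster solution is retained by
explicit override (`choose_k = 3`) for its finer clinical granularity — the
package reports both and never silently overrides the metric. Profiling the
three clusters (relabeled so cluster 1 has the lowest fatigue):

```r
cl <- relabel_by_fss(cut_tree(attr(keval, "tree"), 3),
                     cohort$fss_score, cohort$phq9_score)
pr <- profile_clusters(score_cohort(cohort), cl)
#>   variable  test statistic  p_value    group_1    group_2    group_3
#>        age ANOVA     517.2 6.82e-61 22.5 ± 3.4 39.6 ± 4.1 53.8 ± 6.5
#>        bmi ANOVA      62.2 2.00e-19 20.1 ± 2.1 21.9 ± 2.3 24.9 ± 2.1
#>  fss_score ANOVA      98.6 2.36e-26  2.7 ± 0.7  3.7 ± 0.7  5.0 ± 1.0
```

Age, BMI and fatigue severity all increase monotonically across the
phenotypes. The association battery on the same cohort:

```r
assoc <- associations(score_cohort(cohort))
assoc$partial
#>                  pair control  rho       p
#>  fss_score~phq9_score     age 0.61 2.6e-14
#>   fss_score~isi_score     age 0.36 4.2e-05
assoc$stratified$threshold
#> [1] 46.2
```

Fatigue remains strongly associated with depressive symptoms (partial
ρ = 0.61) and moderately with insomnia (0.36) after controlling for age;
the upper age tertile starts at 46.2 years in this cohort and is split at
the FSS ≥ 4.67 cut-off for the Mann–Whitney comparisons.

The one-call version of all of the above, writing every table plus a run
manifest that reproduces the run bit-for-bit:

```r
art <- run_pipeline(pipeline_config(synthetic = cohort_config(), seed = 20,
                                    out_dir = "run1"))
```

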