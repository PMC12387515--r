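Package: fatigueclust
Title: Fatigue Phenotyping of Clinical Cohorts by t-SNE and Ward Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for data-driven fatigue phenotyping in clinical
    cohorts: scoring of the Fatigue Severity Scale (FSS), Patient Health
    Questionnaire-9 (PHQ-9) and Insomnia Severity Index (ISI) with their
    published clinical cut-offs; a Gaussian-copula synthetic cohort generator
    with latent cluster structure and targeted Spearman rank correlations;
    Monte Carlo silhouette-based sample-size planning for cluster analyses;
    exact t-SNE embedding of standardized mixed-scale clinical features; Ward
    hierarchical clustering with silhouette-guided model selection and Newick
    dendrogram export; per-cluster profiling with a normality-gated
    ANOVA/Kruskal-Wallis/chi-square test battery; and rank-based association
    analyses (Spearman matrices with Benjamini-Hochberg false discovery rate
    control, age-adjusted partial Spearman correlations, and age-tertile
    stratified Mann-Whitney comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ape,
    ggplot2,
    mclust,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
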