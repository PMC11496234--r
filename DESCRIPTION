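Package: inflacog
Title: Longitudinal Inflammatory-Cognitive Subgrouping for Severe Mental
    Illness Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for discovering and validating transdiagnostic
    inflammatory-cognitive subgroups in longitudinal case-control cohorts
    of severe mental illness (schizophrenia- and bipolar-spectrum
    disorders plus healthy controls). Provides a seeded synthetic cohort
    generator with latent subgroup structure, preprocessing (acute
    infection exclusion, log10 CRP, Z-standardization against the healthy
    control baseline, cognitive composite scores), random-intercept
    linear mixed models fitted by restricted maximum likelihood,
    from-scratch agglomerative hierarchical clustering with linkage
    selection by agglomerative coefficient and silhouette-based choice of
    the number of clusters, a single-Gaussian simulation test of cluster
    existence, bootstrap Jaccard stability assessment, and a subgroup
    comparison battery (Welch t with Cohen's d, chi-squared,
    Kruskal-Wallis, permutation t tests, Wilcoxon signed-rank with effect
    size r, Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    cluster,
    lme4,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
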