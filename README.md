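# inflacog

Longitudinal inflammatory-cognitive subgrouping for severe mental
illness cohorts.

## What this is for

Cognitive impairment and low-grade systemic inflammation are both
heterogeneous across schizophrenia-spectrum (SZ) and bipolar-spectrum
(BD) disorders: only a subset of patients — and some healthy controls
(HC) — combine raised C-reactive protein (CRP) with poorer cognition.
`inflacog` is an R package for biostatisticians and psychiatry
researchers analysing two-visit case-control cohorts in which CRP
(mg/L) and nine cognitive domains are measured at baseline and about a
year later. It implements, as a tested and reusable pipeline:

* **Preprocessing** — acute-infection exclusion (CRP > 10 mg/L at
  either visit), log10 CRP, Z-standardization of each cognitive domain
  against the HC baseline mean and s.d., a cognitive composite (mean of
  domain Z-scores, requiring ≥ 5 non-missing baseline domains), and the
  complete-case baseline feature matrix (log10 CRP, composite).
* **Random-intercept linear mixed models** fitted by REML for each
  outcome,

  Y<sub>ij</sub> = β₀ + β₁·time<sub>j</sub> + β₂·BD<sub>i</sub> + β₃·SZ<sub>i</sub> +
  β₄·time×BD + β₅·time×SZ + β₆·age + β₇·sex [+ β₈·BMI] + b<sub>i</sub> + e<sub>ij</sub>,

  with b<sub>i</sub> ~ N(0, σ²_b), e<sub>ij</sub> ~ N(0, σ²_e), HC as reference,
  BMI in the CRP model only, Wald tests and Bonferroni adjustment
  across the 10-outcome family.
* **Hierarchical cluster discovery** — from-scratch Lance-Williams
  agglomeration (single/complete/average/Ward, ward.D2 dialect, C++
  core), linkage selection by the Kaufman-Rousseeuw agglomerative
  coefficient, choice of k by average silhouette width.
* **Cluster validation** — a single-Gaussian simulation test of
  cluster existence (fit mean/covariance, simulate M datasets, recluster
  identically; p = (1 + #{null ≥ observed})/(M+1)) and bootstrap
  Jaccard stability (B resamples, per-cluster best-match Jaccard on the
  distinct resampled indices; mean > 0.7 = stable).
* **Subgroup profiling** — Welch t with Cohen's d per visit,
  chi-squared composition tests, and, for sustained differences,
  Wilcoxon signed-rank time effects and rank-sum change-score contrasts
  (ΔY = Y₁ − Y₀) with effect size r = |Z|/√n, Bonferroni-corrected per
  family.
* **A synthetic cohort generator** (133 SZ / 88 BD / 220 HC, two
  visits ~400 days apart, SZ ≈ −1 s.d. and BD ≈ −0.5 s.d. cognitive
  offsets, a latent two-subgroup mixture shifting cognition by −1 s.d.
  and log10 CRP by +0.35 with mixing 0.75/0.48/0.38 by SZ/BD/HC,
  practice effects, clinical scales for SMI, item-level missingness)
  with ground-truth labels for recovery testing, since cohorts of this
  kind are not publicly shareable.

Everything is tibble-in/tibble-out and pipe-friendly, with
`tidy()`/`glance()` methods and `autoplot()` visualisations for the
fitted objects.

## Worked example

```r
library(inflacog)

cfg <- pipeline_config(input = cohort_config(seed = 7),
                       M = 199, B = 50, seed = 7)
report <- run_pipeline(cfg)
report
#> <run_report>
#>   participants clustered: 433 | excluded (CRP > 10 mg/L): 0
#>   linkage: ward | k = 2 | AC = 0.995 | mean silhouette = 0.403
#>   existence test p = 0.005 | Jaccard stability: 0.788, 0.798
#>   adjusted Rand index vs latent truth: 0.641
```

The pipeline selected Ward linkage (agglomerative coefficient 0.995
against the three alternatives), found a 2-cluster solution optimal by
silhouette over k = 2..8, rejected the single-Gaussian null
(p = 0.005 with M = 199 simulations), and found both clusters stable
(mean bootstrap Jaccard 0.79 and 0.80, above the 0.7 rule). Labels
recover the generator's latent subgroups with adjusted Rand index 0.64.

```r
dplyr::filter(tibble::as_tibble(report$profile),
              variable %in% c("composite", "crp_log10"),
              contrast == "cluster1_vs_cluster2")
#> # A tibble: 4 x ...
#>   variable  timepoint statistic p_bonferroni effect
#> 1 crp_log10         0     -16.6     2.81e-46  -1.60
#> 2 composite         0      22.3     6.46e-72   2.16
#> 3 crp_log10         1     -16.1     5.80e-44  -1.56
#> 4 composite         1      19.0     1.21e-57   1.82
```

Cluster 2 is the higher-inflammation - lower-cognition subgroup: its
CRP is higher (Cohen's d ≈ −1.6, cluster 1 minus cluster 2) and its
cognitive composite lower (d ≈ 2.2 at baseline, 1.8 at follow-up), a
difference that persists at follow-up. `write_report(report, "out/")`
writes the JSON/TSV report set plus the dendrogram in Newick form, and
`autoplot()` works on the cluster solution, the silhouette curve, the
null test and the stability object.

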