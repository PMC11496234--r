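---
title: "Discovering and validating inflammatory-cognitive subgroups in longitudinal case-control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and validating inflammatory-cognitive subgroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific setting

Only a subset of people with severe mental illness (SMI; schizophrenia-
and bipolar-spectrum disorders, SZ and BD) show signs of low-grade
systemic inflammation, and cognitive impairment is similarly
heterogeneous. `inflacog` implements an unsupervised, transdiagnostic
subgrouping analysis for two-visit cohorts of SZ, BD and healthy
controls (HC) in which C-reactive protein (CRP, mg/L) and nine
cognitive domain scores are measured at baseline and roughly one year
later. The analysis asks three questions:

1. How do CRP and each cognitive domain change over time by diagnostic
   group? (random-intercept linear mixed models)
2. Do participants form subgroups jointly defined by inflammation and
   cognition, irrespective of diagnosis? (hierarchical clustering on a
   two-feature baseline matrix, with a simulation-based existence test
   and bootstrap stability assessment)
3. How do the subgroups differ on demographic, cognitive and clinical
   measures, and do the differences persist at follow-up?
   (a Welch-t / chi-squared / Wilcoxon battery with Bonferroni
   correction)

Because cohorts of this kind are not publicly shareable, the package
includes a first-class synthetic cohort generator with known latent
structure, so every step of the inference pipeline can be exercised and
validated end-to-end against ground truth.

## Preprocessing

* **Acute infection screen.** Any participant with CRP > 10 mg/L at
  either visit is removed entirely (strict inequality; a missing CRP
  never triggers exclusion).
* **CRP scale.** CRP is log10-transformed. Laboratory values reported
  below a detection limit L can optionally be mapped to L/2 first, a
  common convention; the package errors on non-positive CRP otherwise.
* **Z-standardization.** Each cognitive domain is standardized against
  the HC group's mean and s.d. *at baseline*, and that single reference
  is applied to all rows — both diagnostic groups and both visits. Using
  one fixed reference is the only choice that keeps longitudinal change
  interpretable on a common scale; follow-up Z-scores deliberately do
  not get their own reference.
* **Composite score.** The cognitive composite is the mean of the
  available domain Z-scores. It requires at least five non-missing
  domains at baseline; we additionally require five at follow-up for
  the follow-up composite (the baseline-only rule would let a composite
  at follow-up rest on a single domain, which we consider unreliable).
* **Feature matrix.** Clustering uses the complete-case baseline matrix
  with columns (log10 CRP, composite). By default both columns are
  centred and scaled to unit variance before Euclidean distances are
  computed, because log10 CRP (spread ≈ 0.3) and the composite
  (spread ≈ 1) otherwise contribute very unequally to the metric.
  Whether the original analyses scaled the two features is not
  documentable; the choice is therefore a flag
  (`scale_features = FALSE`) and is recorded in the output metadata.

## Mixed models

For each outcome $Y$ (nine domain Z-scores and log10 CRP) we fit

$$Y_{ij} = \beta_0 + \beta_1 t_j + \beta_2 \mathrm{BD}_i +
\beta_3 \mathrm{SZ}_i + \beta_4 (t_j \times \mathrm{BD}_i) +
\beta_5 (t_j \times \mathrm{SZ}_i) + \beta_6 \mathrm{age}_i +
\beta_7 \mathrm{sex}_i \,[+\, \beta_8 \mathrm{BMI}_i] + b_i + e_{ij}$$

with $t_j \in \{0, 1\}$ (time as a two-level factor, not continuous
days), HC as the reference diagnosis, $b_i \sim N(0, \sigma^2_b)$ a
random intercept per participant and $e_{ij} \sim N(0, \sigma^2_e)$.
BMI enters only the CRP model.

Estimation is restricted maximum likelihood, profiled down to a
one-dimensional search: with $\lambda = \sigma^2_b / \sigma^2_e$, the
within-participant covariance is compound-symmetric and all GLS
quantities reduce to per-participant sums, so the REML criterion is
maximized over $\log \lambda \in [-12, 12]$ by bounded search
(tolerance $10^{-9}$), with $\beta$ by generalized least squares and
$\sigma^2_e$ profiled out. If the criterion is maximal at the
$\lambda \to 0$ boundary the fit returns the OLS limit with
$\sigma^2_b = 0$ and a boundary flag. Inference uses
normal-approximation Wald tests; no Satterthwaite or Kenward-Roger
degrees-of-freedom correction is attempted (a documented limitation —
with ~440 participants the normal reference is adequate). Bonferroni
adjustment is reported across the 10-outcome family, per term; whether
the family should instead span coefficients is genuinely ambiguous, so
the family size is an argument.

## Clustering and its validation

The clustering stage follows five steps:

1. Euclidean distance matrix on the (scaled) feature matrix.
2. Agglomeration under four candidate linkages — single, complete,
   average, Ward — with the winner chosen by the
   **agglomerative coefficient** $AC = \frac{1}{n}\sum_i
   (1 - m(i)/h_{\text{final}})$, where $m(i)$ is the height at which
   observation $i$ first merges. Exact ties take
   ward > average > complete > single. Observations whose first merge
   *is* the final merge contribute 0, so $AC = 0$ for $n = 2$.
3. The number of clusters $k \in \{2, \dots, 8\}$ by maximal average
   **silhouette** width ($s(i) = (b_i - a_i)/\max(a_i, b_i)$; singleton
   clusters score 0; ties go to the smallest $k$). The upper bound 8 is
   a pragmatic default for a two-feature matrix.
4. A **cluster existence test**: fit a single multivariate Gaussian to
   the raw features (sample mean and full covariance; a diagonal
   variant is available), draw $M = 999$ datasets of the same size,
   push each through the identical pipeline (same scaling, linkage and
   fixed $k$), and compare mean silhouettes:
   $p = (1 + \#\{s^{\text{null}} \ge s^{\text{obs}}\})/(M + 1)$.
   Holding $k$ fixed (rather than re-selecting it per simulated
   dataset) matches the fixed observed solution being tested;
   re-selection is available behind a flag.
5. **Bootstrap Jaccard stability**: $B = 100$ resamples with
   replacement, each reclustered identically; each original cluster is
   scored by its Jaccard similarity with the most similar bootstrap
   cluster, computed on the distinct original indices present in the
   resample (per-cluster maximum matching, not one-to-one assignment);
   mean Jaccard > 0.7 counts as stable.

The agglomeration itself is written from scratch (Lance-Williams
recurrences, C++ inner loop with a nearest-neighbour cache) because the
whole validation stage rests on re-running it thousands of times inside
the simulation and bootstrap loops. Ward follows the "D2" dialect —
recurrence on squared distances, heights reported on the distance
scale — which is the standard correspondence for Euclidean input; the
"D" dialect is available behind a flag, and the choice is recorded in
output metadata. Ties at equal merge height are broken by the
lexicographically smallest slot pair, for determinism across platforms.
The implementation is held to an exhaustive from-scratch oracle at
small $n$, to `stats::hclust` and to `cluster::agnes`/`silhouette` in
the test suite.

### Calibration of the existence test

The existence test is a plug-in parametric bootstrap and is
*conservative*: the fitted Gaussian adapts to the observed sample, so
when sampling noise makes the data look slightly clustery the simulated
null silhouettes rise too, and the observed statistic rarely lands in
the extreme tail. In our calibration study (single bivariate Gaussian,
$n = 200$, Ward, $k = 2$) the measured type-I error at nominal 0.05 is
roughly 0.005-0.02 — the test under-rejects but never over-rejects, so
a significant result remains trustworthy. Its power is excellent: at
10 s.d. component separation it returns the minimal attainable
$p = 1/(M+1)$ essentially always. Users should read a non-significant
result as "no demonstrable structure", not "no structure".

## The comparison battery

Diagnosis-level (Table-1 style) comparisons use Kruskal-Wallis with
midrank tie correction plus pairwise two-sided permutation tests of the
Welch statistic (10 000 label permutations, add-one Monte-Carlo
p-values; exact enumeration available for small groups) for continuous
variables, and Pearson chi-squared without continuity correction for
categorical ones. Subgroup (Table-2 style) comparisons use Welch t
tests with Cohen's d — pooled-s.d. denominator with $(n-1)$ weights;
a Welch-style denominator is a flag — at each visit, chi-squared for
sex and diagnosis composition, and, for variables whose subgroup
difference survives Bonferroni at *both* visits, a longitudinal family:
within-subgroup Wilcoxon signed-rank time effects and a between-subgroup
rank-sum contrast of change scores $\Delta Y = Y_1 - Y_0$, each with
effect size $r = |Z|/\sqrt{n}$ computed from the continuity-corrected
normal deviate even when an exact p is reported (for comparability).
Bonferroni correction is applied within each reported family (baseline,
follow-up, longitudinal); permutation tests permute group labels
jointly, the most common reading of a "permutation-based t test".

## The synthetic cohort generator

`cohort_config()` encodes the study conditions: 133 SZ, 88 BD, 220 HC;
two visits with the follow-up drawn uniformly on mean ± 150 days
(default mean 400, i.e. within the 6-month-to-1.5-year window);
diagnosis offsets of −1 s.d. (SZ) and −0.5 s.d. (BD) on all domains; a
latent two-subgroup mixture with membership probabilities 0.75 / 0.48 /
0.38 (SZ / BD / HC) for the higher-inflammation - lower-cognition
subgroup, which shifts all domains by −1 s.d. and log10 CRP by +0.35;
practice effects of +0.2 s.d. at follow-up on fine-motor speed,
psychomotor speed, verbal learning and cognitive control; clinical
scales (five PANSS factors, YMRS, GAF symptom/function) for SMI only,
with subgroup 2 more severe and everything improving at follow-up
except the disorganized factor, which stays flat; and item-level
missingness (5% per domain cell, 2% for CRP).

Two modelling choices deserve comment:

* **Within-diagnosis centring of the latent shift.** The subgroup shift
  enters as $\text{shift} \cdot (\mathbb{1}[\text{sg2}] - p_g)$, a
  deviation around the diagnosis mean. This keeps the diagnosis-group
  means exactly at their configured offsets regardless of the mixing
  proportions, gives HC baseline scores mean 0 and s.d. ≈ 1 (so the
  generator's raw scores already live on the HC-referenced scale), and
  — for CRP — reproduces the empirically observed *absence* of
  case-control CRP differences even though SMI groups contain more
  subgroup-2 members.
* **Free noise parameters.** The person-level cognitive intercept s.d.
  (0.25), per-cell residual s.d. (0.85), person-level log10 CRP s.d.
  (0.2) and visit-to-visit CRP s.d. (0.05; within-person CRP
  test-retest variability is essentially undocumented) are not pinned
  down by any published number. They were calibrated once so that the
  default cohort reproduces the qualitative result surface the analysis
  is known to produce on real data — a clear 2-cluster solution under
  Ward linkage with a high agglomerative coefficient, an existence test
  at its minimal p, stable clusters, and latent subgroups recoverable
  well above chance — while keeping the HC baseline s.d. ≈ 1 constraint
  (0.25² + 0.85² + 0.38·0.62·1² ≈ 1). They are deliberately not
  per-study knobs.

What the generator does **not** emulate: the two historical test
batteries and their harmonization (a single battery is simulated),
medication exposure, diagnosis-specific cognitive *profiles* across
domains (offsets are uniform across domains), skewed or heavy-tailed
cognitive residuals, and any causal coupling between inflammation and
cognition beyond shared latent subgroup membership. Passing recovery
tests therefore shows the *inference machinery* works under the assumed
generative structure, not that real cohorts satisfy that structure.

## Numerical and reproducibility choices

* All randomized stages consume a single pipeline seed from which
  per-stage streams are derived deterministically, so changing the
  number of bootstrap resamples does not perturb the null test; every
  result object records its seed, and a rerun with the same
  configuration is bit-identical.
* The REML search is parameterized on $\log \lambda$ to keep both
  variances positive by construction; a perfect-fit guard returns the
  boundary solution when the residual quadratic form is numerically
  zero.
* Degenerate inputs have defined behaviour: identical points give
  $AC = 0$ with a warning; singleton silhouettes are 0; a bootstrap
  resample with fewer than $k$ distinct points is redrawn and counted;
  all-zero paired differences, zero-variance Welch pairs and zero
  marginals are errors.
* Monte-Carlo sizes used by the validation suite: 200 random instances
  ($n \le 12$) for the agglomeration oracle; 200 replicates at
  $n = 200$, $M = 199$ for the existence-test size study; 20 runs at
  10 s.d. separation for its power; 50 runs at $B = 100$, $n = 200$
  for stability behaviour; 200 replicates at $n = 400$ for REML
  coverage; 20 seeded end-to-end cohorts for subgroup recovery; 200
  zero-effect cohorts for the battery's familywise error. These sizes
  give binomial standard errors a few percent wide while keeping the
  whole suite comfortably runnable on a laptop.
* In the familywise-error study the calibration family contains only
  variables generated independently of the clustering features (age,
  sex, BMI with its CRP slope zeroed, diagnosis composition, clinical
  scales with zero subgroup shift). Variables that feed or correlate
  with the features themselves — the composite, the domains, IQ,
  education — are excluded by design: cluster labels are *selected* to
  separate those, so testing them against the labels is circular and no
  multiplicity correction can fix it. This circularity caveat applies
  equally to real-data use of the profile battery.

## Known limitations

* Wald inference without small-sample df correction; adequate at
  $n \approx 440$, optimistic for small cohorts.
* The existence test's conservatism, discussed above.
* Complete-case logic throughout; no imputation.
* The generator's Gaussian, domain-uniform structure is a deliberate
  simplification (see above).
* Cluster labels from a 2-feature Ward tree are sharp partitions of a
  continuum; the stability and existence machinery quantifies, but does
  not remove, the arbitrariness of cutting mixtures with overlapping
  components.
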