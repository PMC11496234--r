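test_that("Welch t reproduces the worked example and conventions", {
  r <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4, tolerance = 1e-9)
  expect_equal(r$p_raw, 0.02131164, tolerance = 1e-6)
  expect_equal(r$effect, -3, tolerance = 1e-12)
  # identical samples
  r0 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_raw, 1)
  expect_equal(r0$effect, 0)
  # equal means, unequal variances -> d = 0
  re <- welch_t(c(1, 3), c(0, 2, 4))
  expect_equal(re$effect, 0)
  # antisymmetry in the group swap
  a <- withr::with_seed(1, rnorm(10))
  b <- withr::with_seed(2, rnorm(12, 0.5))
  r1 <- welch_t(a, b)
  r2 <- welch_t(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$effect, -r2$effect)
  expect_equal(r1$p_raw, r2$p_raw)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "two observations")
})

test_that("Kruskal-Wallis reproduces the worked example", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, 32 / 7, tolerance = 1e-9)
  expect_equal(r$df, 2)
  expect_equal(r$p_raw, pchisq(32 / 7, 2, lower.tail = FALSE),
               tolerance = 1e-9)
  # identical groups -> H = 0 (all midranks equal)
  r0 <- kruskal_wallis(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_raw, 1)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("two-group Kruskal-Wallis equals the squared standardized
           rank-sum statistic", {
  x <- withr::with_seed(3, rnorm(8))
  y <- withr::with_seed(4, rnorm(11, 1))
  H <- kruskal_wallis(list(x, y))$statistic
  n <- 19
  rk <- rank(c(x, y))
  W <- sum(rk[1:8])
  z <- (W - 8 * (n + 1) / 2) / sqrt(8 * 11 * (n + 1) / 12)
  expect_equal(H, z^2, tolerance = 1e-9)
})

test_that("permutation t test matches exhaustive enumeration", {
  r <- pairwise_permutation_t(list(a = c(0, 1), b = c(10, 11)),
                              exact = TRUE)
  expect_equal(r$p_raw, 2 / 6, tolerance = 1e-12)
  # Monte-Carlo agrees with enumeration within 3 s.e.
  x <- withr::with_seed(5, rnorm(6))
  y <- withr::with_seed(6, rnorm(6, 1.2))
  pe <- pairwise_permutation_t(list(x = x, y = y), exact = TRUE)$p_raw
  pm <- pairwise_permutation_t(list(x = x, y = y), n_perm = 4000,
                               seed = 7)$p_raw
  expect_lt(abs(pm - pe), 3 * sqrt(pe * (1 - pe) / 4000) + 1e-3)
  # three groups -> three pairs, Bonferroni monotone
  r3 <- pairwise_permutation_t(list(a = rnorm(5), b = rnorm(5),
                                    c = rnorm(5)),
                               n_perm = 199, seed = 8,
                               bonferroni = TRUE)
  expect_equal(nrow(r3), 3)
  expect_true(all(r3$p_bonferroni >= r3$p_raw))
  # degenerate pair
  expect_warning(
    rd <- pairwise_permutation_t(list(a = c(1, 1), b = c(1, 1)),
                                 n_perm = 99),
    "identical")
  expect_equal(rd$p_raw, 1)
})

test_that("permutation p is seeded and reproducible", {
  x <- rnorm(10)
  y <- rnorm(10, 0.5)
  p1 <- pairwise_permutation_t(list(x = x, y = y), n_perm = 499,
                               seed = 42)$p_raw
  p2 <- pairwise_permutation_t(list(x = x, y = y), n_perm = 499,
                               seed = 42)$p_raw
  expect_identical(p1, p2)
})

test_that("chi-squared uses Pearson without continuity correction", {
  r0 <- chi_squared(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_raw, 1)
  r <- chi_squared(matrix(c(20, 10, 10, 20), 2))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(r$df, 1)
  expect_equal(r$p_raw, pchisq(20 / 3, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  # proportional rows -> independence
  tab <- rbind(c(10, 20), c(20, 40), c(5, 10))
  expect_equal(chi_squared(tab)$statistic, 0, tolerance = 1e-12)
  expect_error(chi_squared(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("Wilcoxon signed-rank covers exact, tied and effect-size cases", {
  r <- wilcoxon_signed_rank(rep(0, 6), 1:6)
  expect_equal(r$statistic, 21)
  expect_equal(r$p_raw, 2 / 64, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  # antisymmetric differences -> p = 1 under the normal approximation
  ra <- wilcoxon_signed_rank(rep(0, 4), c(-2, -1, 1, 2))
  expect_equal(ra$p_raw, 1)
  expect_equal(ra$z, 0)
  # effect size formula: r = |Z| / sqrt(n_pairs)
  expect_equal(2 / sqrt(100), 0.2)
  expect_equal(ra$effect, 0)
  big0 <- withr::with_seed(9, rnorm(40))
  big1 <- big0 + withr::with_seed(10, rnorm(40, 0.5))
  rb <- wilcoxon_signed_rank(big0, big1)
  expect_equal(rb$method, "normal_approx")
  expect_equal(rb$effect, abs(rb$z) / sqrt(40), tolerance = 1e-12)
  # agreement with stats::wilcox.test in the approximate regime
  wt <- stats::wilcox.test(big1, big0, paired = TRUE, exact = FALSE,
                           correct = TRUE)
  expect_equal(rb$p_raw, wt$p.value, tolerance = 1e-9)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
})

test_that("change scores subtract baseline from follow-up", {
  coh <- tibble::tibble(
    participant_id = rep(c("A", "B", "C"), each = 2),
    timepoint = rep(0:1, 3),
    v = c(0.5, 2, 1, NA, 3, 3))
  cs <- change_scores(coh, "v")
  expect_equal(cs$delta[cs$participant_id == "A"], 1.5)
  expect_false("B" %in% cs$participant_id)
  expect_equal(attr(cs, "excluded_ids"), "B")
  expect_equal(cs$delta[cs$participant_id == "C"], 0)
})

test_that("Bonferroni adjustment caps at one and preserves order", {
  expect_equal(bonferroni_adjust(0.01, m = 9), 0.09)
  expect_equal(bonferroni_adjust(0.5, m = 9), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.04), m = 1), c(0.2, 0.04))
  p <- c(0.001, 0.01, 0.02, 0.2)
  adj <- bonferroni_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_equal(adj, pmin(1, 4 * p))
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
})

test_that("the subgroup profile detects the built-in subgroup structure", {
  cfg <- cohort_config(seed = 31)
  sim <- generate_cohort(cfg)
  coh <- inject_missingness(sim$cohort, cfg) |>
    log10_crp() |> exclude_acute_infection() |>
    standardize_cognition() |> cognitive_composite()
  sol <- cluster_features(build_feature_matrix(coh), linkage = "ward",
                          k = 2)
  prof <- subgroup_profile(coh, sol)
  key <- dplyr::filter(prof, variable %in% c("composite", "crp_log10"),
                       contrast == "cluster1_vs_cluster2")
  expect_equal(nrow(key), 4)  # two variables x two visits
  expect_true(all(key$p_bonferroni < 0.05))
  # cluster 1 = higher cognition (positive d), lower CRP (negative d)
  expect_true(all(key$effect[key$variable == "composite"] > 0))
  expect_true(all(key$effect[key$variable == "crp_log10"] < 0))
  # diagnosis composition tested on the 2 x 3 count table
  comp <- dplyr::filter(prof, variable == "diagnosis")
  expect_equal(comp$df, 2)
  expect_lt(comp$p_bonferroni, 0.05)
  # longitudinal family appears for sustained differences
  expect_true(any(prof$family == "longitudinal"))
})
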