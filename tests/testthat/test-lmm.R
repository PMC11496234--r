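# small simulated two-visit cohort with known fixed effects
sim_lmm_data <- function(n = 120, beta_time = 0.3, sigma_b = 1,
                         sigma_e = sqrt(0.5), seed = 1) {
  withr::with_seed(seed, {
    b <- rnorm(n, 0, sigma_b)
    tibble::tibble(
      participant_id = rep(sprintf("P%03d", 1:n), each = 2),
      diagnosis = rep(sample(c("HC", "BD", "SZ"), n, replace = TRUE),
                      each = 2),
      timepoint = rep(0:1, n),
      sex = rep(sample(c("F", "M"), n, replace = TRUE), each = 2),
      age = rep(runif(n, 20, 50), each = 2),
      bmi = rep(runif(n, 20, 32), each = 2),
      y = rep(b, each = 2) + beta_time * rep(0:1, n) +
        rnorm(2 * n, 0, sigma_e))
  })
}

test_that("design assembly drops incomplete rows but keeps participants", {
  df <- sim_lmm_data(n = 30)
  ds <- build_design(df, "y")
  expect_equal(ds$n_obs, 60)
  expect_equal(ds$n_participants, 30)
  expect_setequal(colnames(ds$X),
                  c("(Intercept)", "time", "diagnosisBD", "diagnosisSZ",
                    "age", "sexM", "time:diagnosisBD", "time:diagnosisSZ"))
  df$y[2] <- NA
  ds2 <- build_design(df, "y")
  expect_equal(ds2$n_obs, 59)
  expect_equal(ds2$n_participants, 30)
  # BMI only on request
  expect_true("bmi" %in% colnames(build_design(df, "y",
                                               include_bmi = TRUE)$X))
  # rank deficiency is reported with the offending term
  df$dup <- df$age
  expect_error(build_design(dplyr::mutate(df, age = 0), "y"),
               "rank deficient")
})

test_that("noiseless data gives a perfect boundary fit", {
  df <- sim_lmm_data(n = 20, sigma_b = 0, sigma_e = 0, beta_time = 3)
  df$y <- 2 + 3 * df$timepoint
  fit <- fit_reml(build_design(df, "y"))
  expect_true(fit$boundary)
  expect_equal(unname(fit$beta[["(Intercept)"]]), 2, tolerance = 1e-8)
  expect_equal(unname(fit$beta[["time"]]), 3, tolerance = 1e-8)
  expect_equal(fit$sigma2_b, 0)
})

test_that("balanced two-visit data: time effect equals the mean change", {
  df <- tibble::tibble(
    participant_id = rep(c("A", "B"), each = 2),
    timepoint = rep(0:1, 2),
    y = c(0, 1, 2, 5))
  # time-only model fitted through the low-level design path
  ds <- structure(list(y = df$y,
                       X = cbind("(Intercept)" = 1, time = df$timepoint),
                       id = df$participant_id, outcome = "y",
                       n_obs = 4, n_participants = 2),
                  class = "lmm_design")
  fit <- fit_reml(ds)
  expect_equal(unname(fit$beta[["time"]]), 2, tolerance = 1e-8)
})

test_that("Wald z and p follow the closed form", {
  df <- sim_lmm_data(n = 40)
  fit <- fit_reml(build_design(df, "y"))
  wt <- wald_tests(fit)
  expect_equal(wt$statistic, wt$estimate / wt$std.error)
  expect_equal(wt$p.value, 2 * pnorm(-abs(wt$statistic)))
  expect_equal(2 * pnorm(-3), 0.002699796, tolerance = 1e-6)
  expect_equal(2 * pnorm(-1.96), 0.04999579, tolerance = 1e-6)
})

test_that("Wald z for time equals the paired t statistic on balanced data", {
  n <- 25
  df <- sim_lmm_data(n = n, beta_time = 0.4, seed = 5)
  ds <- structure(list(y = df$y,
                       X = cbind("(Intercept)" = 1, time = df$timepoint),
                       id = df$participant_id, outcome = "y",
                       n_obs = 2 * n, n_participants = n),
                  class = "lmm_design")
  fit <- fit_reml(ds)
  delta <- df$y[df$timepoint == 1] - df$y[df$timepoint == 0]
  t_paired <- mean(delta) / (sd(delta) / sqrt(n))
  expect_lt(abs(unname(fit$wald_z[["time"]]) - t_paired), 1e-8)
})

test_that("the returned variance ratio beats a 64-point grid", {
  df <- sim_lmm_data(n = 60, seed = 7)
  ds <- build_design(df, "y")
  fit <- fit_reml(ds)
  lam_hat <- fit$sigma2_b / fit$sigma2_e
  crit <- function(lam) inflacog:::reml_pieces(ds, lam)$crit
  best <- crit(lam_hat)
  for (ll in seq(-12, 12, length.out = 64)) {
    expect_lte(crit(exp(ll)), best + 1e-6)
  }
})

test_that("estimates agree with lme4 on the full covariate model", {
  skip_if_not_installed("lme4")
  df <- sim_lmm_data(n = 150, seed = 9)
  fit <- fit_reml(build_design(df, "y"))
  lf <- lme4::lmer(
    y ~ timepoint * diagnosis + age + sex + (1 | participant_id),
    data = dplyr::mutate(df,
                         diagnosis = factor(diagnosis,
                                            c("HC", "BD", "SZ"))),
    REML = TRUE)
  fe <- lme4::fixef(lf)
  expect_equal(unname(fit$beta[["time"]]), unname(fe[["timepoint"]]),
               tolerance = 1e-5)
  expect_equal(unname(fit$beta[["diagnosisSZ"]]),
               unname(fe[["diagnosisSZ"]]), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$sigma2_b, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2_e, vc$vcov[2], tolerance = 1e-4)
  # standard errors too
  se_lme4 <- sqrt(diag(as.matrix(stats::vcov(lf))))
  expect_equal(unname(fit$se_beta[["time"]]),
               unname(se_lme4[["timepoint"]]), tolerance = 1e-4)
})

test_that("estimates are invariant to row permutation and relabelling", {
  df <- sim_lmm_data(n = 50, seed = 11)
  fit <- fit_reml(build_design(df, "y"))
  perm <- withr::with_seed(2, sample(nrow(df)))
  df2 <- df[perm, ]
  df2$participant_id <- paste0("X_", df2$participant_id)
  fit2 <- fit_reml(build_design(df2, "y"))
  expect_equal(fit$beta, fit2$beta, tolerance = 1e-8)
  expect_equal(fit$sigma2_b, fit2$sigma2_b, tolerance = 1e-6)
})

test_that("the outcome batch fits 10 models with BMI only for CRP", {
  cfg <- cohort_config(seed = 21)
  coh <- generate_cohort(cfg)$cohort |>
    log10_crp() |> standardize_cognition() |> cognitive_composite()
  res <- fit_all_outcomes(coh)
  expect_equal(length(unique(res$outcome)), 10)
  expect_true(all(is.na(res$error)))
  crp_terms <- res$term[res$outcome == "crp_log10"]
  expect_true("bmi" %in% crp_terms)
  dom_terms <- res$term[res$outcome == "z_attention"]
  expect_false("bmi" %in% dom_terms)
  # Bonferroni across the 10-outcome family
  expect_equal(res$p.bonferroni, pmin(1, res$p.value * 10))
  # practice-effect domains show a positive time effect
  tt <- res[res$term == "time" & res$outcome == "z_fine_motor_speed", ]
  expect_gt(tt$estimate, 0)
})
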