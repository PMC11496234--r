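#' Welch two-sample t test with Cohen's d
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value, plus Cohen's d with the
#' pooled-s.d. denominator using (n-1) weights (sign convention:
#' `x` minus `y`). A Welch-style denominator (root mean of the two
#' variances) is available via `d_denominator = "welch"`. An
#' approximate 95% confidence interval for d is included.
#'
#' @param x,y Numeric samples (each n >= 2; at least one with nonzero
#'   variance).
#' @param d_denominator `"pooled"` (default) or `"welch"`.
#'
#' @return One-row tibble: statistic, df, p_raw, effect (Cohen's d),
#'   effect_lo, effect_hi, group summaries.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
welch_t <- function(x, y, d_denominator = c("pooled", "welch")) {
  d_denominator <- match.arg(d_denominator)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least two observations", call. = FALSE)
  }
  if (var(x) == 0 && var(y) == 0) {
    stop("both samples have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  nx <- length(x)
  ny <- length(y)
  sp <- switch(d_denominator,
    pooled = sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)),
    welch = sqrt((var(x) + var(y)) / 2))
  d <- (mean(x) - mean(y)) / sp
  se_d <- sqrt((nx + ny) / (nx * ny) + d^2 / (2 * (nx + ny - 2)))
  tibble::tibble(test = "welch_t",
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_raw = tt$p.value,
                 effect = d, effect_name = "cohens_d",
                 effect_lo = d - qnorm(0.975) * se_d,
                 effect_hi = d + qnorm(0.975) * se_d,
                 mean1 = mean(x), sd1 = sd(x), n1 = nx,
                 mean2 = mean(y), sd2 = sd(y), n2 = ny)
}

#' Kruskal-Wallis rank sum test
#'
#' H statistic with the midrank tie correction and a chi-squared
#' p-value on (number of groups - 1) degrees of freedom.
#'
#' @param samples List of two or more numeric samples (all non-empty).
#' @return One-row tibble: statistic, df, p_raw.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
kruskal_wallis <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2)
  samples <- lapply(samples, function(s) s[!is.na(s)])
  if (any(lengths(samples) == 0)) {
    stop("all groups must be non-empty", call. = FALSE)
  }
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(seq_along(samples), lengths(samples)))
  kt <- stats::kruskal.test(x, g)
  tibble::tibble(test = "kruskal_wallis",
                 statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_raw = kt$p.value)
}

# Welch t statistic without the t.test overhead (used inside the
# permutation loop).
welch_stat <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

#' Pairwise permutation t tests
#'
#' For each pair of groups, a two-sided permutation test of the Welch t
#' statistic under random relabelling of the pooled observations. The
#' Monte-Carlo p-value uses the add-one correction,
#' `p = (1 + #(|t*| >= |t_obs|)) / (n_perm + 1)`; with
#' `exact = TRUE` all label splits are enumerated and the p-value is
#' the exact proportion.
#'
#' @param samples Named list of two or more numeric samples.
#' @param n_perm Number of label permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @param exact Enumerate all splits instead of sampling (only for
#'   small groups; errors above `max_exact` splits).
#' @param max_exact Largest number of splits allowed for enumeration.
#' @param bonferroni Add a Bonferroni-adjusted column across pairs?
#'
#' @return Tibble with one row per pair: group1, group2, statistic,
#'   p_raw (and p_bonferroni if requested). Degenerate pairs (all
#'   values identical) get p = 1 with a warning.
#' @export
pairwise_permutation_t <- function(samples, n_perm = 10000, seed = 1L,
                                   exact = FALSE, max_exact = 1e5,
                                   bonferroni = FALSE) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (!exact && n_perm < 99) stop("`n_perm` must be >= 99", call. = FALSE)
  if (is.null(names(samples))) {
    names(samples) <- paste0("group", seq_along(samples))
  }
  samples <- lapply(samples, function(s) s[!is.na(s)])
  pairs <- utils::combn(names(samples), 2, simplify = FALSE)
  rows <- with_seed(seed, purrr::map(pairs, function(pr) {
    x <- samples[[pr[1]]]
    y <- samples[[pr[2]]]
    pooled <- c(x, y)
    n1 <- length(x)
    n <- length(pooled)
    if (var(pooled) == 0) {
      warning("all values identical for pair ", pr[1], " vs ", pr[2],
              "; p set to 1")
      return(tibble::tibble(group1 = pr[1], group2 = pr[2],
                            statistic = 0, p_raw = 1))
    }
    t_obs <- welch_stat(x, y)
    eps <- 1e-12
    if (exact) {
      n_comb <- choose(n, n1)
      if (n_comb > max_exact) {
        stop("too many splits for exact enumeration (", n_comb, ")",
             call. = FALSE)
      }
      idx <- utils::combn(n, n1, simplify = FALSE)
      tstar <- vapply(idx, function(i) {
        welch_stat(pooled[i], pooled[-i])
      }, numeric(1))
      p <- mean(abs(tstar) >= abs(t_obs) - eps)
    } else {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        i <- sample.int(n, n1)
        if (abs(welch_stat(pooled[i], pooled[-i])) >= abs(t_obs) - eps) {
          hits <- hits + 1L
        }
      }
      p <- (1 + hits) / (n_perm + 1)
    }
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   statistic = t_obs, p_raw = p)
  }))
  out <- dplyr::bind_rows(rows)
  if (bonferroni) {
    out$p_bonferroni <- bonferroni_adjust(out$p_raw)
  }
  out
}

#' Pearson chi-squared test of independence
#'
#' Pearson's X-squared without continuity correction on an r x c
#' contingency table; df = (r-1)(c-1). All expected counts must be
#' positive (zero marginals error).
#'
#' @param tab A contingency table or matrix of counts.
#' @return One-row tibble: statistic, df, p_raw.
#' @export
#' @examples
#' chi_squared(matrix(c(20, 10, 10, 20), 2))
chi_squared <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(test = "chi_squared",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_raw = ct$p.value)
}

#' Wilcoxon signed-rank test with effect size r
#'
#' Paired test on the nonzero differences `y1 - y0` with midranks for
#' ties. The p-value is exact for 25 or fewer nonzero differences
#' without ties, otherwise a normal approximation with continuity and
#' tie correction is used. The effect size r = |Z| / sqrt(n_pairs) is
#' always computed from the normal-approximation deviate (with
#' continuity correction), where `n_pairs` counts the complete pairs
#' entering the test.
#'
#' @param y0,y1 Paired samples (baseline, follow-up).
#' @return One-row tibble: statistic (W+ on nonzero differences),
#'   n_pairs, n_nonzero, p_raw, z, effect (r), method.
#' @export
#' @examples
#' wilcoxon_signed_rank(rep(0, 6), 1:6)  # exact p = 2/64
wilcoxon_signed_rank <- function(y0, y1) {
  keep <- !is.na(y0) & !is.na(y1)
  d <- y1[keep] - y0[keep]
  n_pairs <- length(d)
  dz <- d[d != 0]
  nz <- length(dz)
  if (nz == 0) stop("all paired differences are zero", call. = FALSE)
  r <- rank(abs(dz))
  W <- sum(r[dz > 0])
  ties <- any(duplicated(abs(dz)))
  mu <- nz * (nz + 1) / 4
  tie_tab <- table(r)
  sig2 <- nz * (nz + 1) * (2 * nz + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- if (sig2 > 0) (W - mu - 0.5 * sign(W - mu)) / sqrt(sig2) else 0
  if (nz <= 25 && !ties) {
    method <- "exact"
    p <- min(1, 2 * min(stats::psignrank(W, nz),
                        stats::psignrank(W - 1, nz, lower.tail = FALSE)))
  } else {
    method <- "normal_approx"
    p <- 2 * pnorm(-abs(z))
  }
  tibble::tibble(test = "wilcoxon_signed_rank", statistic = W,
                 n_pairs = n_pairs, n_nonzero = nz,
                 p_raw = p, z = z,
                 effect = abs(z) / sqrt(n_pairs),
                 effect_name = "wilcoxon_r", method = method)
}

#' Per-participant change scores
#'
#' Computes `delta = Y(follow-up) - Y(baseline)` for one variable.
#' Participants missing the variable at either visit are excluded and
#' listed in the `"excluded_ids"` attribute.
#'
#' @param cohort Cohort tibble with `participant_id`, `timepoint` and
#'   the variable.
#' @param variable Column name.
#' @return Tibble: participant_id, baseline, followup, delta.
#' @export
change_scores <- function(cohort, variable) {
  wide <- cohort |>
    dplyr::select("participant_id", "timepoint",
                  value = dplyr::all_of(variable)) |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "value",
                       names_prefix = "t")
  if (!all(c("t0", "t1") %in% names(wide))) {
    stop("variable must be present at both timepoints", call. = FALSE)
  }
  ok <- !is.na(wide$t0) & !is.na(wide$t1)
  out <- tibble::tibble(participant_id = wide$participant_id[ok],
                        baseline = wide$t0[ok], followup = wide$t1[ok],
                        delta = wide$t1[ok] - wide$t0[ok])
  attr(out, "excluded_ids") <- wide$participant_id[!ok]
  out
}

#' Bonferroni correction
#'
#' `min(1, m * p)` with `m` defaulting to the number of p-values.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param m Number of tests in the family.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]", call. = FALSE)
  pmin(1, m * p)
}

#' Subgroup comparison battery
#'
#' Compares the two clusters on continuous variables (Welch t with
#' Cohen's d) at baseline and follow-up, on categorical variables
#' (Pearson chi-squared, at baseline), and — for variables with
#' sustained subgroup differences (Bonferroni-significant at both
#' visits) — on longitudinal course: within-subgroup time effects by
#' Wilcoxon signed-rank and a between-subgroup contrast of change
#' scores `delta = Y1 - Y0` by rank-sum, all with effect size r.
#' Bonferroni correction is applied within each reported family
#' (baseline, follow-up, longitudinal).
#'
#' @param cohort Preprocessed cohort tibble.
#' @param clusters A [cluster_features()] solution (or a tibble with
#'   `participant_id` and `cluster`).
#' @param continuous Continuous variables to compare; defaults to
#'   demographics, log10 CRP, composite, the nine domain Z-scores and
#'   the clinical scales (present columns only).
#' @param categorical Categorical variables (default sex and diagnosis
#'   composition).
#' @param alpha Familywise level used to decide which differences count
#'   as sustained.
#'
#' @return A tibble of class `"subgroup_profile"`: variable, timepoint,
#'   contrast, test, statistic, df, p_raw, p_bonferroni, effect,
#'   effect_name, group summaries, family.
#' @export
subgroup_profile <- function(cohort, clusters,
                             continuous = NULL,
                             categorical = c("sex", "diagnosis"),
                             alpha = 0.05) {
  labels <- if (inherits(clusters, "cluster_solution")) {
    clusters$labels
  } else {
    clusters
  }
  stopifnot(all(c("participant_id", "cluster") %in% names(labels)))
  if (length(unique(labels$cluster)) != 2) {
    stop("subgroup_profile expects a 2-cluster solution", call. = FALSE)
  }
  if (is.null(continuous)) {
    continuous <- intersect(
      c("age", "bmi", "education", "iq", "crp_log10", "composite",
        paste0("z_", cognitive_domains()), clinical_scales()),
      names(cohort))
  }
  df <- dplyr::inner_join(cohort, labels, by = "participant_id")

  cmp_tp <- function(var, tp) {
    sub <- df[df$timepoint == tp, ]
    x <- sub[[var]][sub$cluster == 1]
    y <- sub[[var]][sub$cluster == 2]
    if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) {
      warning("cluster with fewer than 2 observations for ", var,
              " at timepoint ", tp, "; contrast skipped")
      return(NULL)
    }
    dplyr::mutate(welch_t(x, y), variable = var, timepoint = tp,
                  contrast = "cluster1_vs_cluster2", .before = 1)
  }

  base_rows <- purrr::compact(purrr::map(continuous, cmp_tp, tp = 0))
  fup_rows <- purrr::compact(purrr::map(continuous, cmp_tp, tp = 1))

  cat_rows <- purrr::map(categorical, function(var) {
    sub <- df[df$timepoint == 0, ]
    tab <- table(sub$cluster, sub[[var]])
    dplyr::mutate(chi_squared(tab), variable = var, timepoint = 0,
                  contrast = "composition", .before = 1)
  })

  baseline <- dplyr::bind_rows(c(base_rows, cat_rows)) |>
    dplyr::mutate(family = "baseline",
                  p_bonferroni = bonferroni_adjust(.data$p_raw))
  followup <- dplyr::bind_rows(fup_rows) |>
    dplyr::mutate(family = "followup",
                  p_bonferroni = bonferroni_adjust(.data$p_raw))

  sig_at <- function(fam_tbl) {
    fam_tbl$variable[fam_tbl$p_bonferroni < alpha &
                       fam_tbl$contrast == "cluster1_vs_cluster2"]
  }
  sustained <- intersect(sig_at(baseline), sig_at(followup))

  long_rows <- purrr::map(sustained, function(var) {
    per_cluster <- purrr::map(1:2, function(cl) {
      ids <- labels$participant_id[labels$cluster == cl]
      sub <- df[df$participant_id %in% ids, ]
      cs <- change_scores(sub, var)
      if (nrow(cs) < 2 || all(cs$delta == 0)) return(NULL)
      dplyr::mutate(wilcoxon_signed_rank(cs$baseline, cs$followup),
                    variable = var, timepoint = NA_real_,
                    contrast = paste0("time_within_cluster", cl),
                    .before = 1)
    })
    cs_all <- change_scores(df, var)
    cs_all <- dplyr::inner_join(cs_all, labels, by = "participant_id")
    d1 <- cs_all$delta[cs_all$cluster == 1]
    d2 <- cs_all$delta[cs_all$cluster == 2]
    between <- NULL
    if (length(d1) >= 2 && length(d2) >= 2 && var(c(d1, d2)) > 0) {
      wt <- suppressWarnings(stats::wilcox.test(d1, d2, exact = FALSE,
                                                correct = TRUE))
      z <- qnorm(wt$p.value / 2, lower.tail = FALSE)
      between <- tibble::tibble(
        variable = var, timepoint = NA_real_,
        contrast = "change_cluster1_vs_cluster2",
        test = "wilcoxon_rank_sum", statistic = unname(wt$statistic),
        p_raw = wt$p.value, z = z,
        effect = z / sqrt(length(d1) + length(d2)),
        effect_name = "wilcoxon_r",
        mean1 = mean(d1), sd1 = sd(d1), n1 = length(d1),
        mean2 = mean(d2), sd2 = sd(d2), n2 = length(d2))
    }
    dplyr::bind_rows(c(purrr::compact(per_cluster), list(between)))
  })
  longitudinal <- dplyr::bind_rows(long_rows)
  if (nrow(longitudinal)) {
    longitudinal <- dplyr::mutate(
      longitudinal, family = "longitudinal",
      p_bonferroni = bonferroni_adjust(.data$p_raw))
  }

  out <- dplyr::bind_rows(baseline, followup, longitudinal) |>
    dplyr::relocate("variable", "timepoint", "contrast", "family",
                    "test", "statistic")
  class(out) <- c("subgroup_profile", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.subgroup_profile <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object),
                      .data$contrast == "cluster1_vs_cluster2")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = .data$variable,
                                   colour = factor(.data$timepoint))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$effect_lo, xmax = .data$effect_hi),
      height = 0.2, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "Cohen's d (cluster 1 - cluster 2)", y = NULL,
                  colour = "timepoint",
                  title = "Subgroup contrasts at baseline and follow-up") +
    ggplot2::theme_minimal()
}
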