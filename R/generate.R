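#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. Defaults
#' reproduce the structure of a two-visit case-control cohort of first
#' treatment schizophrenia-spectrum (SZ) and bipolar-spectrum (BD)
#' participants and healthy controls (HC): group sizes 133/88/220, a
#' latent two-subgroup mixture jointly shifting cognition and C-reactive
#' protein (CRP) with diagnosis-dependent mixing proportions
#' (SZ 0.75, BD 0.48, HC 0.38 for the higher-inflammation subgroup),
#' group-level cognitive offsets of -1 s.d. (SZ) and -0.5 s.d. (BD)
#' relative to HC, practice effects on four domains at follow-up, and a
#' follow-up visit roughly 400 days after baseline.
#'
#' The latent subgroup shifts are applied as within-diagnosis deviations
#' (`shift * (subgroup2 - p_g)` where `p_g` is the diagnosis mixing
#' proportion), so the diagnosis-group means equal `domain_offsets`
#' regardless of the mixing, HC baseline scores have mean 0 and s.d.
#' close to 1, and mean CRP does not differ between diagnostic groups.
#'
#' @param n_by_group Named counts of participants per diagnosis
#'   (`SZ`, `BD`, `HC`); all positive.
#' @param subgroup2_prob_by_group Named probabilities of latent
#'   subgroup 2 (higher inflammation - lower cognition) per diagnosis.
#' @param domain_offsets Named diagnosis offsets for cognitive scores in
#'   s.d. units.
#' @param subgroup2_cognition_shift Shift of all cognitive domains for
#'   latent subgroup 2 (s.d. units, negative = worse).
#' @param subgroup2_logcrp_shift Shift of log10 CRP for subgroup 2
#'   (log10 mg/L).
#' @param practice_effect_domains Domains receiving a practice effect at
#'   follow-up.
#' @param practice_effect_size Practice effect in s.d. units.
#' @param person_intercept_sd S.d. of the person-level cognitive
#'   intercept shared across domains and visits.
#' @param residual_sd S.d. of the per-cell cognitive residual.
#' @param crp_log10_mean Baseline constant of log10 CRP (log10 mg/L).
#' @param crp_person_sd Person-level s.d. of log10 CRP.
#' @param crp_visit_sd Within-person between-visit s.d. of log10 CRP
#'   (the paper-grade test-retest noise; treated as a free parameter).
#' @param bmi_logcrp_slope Slope of log10 CRP per kg/m2 of BMI
#'   (centred at 25).
#' @param clinical_subgroup_shift Multiplier on the subgroup-2 shifts of
#'   the clinical scales (1 = default severity difference, 0 = none).
#' @param missing_domain_prob Per-cell probability that a cognitive
#'   domain score is missing, used by [inject_missingness()].
#' @param missing_crp_prob Per-row probability that CRP is missing.
#' @param followup_gap_days_mean Mean days between baseline and
#'   follow-up; the gap is drawn uniformly within +/-150 days.
#' @param seed Integer seed; the generator is fully deterministic given
#'   the configuration.
#'
#' @return A list of class `"cohort_config"`.
#' @export
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$n_by_group
cohort_config <- function(n_by_group = c(SZ = 133, BD = 88, HC = 220),
                          subgroup2_prob_by_group =
                            c(SZ = 0.75, BD = 0.48, HC = 0.38),
                          domain_offsets = c(SZ = -1.0, BD = -0.5, HC = 0.0),
                          subgroup2_cognition_shift = -1.0,
                          subgroup2_logcrp_shift = 0.35,
                          practice_effect_domains =
                            c("fine_motor_speed", "psychomotor_speed",
                              "verbal_learning", "cognitive_control"),
                          practice_effect_size = 0.2,
                          person_intercept_sd = 0.25,
                          residual_sd = 0.85,
                          crp_log10_mean = 0.18,
                          crp_person_sd = 0.2,
                          crp_visit_sd = 0.05,
                          bmi_logcrp_slope = 0.02,
                          clinical_subgroup_shift = 1.0,
                          missing_domain_prob = 0.05,
                          missing_crp_prob = 0.02,
                          followup_gap_days_mean = 400,
                          seed = 1L) {
  groups <- c("SZ", "BD", "HC")
  n_by_group <- n_by_group[groups]
  subgroup2_prob_by_group <- subgroup2_prob_by_group[groups]
  domain_offsets <- domain_offsets[groups]
  if (anyNA(n_by_group) || any(n_by_group <= 0) ||
      any(n_by_group != round(n_by_group))) {
    stop("`n_by_group` must give a positive integer count for SZ, BD and HC",
         call. = FALSE)
  }
  probs <- c(subgroup2_prob_by_group, missing_domain_prob, missing_crp_prob)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  sds <- c(practice_effect_size = 0, person_intercept_sd = person_intercept_sd,
           residual_sd = residual_sd, crp_person_sd = crp_person_sd,
           crp_visit_sd = crp_visit_sd)
  if (any(sds < 0)) stop("s.d. parameters must be >= 0", call. = FALSE)
  if (anyNA(domain_offsets)) {
    stop("`domain_offsets` must name SZ, BD and HC", call. = FALSE)
  }
  bad <- setdiff(practice_effect_domains, cognitive_domains())
  if (length(bad)) {
    stop("unknown practice-effect domains: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    n_by_group = n_by_group,
    subgroup2_prob_by_group = subgroup2_prob_by_group,
    domain_offsets = domain_offsets,
    subgroup2_cognition_shift = subgroup2_cognition_shift,
    subgroup2_logcrp_shift = subgroup2_logcrp_shift,
    practice_effect_domains = practice_effect_domains,
    practice_effect_size = practice_effect_size,
    person_intercept_sd = person_intercept_sd,
    residual_sd = residual_sd,
    crp_log10_mean = crp_log10_mean,
    crp_person_sd = crp_person_sd,
    crp_visit_sd = crp_visit_sd,
    bmi_logcrp_slope = bmi_logcrp_slope,
    clinical_subgroup_shift = clinical_subgroup_shift,
    missing_domain_prob = missing_domain_prob,
    missing_crp_prob = missing_crp_prob,
    followup_gap_days_mean = followup_gap_days_mean,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# clinical scale parameters: natural range, subgroup-1 baseline mean,
# subgroup-2 additive shift (worse), follow-up change, s.d.
# the disorganized factor has zero time effect (stays stable).
clinical_params <- function() {
  tibble::tribble(
    ~scale,               ~lo, ~hi, ~base, ~sg2,  ~time, ~sd,
    "panss_positive",       4,  28,   9.0,  2.5,  -2.0,  3.0,
    "panss_negative",       6,  42,  12.0,  3.0,  -2.5,  4.0,
    "panss_disorganized",   3,  21,   5.5,  1.5,   0.0,  2.0,
    "panss_excited",        4,  28,   6.5,  1.0,  -1.0,  2.0,
    "panss_depressed",      3,  21,   7.0,  1.5,  -1.5,  2.5,
    "ymrs",                 0,  60,   5.0,  2.0,  -2.0,  4.0,
    "gaf_s",                1, 100,  58.0, -7.0,   6.0,  9.0,
    "gaf_f",                1, 100,  57.0, -7.0,   5.0,  9.0
  )
}

#' Generate a synthetic longitudinal inflammatory-cognitive cohort
#'
#' Simulates a two-visit cohort with the generative structure assumed by
#' the subgrouping analysis: nine cognitive domain scores per visit built
#' from a diagnosis offset, a latent-subgroup shift, a shared person
#' intercept, practice effects on a subset of domains at follow-up and
#' Gaussian residuals; CRP generated on the log10 scale from a baseline
#' constant, the latent-subgroup shift, a BMI slope and person-level
#' noise, nearly constant across visits, then back-transformed to mg/L;
#' clinical scales (five PANSS factors, YMRS, GAF symptom/function) for
#' SMI participants only, with subgroup 2 more severe and improvement at
#' follow-up except the disorganized factor.
#'
#' @param config A [cohort_config()].
#'
#' @return A list of class `"cohort_sim"` with elements
#'   * `cohort`: tibble with one row per participant and visit
#'     (`timepoint` 0/1) holding demographics, `crp` (mg/L), raw domain
#'     scores and clinical scales (`NA` for HC);
#'   * `latent`: tibble with one row per participant giving
#'     `true_subgroup` (1 or 2) and the person intercept, the ground
#'     truth for recovery experiments.
#' @export
#' @examples
#' sim <- generate_cohort(cohort_config(seed = 1))
#' dplyr::count(sim$cohort, diagnosis, timepoint)
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be created by cohort_config()", call. = FALSE)
  }
  domains <- cognitive_domains()
  with_seed(config$seed, {
    groups <- rep(names(config$n_by_group), config$n_by_group)
    n <- length(groups)
    id <- sprintf("P%04d", seq_len(n))
    p2 <- unname(config$subgroup2_prob_by_group[groups])
    sg2 <- rbinom(n, 1L, p2)
    intercept <- rnorm(n, 0, config$person_intercept_sd)

    female_prob <- c(SZ = 0.42, BD = 0.58, HC = 0.49)[groups]
    sex <- ifelse(runif(n) < female_prob, "F", "M")
    age_mu <- c(SZ = 27, BD = 29, HC = 31)[groups]
    age_sd <- c(SZ = 7, BD = 9, HC = 8)[groups]
    age <- pmin(pmax(rnorm(n, age_mu, age_sd), 18), 65)
    bmi <- pmin(pmax(rnorm(n, 25, 3.8), 16), 45)

    cog_shift <- config$subgroup2_cognition_shift * (sg2 - p2)
    latent_cog <- unname(config$domain_offsets[groups]) + cog_shift + intercept
    education <- pmax(9, 13 + 0.8 * latent_cog + rnorm(n, 0, 1.8))
    iq <- pmax(70, 105 + 8 * latent_cog + rnorm(n, 0, 8))

    logcrp_person <- config$crp_log10_mean +
      config$subgroup2_logcrp_shift * (sg2 - p2) +
      config$bmi_logcrp_slope * (bmi - 25) +
      rnorm(n, 0, config$crp_person_sd)

    gap <- runif(n, config$followup_gap_days_mean - 150,
                 config$followup_gap_days_mean + 150)

    rows <- purrr::map(0:1, function(tp) {
      base <- unname(config$domain_offsets[groups]) + cog_shift + intercept
      dm <- vapply(domains, function(d) {
        practice <- if (tp == 1 && d %in% config$practice_effect_domains) {
          config$practice_effect_size
        } else 0
        base + practice + rnorm(n, 0, config$residual_sd)
      }, numeric(n))
      colnames(dm) <- domains
      crp <- 10^(logcrp_person + rnorm(n, 0, config$crp_visit_sd))
      tibble::tibble(
        participant_id = id, diagnosis = groups, timepoint = tp,
        visit_day = if (tp == 0) 0 else round(gap),
        sex = sex, age = age, bmi = bmi,
        education = education, iq = iq, crp = crp
      ) |>
        dplyr::bind_cols(tibble::as_tibble(dm))
    })

    cp <- clinical_params()
    clin <- purrr::map(0:1, function(tp) {
      out <- matrix(NA_real_, nrow = n, ncol = nrow(cp),
                    dimnames = list(NULL, cp$scale))
      smi <- groups != "HC"
      for (r in seq_len(nrow(cp))) {
        mu <- cp$base[r] + config$clinical_subgroup_shift * cp$sg2[r] * sg2 +
          cp$time[r] * tp
        v <- rnorm(n, mu, cp$sd[r])
        v <- pmin(pmax(v, cp$lo[r]), cp$hi[r])
        v[!smi] <- NA_real_
        out[, r] <- v
      }
      tibble::as_tibble(out)
    })

    cohort <- dplyr::bind_rows(
      dplyr::bind_cols(rows[[1]], clin[[1]]),
      dplyr::bind_cols(rows[[2]], clin[[2]])
    ) |>
      dplyr::arrange(.data$participant_id, .data$timepoint)

    latent <- tibble::tibble(
      participant_id = id,
      diagnosis = groups,
      true_subgroup = sg2 + 1L,
      person_intercept = intercept
    )
    structure(list(cohort = cohort, latent = latent, config = config),
              class = "cohort_sim")
  })
}

#' Inject item-level missingness into a cohort table
#'
#' Independently blanks each cognitive domain cell with probability
#' `missing_domain_prob` and each CRP value with `missing_crp_prob`
#' (both from the configuration). Deterministic given the configuration
#' seed; the missingness stream is derived from the generator seed so it
#' does not perturb cohort generation.
#'
#' @param cohort A cohort tibble (e.g. `generate_cohort(cfg)$cohort`).
#' @param config The [cohort_config()] used to generate it.
#'
#' @return The cohort tibble with `NA`s injected.
#' @export
inject_missingness <- function(cohort, config) {
  stopifnot(inherits(config, "cohort_config"))
  pd <- config$missing_domain_prob
  pc <- config$missing_crp_prob
  if (pd < 0 || pd > 1 || pc < 0 || pc > 1) {
    stop("missingness probabilities must lie in [0, 1]", call. = FALSE)
  }
  with_seed(derive_seed(config$seed, "missingness"), {
    n <- nrow(cohort)
    for (d in cognitive_domains()) {
      cohort[[d]][runif(n) < pd] <- NA_real_
    }
    cohort$crp[runif(n) < pc] <- NA_real_
    cohort
  })
}
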