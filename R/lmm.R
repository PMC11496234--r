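#' Build the design for a random-intercept mixed model
#'
#' Assembles the response vector, fixed-effect matrix and participant
#' index for one outcome. The fixed effects are an intercept, time
#' (coded 0/1), diagnosis dummies (BD and SZ against the HC reference),
#' their time interactions, age and sex, plus BMI when
#' `include_bmi = TRUE` (the CRP model). Rows with a missing outcome or
#' covariate are dropped listwise; participants left with a single
#' visit are retained and still inform the fixed effects.
#'
#' @param cohort Preprocessed cohort tibble.
#' @param outcome Name of the outcome column (e.g. `"z_attention"` or
#'   `"crp_log10"`).
#' @param include_bmi Add BMI as a covariate?
#'
#' @return A list of class `"lmm_design"` with `y`, `X`, `id`,
#'   `outcome`, `n_obs`, `n_participants`.
#' @export
build_design <- function(cohort, outcome, include_bmi = FALSE) {
  covars <- c("timepoint", "diagnosis", "age", "sex",
              if (include_bmi) "bmi")
  need <- c("participant_id", outcome, covars)
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- cohort[need]
  df <- df[complete.cases(df), ]
  df$diagnosis <- factor(df$diagnosis, levels = c("HC", "BD", "SZ"))
  df$sex <- factor(df$sex)
  df$time <- as.numeric(df$timepoint)
  fml <- stats::as.formula(paste(
    "~ time * diagnosis + age + sex", if (include_bmi) "+ bmi"))
  X <- model.matrix(fml, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; collinear terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  structure(list(y = df[[outcome]], X = X,
                 id = as.character(df$participant_id),
                 outcome = outcome, n_obs = nrow(X),
                 n_participants = length(unique(df$participant_id))),
            class = "lmm_design")
}

# REML profile criterion for the random-intercept model, parameterized
# on the variance ratio lambda = sigma2_b / sigma2_e. For participant i
# with n_i rows, V_i/sigma2_e = I + lambda J, whose inverse is
# I - (lambda / (1 + n_i lambda)) J, so all GLS quantities reduce to
# per-participant sums.
reml_pieces <- function(design, lambda) {
  X <- design$X
  y <- design$y
  id <- design$id
  p <- ncol(X)
  N <- length(y)
  Xs <- rowsum(X, id)
  ys <- rowsum(y, id)
  ni <- tabulate(factor(id, levels = rownames(Xs)))
  ci <- lambda / (1 + ni * lambda)
  XtWX <- crossprod(X) - crossprod(Xs * sqrt(ci), Xs * sqrt(ci))
  XtWy <- crossprod(X, y) - crossprod(Xs, ys * ci)
  beta <- solve(XtWX, XtWy)
  r <- y - X %*% beta
  rs <- rowsum(as.vector(r), id)
  quad <- sum(r^2) - sum(ci * rs^2)
  sigma2e <- quad / (N - p)
  logdetV <- sum(log1p(ni * lambda))
  ld <- determinant(XtWX, logarithm = TRUE)$modulus
  crit <- if (sigma2e <= 0) Inf else {
    -0.5 * ((N - p) * log(sigma2e) + logdetV + as.numeric(ld) + (N - p))
  }
  list(beta = as.vector(beta), sigma2e = sigma2e, crit = crit,
       XtWX = XtWX, quad = quad, N = N, p = p)
}

#' Fit a random-intercept linear mixed model by REML
#'
#' Maximizes the restricted likelihood of the compound-symmetry
#' random-intercept model over the variance ratio
#' `lambda = sigma2_b / sigma2_e` by one-dimensional bounded search on
#' `log(lambda)` in `[-12, 12]` (tolerance 1e-9), with the fixed
#' effects obtained by generalized least squares given `lambda` and the
#' residual variance profiled out. The per-participant block structure
#' is exploited in closed form, so no general matrix factorizations of
#' the full covariance are needed. If the criterion is maximized at the
#' `lambda -> 0` boundary the ordinary-least-squares limit is returned
#' with `sigma2_b = 0` and a boundary flag.
#'
#' @param design An [build_design()] object.
#'
#' @return An object of class `"lmm_fit"`: fixed-effect estimates
#'   (`beta`), standard errors (`se_beta`), Wald `z` and `p`, variance
#'   components `sigma2_b` and `sigma2_e`, `reml_loglik` (the profiled
#'   criterion up to an additive constant), sample sizes, `boundary`
#'   flag.
#' @export
fit_reml <- function(design) {
  stopifnot(inherits(design, "lmm_design"))
  two_visits <- sum(table(design$id) >= 2)
  if (two_visits < 2) {
    stop("need at least two participants with two visits to identify ",
         "the variance ratio", call. = FALSE)
  }
  # perfect-fit guard: residual variance numerically zero
  ols <- reml_pieces(design, 0)
  if (ols$quad < 1e-10 * max(1, sum(design$y^2))) {
    se <- rep(0, length(ols$beta))
    return(new_lmm_fit(design, ols$beta, se, sigma2_b = 0,
                       sigma2_e = ols$sigma2e, loglik = Inf,
                       boundary = TRUE))
  }
  crit_fun <- function(loglam) reml_pieces(design, exp(loglam))$crit
  opt <- optimize(crit_fun, interval = c(-12, 12), maximum = TRUE,
                  tol = 1e-9)
  if (!is.finite(opt$objective)) {
    stop("REML criterion did not evaluate to a finite value",
         call. = FALSE)
  }
  boundary <- FALSE
  if (ols$crit >= opt$objective || opt$maximum <= -12 + 1e-6) {
    lambda <- 0
    pieces <- ols
    loglik <- ols$crit
    boundary <- TRUE
  } else {
    lambda <- exp(opt$maximum)
    pieces <- reml_pieces(design, lambda)
    loglik <- opt$objective
  }
  covb <- pieces$sigma2e * solve(pieces$XtWX)
  se <- sqrt(diag(covb))
  new_lmm_fit(design, pieces$beta, se,
              sigma2_b = lambda * pieces$sigma2e,
              sigma2_e = pieces$sigma2e, loglik = loglik,
              boundary = boundary)
}

new_lmm_fit <- function(design, beta, se, sigma2_b, sigma2_e, loglik,
                        boundary) {
  names(beta) <- colnames(design$X)
  names(se) <- colnames(design$X)
  z <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf))
  structure(list(outcome = design$outcome, beta = beta, se_beta = se,
                 wald_z = z, p = 2 * pnorm(-abs(z)),
                 sigma2_b = sigma2_b, sigma2_e = sigma2_e,
                 reml_loglik = loglik, n_obs = design$n_obs,
                 n_participants = design$n_participants,
                 boundary = boundary),
            class = "lmm_fit")
}

#' Wald tests for the fixed effects
#'
#' Normal-approximation Wald tests: `z = beta / se` with two-sided
#' p-values from the standard normal. (No small-sample degrees-of-
#' freedom correction is applied.)
#'
#' @param fit An [fit_reml()] object.
#' @return Tibble with term, estimate, std.error, statistic, p.value.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  tibble::tibble(term = names(fit$beta), estimate = unname(fit$beta),
                 std.error = unname(fit$se_beta),
                 statistic = unname(fit$wald_z),
                 p.value = unname(fit$p))
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> outcome = ", x$outcome, ", n = ", x$n_obs,
      " observations of ", x$n_participants, " participants\n",
      "  sigma2_b = ", format(x$sigma2_b, digits = 4),
      ", sigma2_e = ", format(x$sigma2_e, digits = 4),
      if (x$boundary) "  (boundary: random-intercept variance at 0)",
      "\n", sep = "")
  print(wald_tests(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lmm_fit <- function(x, ...) wald_tests(x)

#' @exportS3Method generics::glance
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(sigma2_b = x$sigma2_b, sigma2_e = x$sigma2_e,
                 reml_loglik = x$reml_loglik, n_obs = x$n_obs,
                 n_participants = x$n_participants,
                 boundary = x$boundary)
}

#' Fit mixed models for all outcomes
#'
#' Fits the random-intercept model separately for each cognitive domain
#' Z-score and for log10 CRP (which additionally adjusts for BMI), and
#' reports Bonferroni-adjusted p-values across the outcome family
#' alongside the raw ones.
#'
#' @param cohort Preprocessed cohort tibble.
#' @param outcomes Outcome columns; defaults to the nine `z_` domains
#'   plus `crp_log10`.
#'
#' @return A tibble with one row per outcome and term: estimate,
#'   std.error, statistic, p.value, p.bonferroni (adjusted across
#'   outcomes within each term), variance components and sample sizes.
#'   Outcomes whose fit fails are reported with an `error` message and
#'   do not abort the batch.
#' @export
fit_all_outcomes <- function(cohort, outcomes = NULL) {
  if (is.null(outcomes)) {
    outcomes <- c(paste0("z_", cognitive_domains()), "crp_log10")
  }
  res <- purrr::map(outcomes, function(oc) {
    tryCatch({
      fit <- fit_reml(build_design(cohort, oc,
                                   include_bmi = oc == "crp_log10"))
      dplyr::mutate(wald_tests(fit), outcome = oc,
                    sigma2_b = fit$sigma2_b, sigma2_e = fit$sigma2_e,
                    n_obs = fit$n_obs,
                    n_participants = fit$n_participants,
                    error = NA_character_, .before = 1)
    }, error = function(e) {
      tibble::tibble(outcome = oc, error = conditionMessage(e))
    })
  })
  out <- dplyr::bind_rows(res)
  m <- length(outcomes)
  dplyr::mutate(dplyr::group_by(out, .data$term),
                p.bonferroni = bonferroni_adjust(.data$p.value, m = m)) |>
    dplyr::ungroup() |>
    dplyr::relocate("outcome", "term", "estimate", "std.error",
                    "statistic", "p.value", "p.bonferroni")
}
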