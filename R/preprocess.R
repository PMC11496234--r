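#' Log10-transform CRP
#'
#' Adds a `crp_log10` column. CRP values must be positive; laboratory
#' reports below the detection limit (e.g. `"<0.6"` parsed upstream to a
#' limit via `detection_limit`) can be mapped to half the limit before
#' the transform, a common convention.
#'
#' @param cohort Cohort tibble with a `crp` column in mg/L.
#' @param detection_limit Optional positive limit L; non-missing CRP
#'   values below L are replaced by L/2 before the transform.
#'
#' @return The tibble with `crp_log10` added (missing CRP propagates).
#' @export
#' @examples
#' log10_crp(tibble::tibble(crp = c(10, 1, NA)))$crp_log10
log10_crp <- function(cohort, detection_limit = NULL) {
  crp <- cohort$crp
  if (!is.null(detection_limit)) {
    stopifnot(detection_limit > 0)
    crp[!is.na(crp) & crp < detection_limit] <- detection_limit / 2
  }
  if (any(!is.na(crp) & crp <= 0)) {
    stop("CRP must be positive (mg/L); use `detection_limit` for ",
         "below-detection values", call. = FALSE)
  }
  cohort$crp <- crp
  cohort$crp_log10 <- log10(crp)
  cohort
}

#' Exclude participants with signs of acute infection
#'
#' Removes all rows of any participant whose CRP exceeds `threshold`
#' (strictly) at either visit, the conventional acute-infection screen
#' at CRP > 10 mg/L. Missing CRP at a visit does not trigger exclusion.
#'
#' @param cohort Cohort tibble with `participant_id` and `crp`.
#' @param threshold Exclusion threshold in mg/L.
#'
#' @return The filtered tibble; the excluded participant ids are
#'   attached as attribute `"excluded_ids"` (also retrievable with
#'   [excluded_ids()]).
#' @export
exclude_acute_infection <- function(cohort, threshold = 10) {
  flagged <- cohort$participant_id[!is.na(cohort$crp) &
                                     cohort$crp > threshold]
  flagged <- sort(unique(flagged))
  out <- dplyr::filter(cohort, !.data$participant_id %in% flagged)
  attr(out, "excluded_ids") <- flagged
  out
}

#' @rdname exclude_acute_infection
#' @param x A tibble returned by [exclude_acute_infection()].
#' @export
excluded_ids <- function(x) attr(x, "excluded_ids")

#' Standardize cognitive domain scores against the HC baseline
#'
#' Computes Z-scores for each of the nine cognitive domains using the
#' healthy control group's mean and s.d. at baseline as the fixed
#' reference, applied to all rows (every diagnosis, both visits) so that
#' longitudinal change stays interpretable on a single scale.
#'
#' @param cohort Cohort tibble with `diagnosis`, `timepoint` and the raw
#'   domain columns.
#'
#' @return The tibble with `z_<domain>` columns added; the reference
#'   means and s.d.s are attached as attribute `"standardization"`
#'   (a tibble) for audit.
#' @export
standardize_cognition <- function(cohort) {
  hc <- dplyr::filter(cohort, .data$diagnosis == "HC", .data$timepoint == 0)
  ref <- purrr::map_dfr(cognitive_domains(), function(d) {
    x <- hc[[d]]
    x <- x[!is.na(x)]
    if (length(x) < 2) {
      stop("need at least two HC baseline observations for domain ", d,
           call. = FALSE)
    }
    s <- sd(x)
    if (s == 0) {
      stop("HC baseline s.d. is zero for domain ", d, call. = FALSE)
    }
    tibble::tibble(domain = d, mean = mean(x), sd = s)
  })
  for (i in seq_len(nrow(ref))) {
    d <- ref$domain[i]
    cohort[[paste0("z_", d)]] <- (cohort[[d]] - ref$mean[i]) / ref$sd[i]
  }
  attr(cohort, "standardization") <- ref
  cohort
}

#' Cognitive composite score
#'
#' The composite is the mean of the available domain Z-scores at a
#' visit, computed only for participants with at least `min_domains`
#' non-missing domains at baseline (and, symmetrically, at follow-up for
#' the follow-up composite); otherwise it is missing.
#'
#' @param cohort Cohort tibble with `z_<domain>` columns (see
#'   [standardize_cognition()]).
#' @param min_domains Minimum number of non-missing domains required.
#'
#' @return The tibble with a `composite` column added.
#' @export
cognitive_composite <- function(cohort, min_domains = 5) {
  zcols <- paste0("z_", cognitive_domains())
  missing_cols <- setdiff(zcols, names(cohort))
  if (length(missing_cols)) {
    stop("standardized columns missing; run standardize_cognition() first",
         call. = FALSE)
  }
  zm <- as.matrix(cohort[zcols])
  avail <- rowSums(!is.na(zm))
  comp <- rowMeans(zm, na.rm = TRUE)
  comp[avail == 0] <- NA_real_
  comp[avail < min_domains] <- NA_real_
  # the baseline rule governs both visits: a participant without a valid
  # baseline composite has no composite at follow-up either
  base_ok <- cohort$participant_id[cohort$timepoint == 0 &
                                     avail >= min_domains]
  comp[!cohort$participant_id %in% base_ok] <- NA_real_
  cohort$composite <- comp
  cohort
}

#' Build the clustering feature matrix
#'
#' Assembles the n x 2 complete-case baseline matrix (column 1 = log10
#' CRP, column 2 = cognitive composite) that feeds hierarchical
#' clustering. Participants missing either feature at baseline are
#' dropped. By default both columns are centred and scaled to unit
#' variance before Euclidean distances are computed, since log10 CRP and
#' the composite otherwise live on unequal scales; disable with
#' `scale_features = FALSE`.
#'
#' @param cohort Preprocessed cohort tibble (needs `crp_log10` and
#'   `composite`).
#' @param scale_features Standardize each column to mean 0, s.d. 1?
#'
#' @return An object of class `"feature_matrix"`: list with
#'   `participant_ids`, `X` (the matrix used downstream), `X_raw`
#'   (before scaling), `scaled`, `center`, `scale`.
#' @export
build_feature_matrix <- function(cohort, scale_features = TRUE) {
  base <- dplyr::filter(cohort, .data$timepoint == 0) |>
    dplyr::arrange(.data$participant_id)
  keep <- !is.na(base$crp_log10) & !is.na(base$composite)
  base <- base[keep, ]
  X <- cbind(crp_log10 = base$crp_log10, composite = base$composite)
  feature_matrix(X, ids = base$participant_id,
                 scale_features = scale_features)
}

#' @rdname build_feature_matrix
#' @param X Numeric matrix of raw feature values (no missing entries).
#' @param ids Optional row identifiers (default `1..n` as character).
#' @export
feature_matrix <- function(X, ids = NULL, scale_features = TRUE) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("feature matrix must be complete-case", call. = FALSE)
  if (nrow(X) < 10) {
    stop("fewer than 10 complete cases; clustering is not meaningful",
         call. = FALSE)
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  ctr <- rep(0, ncol(X))
  scl <- rep(1, ncol(X))
  Xs <- X
  if (scale_features) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    if (any(scl == 0)) stop("constant feature column", call. = FALSE)
    Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  structure(list(participant_ids = ids, X = Xs, X_raw = X,
                 scaled = scale_features, center = ctr, scale = scl),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$X), " participants x ", ncol(x$X),
      " features (", paste(colnames(x$X), collapse = ", "), ")",
      if (x$scaled) "; columns scaled to unit variance" else "", "\n",
      sep = "")
  invisible(x)
}
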