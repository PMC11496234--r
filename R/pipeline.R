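#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis: the input source
#' (a [cohort_config()] for synthetic data, or a CSV path), the
#' preprocessing options, the clustering options and the Monte-Carlo
#' sizes. A single `seed` deterministically spawns independent
#' per-stage streams, so e.g. changing the number of bootstrap
#' resamples does not perturb the null test.
#'
#' @param input A [cohort_config()] (synthetic cohort) or a path to a
#'   long-format cohort CSV.
#' @param scale_features Scale the two clustering features to unit
#'   variance (see [build_feature_matrix()]).
#' @param linkage Linkage override; `NULL` selects by agglomerative
#'   coefficient.
#' @param k Fixed number of clusters; `NULL` selects by silhouette.
#' @param k_range Candidate cluster numbers.
#' @param ward_dialect Ward dialect for [agglomerate()].
#' @param M Null simulations for [gaussian_null_test()].
#' @param B Bootstrap resamples for [bootstrap_stability()].
#' @param n_perm Permutations for [pairwise_permutation_t()].
#' @param alpha Significance level for the cluster-existence gate.
#' @param force Run the subgroup profile even when the null test does
#'   not reject at `alpha`.
#' @param crp_threshold Acute-infection exclusion threshold (mg/L).
#' @param detection_limit Optional CRP detection limit (see
#'   [log10_crp()]).
#' @param seed Integer master seed.
#'
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = cohort_config(),
                            scale_features = TRUE, linkage = NULL,
                            k = NULL, k_range = 2:8,
                            ward_dialect = "D2", M = 999, B = 100,
                            n_perm = 10000, alpha = 0.05, force = FALSE,
                            crp_threshold = 10, detection_limit = NULL,
                            seed = 1L) {
  if (!inherits(input, "cohort_config") &&
      !(is.character(input) && length(input) == 1)) {
    stop("`input` must be a cohort_config() or a CSV path", call. = FALSE)
  }
  if (is.character(input) && !file.exists(input)) {
    stop("input CSV not found: ", input, call. = FALSE)
  }
  if (M < 19 || B < 20) stop("M >= 19 and B >= 20 required", call. = FALSE)
  structure(list(input = input, scale_features = scale_features,
                 linkage = linkage, k = k, k_range = k_range,
                 ward_dialect = ward_dialect, M = M, B = B,
                 n_perm = n_perm, alpha = alpha, force = force,
                 crp_threshold = crp_threshold,
                 detection_limit = detection_limit,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full subgrouping analysis
#'
#' Executes the stages in their canonical order: ingest (simulate or
#' read), preprocess (log10 CRP, acute-infection exclusion,
#' HC-baseline standardization, composite, feature matrix), linear
#' mixed models per outcome, hierarchical clustering with linkage and
#' k selection, cluster validation (single-Gaussian existence test and
#' bootstrap Jaccard stability) and the subgroup comparison battery.
#' If the existence test does not reject at `alpha` the profile stage
#' halts with an error unless `force = TRUE` was configured. The report
#' is bit-identical under a fixed configuration and seed.
#'
#' @param config A [pipeline_config()].
#'
#' @return A list of class `"run_report"` with elements `config`,
#'   `cohort` (preprocessed), `latent` (synthetic truth or `NULL`),
#'   `excluded_ids`, `standardization`, `lmm`, `features`, `clusters`,
#'   `null_test`, `stability`, `profile`, `recovery_ari` (if latent
#'   truth and mclust are available), `seeds`, `timings`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list(
    generator = if (inherits(config$input, "cohort_config"))
      config$input$seed else NA_integer_,
    null_test = derive_seed(config$seed, "null_test"),
    stability = derive_seed(config$seed, "stability"),
    permutation = derive_seed(config$seed, "permutation"))
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  latent <- NULL
  cohort <- clock("ingest", {
    if (inherits(config$input, "cohort_config")) {
      sim <- generate_cohort(config$input)
      latent <- sim$latent
      inject_missingness(sim$cohort, config$input)
    } else {
      read_cohort_csv(config$input,
                      detection_limit = config$detection_limit)
    }
  })

  cohort <- clock("preprocess", {
    cohort |>
      log10_crp(detection_limit = config$detection_limit) |>
      exclude_acute_infection(threshold = config$crp_threshold) |>
      standardize_cognition() |>
      cognitive_composite()
  })
  excluded <- excluded_ids(cohort)
  standardization <- attr(cohort, "standardization")
  fm <- build_feature_matrix(cohort,
                             scale_features = config$scale_features)

  lmm <- clock("lmm", fit_all_outcomes(cohort))

  clusters <- clock("cluster", {
    cluster_features(fm, linkage = config$linkage, k = config$k,
                     k_range = config$k_range,
                     ward_dialect = config$ward_dialect)
  })

  null_test <- clock("null_test", {
    gaussian_null_test(fm, k = clusters$k, linkage = clusters$linkage,
                       M = config$M, seed = seeds$null_test,
                       ward_dialect = config$ward_dialect)
  })
  stability <- clock("stability", {
    bootstrap_stability(fm, k = clusters$k, linkage = clusters$linkage,
                        B = config$B, seed = seeds$stability,
                        ward_dialect = config$ward_dialect)
  })

  profile <- NULL
  if (null_test$p_value > config$alpha && !config$force) {
    stop(structure(class = c("cluster_existence_error", "error",
                             "condition"),
                   list(message = sprintf(
                     paste0("cluster existence test did not reject ",
                            "(p = %.4g > alpha = %g); subgroup profiling ",
                            "halted - set force = TRUE to override"),
                     null_test$p_value, config$alpha),
                     call = NULL)))
  }
  if (clusters$k == 2) {
    profile <- clock("profile", subgroup_profile(cohort, clusters,
                                                 alpha = config$alpha))
  }

  recovery_ari <- NULL
  if (!is.null(latent) && requireNamespace("mclust", quietly = TRUE)) {
    joined <- dplyr::inner_join(clusters$labels, latent,
                                by = "participant_id")
    recovery_ari <- mclust::adjustedRandIndex(joined$cluster,
                                              joined$true_subgroup)
  }

  structure(list(config = config, cohort = cohort, latent = latent,
                 excluded_ids = excluded,
                 standardization = standardization, lmm = lmm,
                 features = fm, clusters = clusters,
                 null_test = null_test, stability = stability,
                 profile = profile, recovery_ari = recovery_ari,
                 seeds = seeds, timings = timings),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  participants clustered:", nrow(x$clusters$labels),
      "| excluded (CRP >", x$config$crp_threshold, "mg/L):",
      length(x$excluded_ids), "\n")
  cat("  linkage:", x$clusters$linkage,
      "| k =", x$clusters$k,
      "| AC =", format(x$clusters$agglomerative_coefficient, digits = 3),
      "| mean silhouette =",
      format(x$clusters$mean_silhouette, digits = 3), "\n")
  cat("  existence test p =", format(x$null_test$p_value, digits = 4),
      "| Jaccard stability:",
      paste(format(x$stability$summary$mean_jaccard, digits = 3),
            collapse = ", "), "\n")
  if (!is.null(x$recovery_ari)) {
    cat("  adjusted Rand index vs latent truth:",
        format(x$recovery_ari, digits = 3), "\n")
  }
  invisible(x)
}

#' Read a long-format cohort CSV
#'
#' Reads a participant-visit table following the documented column
#' dictionary (`participant_id`, `diagnosis`, `timepoint`, `visit_day`,
#' `sex`, `age`, `bmi`, `crp`, the nine domain columns, optional
#' clinical columns). Unknown columns are kept with a warning; missing
#' mandatory columns and duplicated (participant, timepoint) pairs are
#' fatal. CRP entries like `"<0.6"` are mapped to half the stated limit
#' when `detection_limit` is set, otherwise they are an error.
#'
#' @param path CSV path.
#' @param detection_limit Optional CRP detection limit in mg/L.
#' @return A cohort tibble.
#' @export
read_cohort_csv <- function(path, detection_limit = NULL) {
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  char_cols <- intersect(c("participant_id", "diagnosis", "sex", "crp"),
                         header)
  spec <- do.call(readr::cols,
                  c(stats::setNames(rep(list(readr::col_character()),
                                        length(char_cols)), char_cols),
                    list(.default = readr::col_guess())))
  df <- readr::read_csv(path, show_col_types = FALSE, col_types = spec)
  mandatory <- c("participant_id", "diagnosis", "timepoint", "crp",
                 cognitive_domains())
  miss <- setdiff(mandatory, names(df))
  if (length(miss)) {
    stop("missing mandatory columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  known <- c(mandatory, "visit_day", "sex", "age", "bmi", "education",
             "iq", clinical_scales())
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    warning("unknown columns kept as-is: ",
            paste(unknown, collapse = ", "))
  }
  dup <- df[duplicated(df[c("participant_id", "timepoint")]), ]
  if (nrow(dup)) {
    stop("duplicated (participant, timepoint) rows: ",
         paste(unique(paste0(dup$participant_id, "/t", dup$timepoint)),
               collapse = ", "), call. = FALSE)
  }
  crp <- df$crp
  below <- !is.na(crp) & grepl("^<", crp)
  if (any(below)) {
    if (is.null(detection_limit)) {
      stop("CRP values below detection (e.g. \"", crp[below][1],
           "\") need the `detection_limit` option", call. = FALSE)
    }
    crp[below] <- as.numeric(sub("^<", "", crp[below])) / 2
  }
  df$crp <- as.numeric(crp)
  if (any(!is.na(df$crp) & df$crp < 0)) {
    stop("CRP must be non-negative (mg/L)", call. = FALSE)
  }
  df
}

#' Write a cohort (and latent labels) to CSV
#'
#' @param x A cohort tibble or a `generate_cohort()` result; for the
#'   latter the latent labels are written alongside with suffix
#'   `_latent.csv`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(x, path) {
  if (inherits(x, "cohort_sim")) {
    readr::write_csv(x$cohort, path)
    readr::write_csv(x$latent, sub("\\.csv$", "_latent.csv", path))
  } else {
    readr::write_csv(x, path)
  }
  invisible(path)
}

#' Write a machine-readable report
#'
#' Writes the run report as JSON (configuration echo, seeds, headline
#' numbers, silhouette curve, AC table, stability summary), TSV tables
#' (mixed models, subgroup profile, cluster labels) and the dendrogram
#' in Newick form. Stage timings go to a separate file so the main
#' report is reproducible bit-for-bit under a fixed seed.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- report$clusters
  summary <- list(
    seed = report$config$seed,
    seeds = report$seeds,
    n_clustered = nrow(cl$labels),
    excluded_ids = as.list(report$excluded_ids),
    scale_features = report$config$scale_features,
    linkage = cl$linkage,
    ward_dialect = cl$ward_dialect,
    k = cl$k,
    agglomerative_coefficient = round(cl$agglomerative_coefficient, 12),
    mean_silhouette = round(cl$mean_silhouette, 12),
    ac_table = if (!is.null(cl$ac_table)) {
      setNames(as.list(round(cl$ac_table$ac, 12)), cl$ac_table$linkage)
    },
    silhouette_by_k = if (!is.null(cl$k_selection)) {
      setNames(as.list(round(cl$k_selection$silhouette$mean_silhouette,
                             12)),
               paste0("k", cl$k_selection$silhouette$k))
    },
    null_test = list(
      observed_mean_silhouette =
        round(report$null_test$observed_mean_silhouette, 12),
      p_value = report$null_test$p_value,
      M = report$null_test$M, seed = report$null_test$seed),
    stability = list(
      mean_jaccard = as.list(round(report$stability$summary$mean_jaccard,
                                   12)),
      stable = as.list(report$stability$summary$stable),
      B = report$stability$B, seed = report$stability$seed),
    recovery_ari = if (!is.null(report$recovery_ari)) {
      round(report$recovery_ari, 12)
    })
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  readr::write_tsv(report$lmm, file.path(dir, "lmm.tsv"))
  readr::write_tsv(cl$labels, file.path(dir, "cluster_labels.tsv"))
  if (!is.null(report$profile)) {
    readr::write_tsv(tibble::as_tibble(report$profile),
                     file.path(dir, "subgroup_profile.tsv"))
  }
  readr::write_tsv(report$standardization,
                   file.path(dir, "standardization.tsv"))
  export_newick(cl$merge, file.path(dir, "dendrogram.nwk"))
  readr::write_tsv(
    tibble::tibble(stage = names(report$timings),
                   seconds = round(unlist(report$timings), 3)),
    file.path(dir, "timings.tsv"))
  invisible(dir)
}
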