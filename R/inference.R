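#' Jaccard similarity of two sets
#'
#' `|a intersect b| / |a union b|`, defined as 0 when both sets are
#' empty.
#'
#' @param a,b Vectors interpreted as sets of identifiers.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' jaccard_index(1:3, 2:4)  # 0.5
jaccard_index <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

# the clustering pipeline applied identically to observed and simulated
# or resampled data: scaling (if configured), distances, agglomeration,
# cut. k can be re-selected by silhouette when reselect_k = TRUE.
pipeline_labels <- function(X_raw, scale_features, linkage, k,
                            ward_dialect = "D2", reselect_k = FALSE,
                            k_range = 2:8) {
  fmx <- feature_matrix(X_raw, scale_features = scale_features)
  d <- dist(fmx$X)
  mh <- agglomerate(d, linkage, ward_dialect = ward_dialect)
  if (reselect_k) k <- select_k(d, mh, k_range)$k
  list(labels = cut_merge_tree(mh, k), d = d, k = k)
}

#' Single-Gaussian simulation test of cluster existence
#'
#' Tests whether the observed clustering structure exceeds what a single
#' multivariate Gaussian would produce. A Gaussian is fitted to the raw
#' feature matrix (sample mean and covariance); `M` synthetic datasets
#' of the same size are drawn and pushed through the identical
#' clustering pipeline (same scaling, linkage and fixed `k`); the null
#' statistic is the mean silhouette width. The Monte-Carlo p-value uses
#' the add-one correction, `p = (1 + #(null >= observed)) / (M + 1)`,
#' so it is always strictly positive.
#'
#' @param fm A [feature_matrix()] object.
#' @param k Number of clusters of the observed solution.
#' @param linkage Linkage of the observed solution.
#' @param M Number of null simulations (>= 19).
#' @param seed Integer seed for the simulation stream.
#' @param null_cov `"full"` (sample covariance, default) or
#'   `"diagonal"` (independent features).
#' @param ridge Non-negative ridge added to the covariance diagonal if
#'   it is numerically singular.
#' @param reselect_k Re-select `k` by silhouette inside each simulated
#'   dataset instead of holding it fixed.
#' @param ward_dialect,k_range Passed through to the pipeline.
#'
#' @return An object of class `"null_test"`: list with
#'   `observed_mean_silhouette`, `null_silhouettes` (length `M`),
#'   `p_value`, `M`, `k`, `linkage`, `seed`.
#' @export
gaussian_null_test <- function(fm, k, linkage = "ward", M = 999,
                               seed = 1L, null_cov = c("full", "diagonal"),
                               ridge = 0, reselect_k = FALSE,
                               ward_dialect = "D2", k_range = 2:8) {
  stopifnot(inherits(fm, "feature_matrix"))
  null_cov <- match.arg(null_cov)
  n <- nrow(fm$X_raw)
  if (n < 3 * k) stop("need n >= 3k observations", call. = FALSE)
  if (M < 19) stop("`M` must be at least 19", call. = FALSE)

  obs <- pipeline_labels(fm$X_raw, fm$scaled, linkage, k,
                         ward_dialect, reselect_k, k_range)
  observed <- silhouette_widths(obs$d, obs$labels)$mean

  mu <- colMeans(fm$X_raw)
  S <- if (null_cov == "full") cov(fm$X_raw) else diag(diag(cov(fm$X_raw)),
                                                       ncol(fm$X_raw))
  S <- S + diag(ridge, ncol(S))
  if (rcond_psd(S) < 1e-12) {
    stop("covariance of the features is numerically singular; ",
         "consider the `ridge` option", call. = FALSE)
  }
  nulls <- with_seed(seed, {
    vapply(seq_len(M), function(m) {
      Xs <- MASS::mvrnorm(n, mu, S)
      sim <- pipeline_labels(Xs, fm$scaled, linkage, k,
                             ward_dialect, reselect_k, k_range)
      silhouette_widths(sim$d, sim$labels)$mean
    }, numeric(1))
  })
  p <- (1 + sum(nulls >= observed)) / (M + 1)
  structure(list(observed_mean_silhouette = observed,
                 null_silhouettes = nulls, p_value = p, M = M,
                 k = k, linkage = linkage, seed = seed,
                 null_cov = null_cov, reselect_k = reselect_k),
            class = "null_test")
}

rcond_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' @export
print.null_test <- function(x, ...) {
  cat("<null_test> observed mean silhouette = ",
      format(x$observed_mean_silhouette, digits = 4),
      ", p = ", format(x$p_value, digits = 4),
      " (M = ", x$M, " single-Gaussian simulations)\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.null_test <- function(x, ...) {
  tibble::tibble(observed_mean_silhouette = x$observed_mean_silhouette,
                 p_value = x$p_value, M = x$M, k = x$k,
                 linkage = x$linkage, seed = x$seed)
}

#' @exportS3Method ggplot2::autoplot
autoplot.null_test <- function(object, ...) {
  df <- tibble::tibble(null = object$null_silhouettes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed_mean_silhouette,
                        colour = "red", linewidth = 1) +
    ggplot2::labs(x = "mean silhouette under single-Gaussian null",
                  title = sprintf("Cluster existence test: p = %.4g",
                                  object$p_value)) +
    ggplot2::theme_minimal()
}

#' Bootstrap Jaccard stability of a cluster solution
#'
#' Draws `B` bootstrap resamples of the participants, re-runs the
#' identical clustering pipeline on each, and scores every original
#' cluster by its Jaccard similarity with the most similar bootstrap
#' cluster, computed on the set of distinct original indices present in
#' the resample (the clusterboot convention). A cluster with mean
#' Jaccard above 0.7 is flagged stable.
#'
#' @param fm A [feature_matrix()] object.
#' @param k,linkage The observed solution's settings.
#' @param B Number of bootstrap resamples (>= 20).
#' @param seed Integer seed for the resampling stream.
#' @param stable_threshold Mean Jaccard above which a cluster counts as
#'   stable.
#' @param ward_dialect Passed through to the pipeline.
#' @param resample_hook Test hook: `function(b)` returning the indices
#'   of resample `b` (bypasses random sampling).
#'
#' @return An object of class `"stability"`: list with `summary`
#'   (tibble: cluster, mean_jaccard, stable), `jaccard` (B x k matrix),
#'   `B`, `seed`, `redraws` (resamples redrawn for having fewer than k
#'   distinct points).
#' @export
bootstrap_stability <- function(fm, k, linkage = "ward", B = 100,
                                seed = 1L, stable_threshold = 0.7,
                                ward_dialect = "D2",
                                resample_hook = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  n <- nrow(fm$X_raw)
  if (n < 3 * k) stop("need n >= 3k observations", call. = FALSE)
  if (B < 20) stop("`B` must be at least 20", call. = FALSE)

  orig <- pipeline_labels(fm$X_raw, fm$scaled, linkage, k, ward_dialect)
  orig_sets <- split(seq_len(n), orig$labels)

  redraws <- 0L
  J <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      repeat {
        idx <- if (is.null(resample_hook)) {
          sample.int(n, n, replace = TRUE)
        } else {
          resample_hook(b)
        }
        if (length(unique(idx)) >= k) break
        if (!is.null(resample_hook)) {
          stop("resample hook returned fewer than k distinct points",
               call. = FALSE)
        }
        redraws <<- redraws + 1L
      }
      boot <- pipeline_labels(fm$X_raw[idx, , drop = FALSE], fm$scaled,
                              linkage, k, ward_dialect)
      present <- unique(idx)
      boot_sets <- lapply(split(idx, boot$labels), unique)
      vapply(orig_sets, function(A) {
        A_present <- intersect(A, present)
        max(vapply(boot_sets, function(Bset) {
          jaccard_index(A_present, Bset)
        }, numeric(1)))
      }, numeric(1))
    }, numeric(length(orig_sets))))
  })
  mean_j <- colMeans(J)
  structure(list(
    summary = tibble::tibble(cluster = as.integer(names(orig_sets)),
                             mean_jaccard = unname(mean_j),
                             stable = unname(mean_j > stable_threshold)),
    jaccard = J, B = B, seed = seed,
    stable_threshold = stable_threshold, redraws = redraws,
    k = k, linkage = linkage
  ), class = "stability")
}

#' @export
print.stability <- function(x, ...) {
  cat("<stability> B = ", x$B, " bootstrap resamples, threshold > ",
      x$stable_threshold, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.stability <- function(x, ...) x$summary

#' @exportS3Method ggplot2::autoplot
autoplot.stability <- function(object, ...) {
  df <- tibble::as_tibble(object$jaccard, .name_repair = "minimal")
  names(df) <- as.character(object$summary$cluster)
  df <- tidyr::pivot_longer(df, dplyr::everything(),
                            names_to = "cluster", values_to = "jaccard")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$jaccard)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::geom_hline(yintercept = object$stable_threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(y = "bootstrap Jaccard similarity",
                  title = "Cluster stability under bootstrap resampling") +
    ggplot2::theme_minimal()
}
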