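#' Cluster participants on the inflammatory-cognitive features
#'
#' Convenience orchestration of the clustering stage: Euclidean distance
#' matrix, linkage selection by agglomerative coefficient (unless
#' overridden), silhouette-based selection of the number of clusters
#' (unless `k` is fixed) and tree cutting. When the features are the
#' usual (log10 CRP, cognitive composite) pair, labels are
#' canonicalized so that cluster 1 is the lower-inflammation /
#' higher-cognition subgroup and cluster 2 the higher-inflammation /
#' lower-cognition one, matching the conventional presentation.
#'
#' @param fm A [feature_matrix()] / [build_feature_matrix()] object.
#' @param linkage Linkage override; `NULL` selects by agglomerative
#'   coefficient.
#' @param k Fixed number of clusters; `NULL` selects by silhouette.
#' @param k_range Candidate `k` values when selecting.
#' @param ward_dialect Passed to [agglomerate()].
#' @param canonical Reorder cluster labels by increasing mean of the
#'   first feature column (CRP)?
#'
#' @return An object of class `"cluster_solution"`: list with `labels`
#'   (tibble: participant_id, cluster), `k`, `linkage`,
#'   `mean_silhouette`, `silhouette` (per-point tibble),
#'   `agglomerative_coefficient`, `ac_table`, `k_selection`, `merge`
#'   (the [agglomerate()] object) and `features`.
#' @export
cluster_features <- function(fm, linkage = NULL, k = NULL, k_range = 2:8,
                             ward_dialect = "D2", canonical = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  d <- dist(fm$X)
  ac_table <- NULL
  if (is.null(linkage)) {
    sel <- select_linkage(d, ward_dialect = ward_dialect)
    linkage <- sel$linkage
    ac_table <- sel$ac
  }
  mh <- agglomerate(d, linkage, ward_dialect = ward_dialect)
  ksel <- NULL
  if (is.null(k)) {
    ksel <- select_k(d, mh, k_range)
    k <- ksel$k
  }
  labels <- cut_merge_tree(mh, k)
  if (canonical) labels <- canonical_labels(labels, fm$X_raw[, 1])
  sil <- silhouette_widths(d, labels)
  structure(list(
    labels = tibble::tibble(participant_id = fm$participant_ids,
                            cluster = labels),
    k = k, linkage = linkage, ward_dialect = ward_dialect,
    mean_silhouette = sil$mean, silhouette = sil$widths,
    agglomerative_coefficient = agglom_coefficient(mh),
    ac_table = ac_table, k_selection = ksel,
    merge = mh, features = fm
  ), class = "cluster_solution")
}

# relabel clusters 1..k by increasing cluster mean of `by`
canonical_labels <- function(labels, by) {
  mu <- tapply(by, labels, mean)
  rank_of <- rank(mu, ties.method = "first")
  as.integer(rank_of[as.character(labels)])
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> k = ", x$k, " (", x$linkage, " linkage), ",
      "mean silhouette = ", format(x$mean_silhouette, digits = 3),
      ", AC = ", format(x$agglomerative_coefficient, digits = 3), "\n",
      sep = "")
  print(dplyr::count(x$labels, .data$cluster))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cluster_solution <- function(x, ...) {
  dplyr::bind_cols(x$labels,
                   tibble::as_tibble(x$features$X_raw),
                   silhouette = x$silhouette$silhouette)
}

#' @exportS3Method generics::glance
glance.cluster_solution <- function(x, ...) {
  tibble::tibble(k = x$k, linkage = x$linkage,
                 mean_silhouette = x$mean_silhouette,
                 agglomerative_coefficient = x$agglomerative_coefficient,
                 n = nrow(x$labels))
}

#' @exportS3Method ggplot2::autoplot
autoplot.cluster_solution <- function(object, ...) {
  df <- tidy(object)
  nm <- colnames(object$features$X_raw)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[nm[1]]], y = .data[[nm[2]]],
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = "cluster",
                  title = "Inflammatory-cognitive cluster solution") +
    ggplot2::theme_minimal()
}
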