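#' Agglomerative hierarchical clustering via Lance-Williams recurrences
#'
#' From-scratch agglomeration of a Euclidean (or other) dissimilarity
#' matrix under one of four linkages. At each step the pair of clusters
#' with the smallest inter-cluster dissimilarity is merged and the
#' dissimilarities to the remaining clusters updated by the
#' Lance-Williams recurrence. Ward linkage follows the `"D2"` dialect by
#' default: the recurrence runs on squared distances and merge heights
#' are reported back on the original distance scale; the `"D"` dialect
#' (recurrence on raw distances) is available for comparison. Ties at
#' the minimum are broken deterministically by the lexicographically
#' smallest pair of cluster slots.
#'
#' @param d A `dist` object or square dissimilarity matrix.
#' @param linkage One of `"ward"`, `"average"`, `"complete"`, `"single"`.
#' @param ward_dialect `"D2"` (default) or `"D"`; ignored unless
#'   `linkage = "ward"`.
#'
#' @return An object of class `"agglomeration"`: list with `merge`
#'   (the standard (n-1) x 2 merge table, negative entries = original
#'   observations), `height`, `order` (leaf order for dendrograms),
#'   `labels`, `linkage`, `ward_dialect`, `n` and
#'   `first_merge_height` (per observation, used by
#'   [agglom_coefficient()]).
#' @export
#' @examples
#' mh <- agglomerate(dist(c(0, 2, 9)), "average")
#' mh$height  # 2 then 8 = mean(9, 7)
agglomerate <- function(d, linkage = c("ward", "average", "complete",
                                       "single"),
                        ward_dialect = c("D2", "D")) {
  linkage <- match.arg(linkage)
  ward_dialect <- match.arg(ward_dialect)
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 2) stop("need at least two observations", call. = FALSE)
  if (any(D < 0)) stop("dissimilarities must be non-negative", call. = FALSE)
  labels <- rownames(D)
  code <- match(linkage, c("single", "complete", "average", "ward")) - 1L
  squared <- linkage == "ward" && ward_dialect == "D2"
  res <- agglomerate_cpp(if (squared) D^2 else D, code)
  height <- as.numeric(res$height)
  if (squared) height <- sqrt(pmax(height, 0))
  merge <- res$merge
  fm <- first_merge_heights(merge, height)
  structure(list(merge = merge, height = height,
                 order = leaf_order(merge), labels = labels,
                 linkage = linkage, ward_dialect = ward_dialect,
                 n = n, first_merge_height = fm),
            class = "agglomeration")
}

# height at which each original observation is first absorbed
first_merge_heights <- function(merge, height) {
  n <- nrow(merge) + 1L
  row1 <- match(-(1:n), merge[, 1])
  row2 <- match(-(1:n), merge[, 2])
  height[pmin(row1, row2, na.rm = TRUE)]
}

# dendrogram leaf order by depth-first traversal of the merge table
leaf_order <- function(merge) {
  st <- nrow(merge)
  out <- integer(0)
  while (length(st)) {
    id <- st[length(st)]
    st <- st[-length(st)]
    if (id < 0) out <- c(out, -id) else st <- c(st, merge[id, 2], merge[id, 1])
  }
  out
}

#' @export
print.agglomeration <- function(x, ...) {
  cat("<agglomeration> n = ", x$n, ", linkage = ", x$linkage,
      if (x$linkage == "ward") paste0(" (", x$ward_dialect, ")"),
      ", final height = ", format(x$height[x$n - 1], digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' @export
as.hclust.agglomeration <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$linkage,
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' Agglomerative coefficient
#'
#' The Kaufman-Rousseeuw agglomerative coefficient: the mean over
#' observations of `1 - m(i)/h_final`, where `m(i)` is the height at
#' which observation i is first merged and `h_final` the height of the
#' final merge. Values near 1 indicate strong clustering structure.
#' When all points are identical (`h_final = 0`) the coefficient is
#' defined as 0, with a warning.
#'
#' @param mh An [agglomerate()] result.
#' @return A number in `[0, 1]`.
#' @export
agglom_coefficient <- function(mh) {
  stopifnot(inherits(mh, "agglomeration"))
  h_final <- mh$height[mh$n - 1]
  if (h_final == 0) {
    warning("all observations identical; agglomerative coefficient set to 0")
    return(0)
  }
  mean(1 - mh$first_merge_height / h_final)
}

#' Cut an agglomeration into k clusters
#'
#' Undoes the last `k - 1` merges and labels the resulting clusters
#' `1..k` in order of first occurrence along the observation sequence.
#'
#' @param mh An [agglomerate()] result.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster labels.
#' @export
cut_merge_tree <- function(mh, k) {
  stopifnot(inherits(mh, "agglomeration"))
  n <- mh$n
  if (k < 1 || k > n || k != round(k)) {
    stop("`k` must be an integer in [1, ", n, "]", call. = FALSE)
  }
  comp <- -(seq_len(n))
  members <- vector("list", n - 1L)
  n_merge <- n - k
  if (n_merge >= 1) {
    for (m in seq_len(n_merge)) {
      a <- mh$merge[m, 1]
      b <- mh$merge[m, 2]
      ma <- if (a < 0) -a else members[[a]]
      mb <- if (b < 0) -b else members[[b]]
      members[[m]] <- c(ma, mb)
      comp[members[[m]]] <- m
    }
  }
  match(comp, unique(comp))
}

#' Silhouette widths of a partition
#'
#' For each observation, `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where
#' `a(i)` is the mean dissimilarity to its own cluster (excluding
#' itself) and `b(i)` the smallest mean dissimilarity to any other
#' cluster. Members of singleton clusters get `s(i) = 0` by convention.
#'
#' @param d A `dist` object or square dissimilarity matrix.
#' @param labels Cluster labels (at least two clusters).
#' @return A list with `widths` (tibble: observation, cluster,
#'   silhouette) and `mean`.
#' @export
silhouette_widths <- function(d, labels) {
  D <- as.matrix(d)
  n <- nrow(D)
  labels <- as.integer(factor(labels))
  if (length(labels) != n) stop("labels length must match d", call. = FALSE)
  k <- max(labels)
  if (k < 2) stop("silhouette requires at least two clusters", call. = FALSE)
  sizes <- tabulate(labels, k)
  # M[i, c] = sum of dissimilarities from i to members of cluster c
  M <- t(rowsum(D, labels, reorder = TRUE))
  own <- cbind(seq_len(n), labels)
  a <- M[own] / pmax(sizes[labels] - 1L, 1L)
  Mb <- sweep(M, 2, sizes, "/")
  Mb[own] <- Inf
  b <- apply(Mb, 1, min)
  s <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
  s[sizes[labels] == 1L] <- 0
  list(widths = tibble::tibble(observation = seq_len(n), cluster = labels,
                               silhouette = s),
       mean = mean(s))
}

#' Select the linkage by agglomerative coefficient
#'
#' Runs all four candidate linkages (average, single, complete, Ward)
#' and returns the one with the highest agglomerative coefficient. Exact
#' ties are resolved by the documented priority
#' ward > average > complete > single.
#'
#' @param d A `dist` object or square dissimilarity matrix (n >= 3).
#' @param ward_dialect Passed to [agglomerate()].
#' @return A list with `linkage` (the winner) and `ac` (tibble of the
#'   four coefficients).
#' @export
select_linkage <- function(d, ward_dialect = "D2") {
  priority <- c("ward", "average", "complete", "single")
  ac <- vapply(priority, function(l) {
    agglom_coefficient(agglomerate(d, l, ward_dialect = ward_dialect))
  }, numeric(1))
  best <- priority[which.max(ac)]  # which.max takes the first = priority order
  list(linkage = best,
       ac = tibble::tibble(linkage = priority, ac = unname(ac)))
}

#' Select the number of clusters by average silhouette
#'
#' Cuts the tree at each candidate `k` and picks the `k` maximizing the
#' mean silhouette width; ties go to the smallest `k`.
#'
#' @param d The dissimilarity used to build `mh`.
#' @param mh An [agglomerate()] result.
#' @param k_range Candidate numbers of clusters (subset of `2..n-1`).
#' @return An object of class `"k_selection"`: list with `k` (the
#'   chosen value) and `silhouette` (tibble of mean silhouette per k).
#' @export
select_k <- function(d, mh, k_range = 2:8) {
  stopifnot(inherits(mh, "agglomeration"))
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) stop("empty `k_range`", call. = FALSE)
  if (any(k_range < 2) || any(k_range > mh$n - 1)) {
    stop("`k_range` must lie within [2, n-1]", call. = FALSE)
  }
  sil <- vapply(k_range, function(k) {
    silhouette_widths(d, cut_merge_tree(mh, k))$mean
  }, numeric(1))
  structure(list(k = k_range[which.max(sil)],
                 silhouette = tibble::tibble(k = k_range,
                                             mean_silhouette = sil)),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("<k_selection> optimal k =", x$k, "\n")
  print(x$silhouette)
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.k_selection <- function(object, ...) {
  ggplot2::ggplot(object$silhouette,
                  ggplot2::aes(x = .data$k, y = .data$mean_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = dplyr::filter(object$silhouette,
                                             .data$k == object$k),
                        colour = "red", size = 3) +
    ggplot2::labs(x = "number of clusters k",
                  y = "mean silhouette width",
                  title = "Silhouette-based selection of k") +
    ggplot2::theme_minimal()
}

#' Export an agglomeration as a Newick tree
#'
#' Converts the merge history to a `phylo` tree (via the standard
#' `hclust` representation) and writes Newick with branch lengths
#' derived from merge heights, for cross-tool comparison.
#'
#' @param mh An [agglomerate()] result.
#' @param file Path to write; if `NULL`, the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
export_newick <- function(mh, file = NULL) {
  hc <- stats::as.hclust(mh)
  if (is.null(hc$labels)) hc$labels <- as.character(seq_len(mh$n))
  phy <- ape::as.phylo(hc)
  if (is.null(file)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = file)
    invisible(ape::write.tree(phy))
  }
}
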