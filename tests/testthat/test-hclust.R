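test_that("worked 1-D examples reproduce the hand computations", {
  d <- dist(c(0, 2, 9))
  expect_equal(as.vector(d), c(2, 9, 7))
  expect_equal(agglomerate(d, "average")$height, c(2, 8))
  expect_equal(agglomerate(d, "single")$height, c(2, 7))
  expect_equal(agglomerate(d, "complete")$height, c(2, 9))
  # n = 2: single merge at the pairwise distance
  mh2 <- agglomerate(dist(c(0, 5)), "ward")
  expect_equal(mh2$height, 5)
  expect_equal(agglom_coefficient(mh2), 0)
  # cut of {0, 2, 9} at k = 2 separates {1,2} from {3}
  labs <- cut_merge_tree(agglomerate(d, "average"), 2)
  expect_true(same_partition(partition_sets(labs),
                             list(c(1, 2), 3)))
})

test_that("agglomerative coefficient follows the first-merge definition", {
  mh <- agglomerate(dist(c(0, 1, 10)), "average")
  expect_equal(mh$first_merge_height, c(1, 1, 9.5))
  expect_equal(agglom_coefficient(mh), (2 * (1 - 1 / 9.5) + 0) / 3,
               tolerance = 1e-12)
  # tight clusters far apart push AC towards 1
  tight <- c(0, 1e-4, 2e-4, 100, 100.0001, 100.0002)
  expect_gt(agglom_coefficient(agglomerate(dist(tight), "average")),
            0.999)
  # identical points: defined as 0 with a warning
  expect_warning(
    ac0 <- agglom_coefficient(agglomerate(dist(c(1, 1, 1)), "single")),
    "identical")
  expect_equal(ac0, 0)
})

test_that("cut_tree obeys its boundary cases and labelling convention", {
  set.seed(42)
  d <- dist(matrix(rnorm(24), ncol = 2))
  mh <- agglomerate(d, "ward")
  expect_equal(cut_merge_tree(mh, 1), rep(1L, 12))
  expect_equal(cut_merge_tree(mh, 12), 1:12)
  labs <- cut_merge_tree(mh, 3)
  # labels numbered by first occurrence
  expect_equal(unique(labs), 1:3)
  expect_error(cut_merge_tree(mh, 0), "\\[1, 12\\]")
  expect_error(cut_merge_tree(mh, 13), "\\[1, 12\\]")
})

test_that("silhouette matches the hand computation and conventions", {
  d <- dist(c(0, 1, 10, 11))
  sw <- silhouette_widths(d, c(1, 1, 2, 2))
  expect_equal(sw$widths$silhouette[1], (10.5 - 1) / 10.5,
               tolerance = 1e-12)
  expect_equal(sw$widths$silhouette[2], (9.5 - 1) / 9.5,
               tolerance = 1e-12)
  expect_equal(sw$mean, mean(c((10.5 - 1) / 10.5, (9.5 - 1) / 9.5,
                               (10.5 - 1) / 10.5, (9.5 - 1) / 9.5)),
               tolerance = 1e-12)
  # singleton convention
  sw1 <- silhouette_widths(d, c(1, 2, 2, 2))
  expect_equal(sw1$widths$silhouette[1], 0)
  # identical overlapping sets split arbitrarily: mean <= 0
  dd <- dist(rep(c(0, 1, 2), 2))
  sw2 <- silhouette_widths(dd, c(1, 1, 1, 2, 2, 2))
  expect_lte(sw2$mean, 0)
  expect_error(silhouette_widths(d, rep(1, 4)), "two clusters")
})

test_that("silhouette equals a naive double-loop implementation", {
  naive_sil <- function(D, labels) {
    n <- nrow(D)
    vapply(seq_len(n), function(i) {
      own <- labels == labels[i]
      if (sum(own) == 1) return(0)
      a <- mean(D[i, own & seq_len(n) != i])
      b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
        mean(D[i, labels == cl])
      }, numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1))
  }
  set.seed(7)
  for (rep in 1:5) {
    X <- matrix(rnorm(40), ncol = 2)
    D <- as.matrix(dist(X))
    labels <- sample(1:3, 20, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_lt(max(abs(silhouette_widths(D, labels)$widths$silhouette -
                        naive_sil(D, labels))), 1e-12)
  }
})

test_that("linkage selection reports four coefficients with the tie rule", {
  blobs <- make_blobs(n_per = 20, sep = 10, seed = 3)
  sel <- select_linkage(dist(blobs$X))
  expect_equal(nrow(sel$ac), 4)
  expect_setequal(sel$ac$linkage,
                  c("ward", "average", "complete", "single"))
  # the winner really is the arg-max of the reported coefficients
  expect_equal(sel$linkage,
               sel$ac$linkage[which.max(sel$ac$ac)])
  # equidistant points: all linkages tie, priority picks ward
  deq <- matrix(1, 4, 4) - diag(4)
  sel_tie <- select_linkage(stats::as.dist(deq))
  expect_equal(length(unique(round(sel_tie$ac$ac, 12))), 1)
  expect_equal(sel_tie$linkage, "ward")
})

test_that("silhouette-based k selection recovers constructed structure", {
  blobs <- make_blobs(n_per = 50, sep = 10, seed = 5)
  d <- dist(blobs$X)
  mh <- agglomerate(d, "ward")
  ks <- select_k(d, mh, 2:8)
  expect_equal(ks$k, 2)
  # three equidistant tight triplets
  centers <- rbind(c(0, 0), c(100, 0), c(50, 100 * sqrt(3) / 2))
  X3 <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(c(0, 0.3, -0.3, 0, 0.3, -0.3), ncol = 2), 2,
          centers[i, ], "+")
  }))
  d3 <- dist(X3)
  ks3 <- select_k(d3, agglomerate(d3, "ward"), 2:5)
  expect_equal(ks3$k, 3)
  # singleton range is returned as-is with its silhouette
  ks1 <- select_k(d, mh, 2)
  expect_equal(ks1$k, 2)
  expect_equal(nrow(ks1$silhouette), 1)
  expect_error(select_k(d, mh, integer(0)), "empty")
})

test_that("merge heights are non-decreasing for all four linkages", {
  set.seed(11)
  for (linkage in c("single", "complete", "average", "ward")) {
    for (rep in 1:5) {
      X <- matrix(rnorm(60), ncol = 2)
      mh <- agglomerate(dist(X), linkage)
      expect_true(all(diff(mh$height) >= -1e-10), info = linkage)
    }
  }
})

test_that("agglomeration matches stats::hclust on random data", {
  set.seed(13)
  for (rep in 1:3) {
    X <- matrix(rnorm(80), ncol = 2)
    d <- dist(X)
    for (linkage in c("single", "complete", "average", "ward")) {
      mh <- agglomerate(d, linkage)
      hc <- stats::hclust(d, method = if (linkage == "ward") "ward.D2"
                                      else linkage)
      expect_lt(max(abs(sort(mh$height) - sort(hc$height))), 1e-8)
      for (k in c(2, 4)) {
        expect_true(same_partition(
          partition_sets(cut_merge_tree(mh, k)),
          partition_sets(stats::cutree(hc, k))), info = linkage)
      }
    }
  }
})

test_that("agglomerative coefficient matches cluster::agnes", {
  skip_if_not_installed("cluster")
  set.seed(17)
  X <- matrix(rnorm(60), ncol = 2)
  d <- dist(X)
  for (linkage in c("single", "complete", "average", "ward")) {
    ag <- cluster::agnes(d, method = linkage)
    expect_equal(agglom_coefficient(agglomerate(d, linkage)), ag$ac,
                 tolerance = 1e-9, info = linkage)
  }
})

test_that("labels are permutation invariant and silhouette exactly so", {
  set.seed(19)
  X <- matrix(rnorm(60), ncol = 2)
  perm <- sample(30)
  d <- dist(X)
  dp <- dist(X[perm, ])
  mh <- agglomerate(d, "ward")
  mhp <- agglomerate(dp, "ward")
  labs <- cut_merge_tree(mh, 3)
  labsp <- cut_merge_tree(mhp, 3)
  expect_true(same_partition(partition_sets(labs),
                             lapply(partition_sets(labsp),
                                    function(s) sort(perm[s]))))
  expect_equal(silhouette_widths(d, labs)$mean,
               silhouette_widths(dp, labsp)$mean, tolerance = 1e-12)
})

test_that("the dendrogram round-trips through hclust and Newick", {
  set.seed(23)
  X <- matrix(rnorm(30), ncol = 2)
  mh <- agglomerate(dist(X), "ward")
  hc <- stats::as.hclust(mh)
  expect_s3_class(hc, "hclust")
  expect_equal(sort(hc$order), 1:15)
  nwk <- export_newick(mh)
  phy <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(phy), 15)
})
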