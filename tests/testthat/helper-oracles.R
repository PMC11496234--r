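# Brute-force agglomeration oracle: recomputes every inter-cluster
# dissimilarity from the member-pair distances at every step, with the
# same lexicographic tie rule as the implementation. Ward uses the
# centroid identity on squared distances (D2 dialect):
#   delta(A, B) = 2|A||B|/(|A|+|B|) * ||c_A - c_B||^2
# with the centroid gap recovered from the distance matrix alone.
oracle_dissim <- function(D2, D, A, B, linkage) {
  cross <- D[A, B, drop = FALSE]
  switch(linkage,
    single = min(cross),
    complete = max(cross),
    average = mean(cross),
    ward = {
      nA <- length(A); nB <- length(B)
      within <- function(S) {
        if (length(S) < 2) return(0)
        sum(D2[S, S]) / 2  # ordered pairs double-count halved
      }
      gap2 <- sum(D2[A, B]) / (nA * nB) - within(A) / nA^2 -
        within(B) / nB^2
      sqrt(2 * nA * nB / (nA + nB) * gap2)
    })
}

oracle_agglomerate <- function(D, linkage) {
  D <- as.matrix(D)
  D2 <- D^2
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  for (m in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- oracle_dissim(D2, D, clusters[[i]], clusters[[j]], linkage)
        if (dd < best) { best <- dd; bi <- i; bj <- j }
      }
    }
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
    heights[m] <- best
    partitions[[m]] <- lapply(clusters, sort)
  }
  list(height = heights, partitions = partitions)
}

# canonical representation of a labelling as sorted member sets
partition_sets <- function(labels) {
  unname(lapply(split(seq_along(labels), labels), sort))
}

same_partition <- function(a, b) {
  setequal(lapply(a, paste, collapse = ","),
           lapply(b, paste, collapse = ","))
}

# two well-separated Gaussian blobs in 2-D
make_blobs <- function(n_per = 50, sep = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(
    cbind(rnorm(n_per), rnorm(n_per)),
    cbind(rnorm(n_per) + sep, rnorm(n_per) + sep))
  list(X = X, truth = rep(1:2, each = n_per))
}

# minimal deterministic two-visit cohort for preprocessing tests:
# 4 HC + 2 SZ participants, domain scores laid out by hand
make_tiny_cohort <- function() {
  domains <- cognitive_domains()
  grid <- expand.grid(participant_id = sprintf("T%02d", 1:6),
                      timepoint = 0:1, stringsAsFactors = FALSE)
  df <- tibble::as_tibble(grid[order(grid$participant_id), ])
  df$diagnosis <- rep(c("HC", "HC", "HC", "HC", "SZ", "SZ"), each = 2)
  df$visit_day <- rep(c(0, 400), 6)
  df$sex <- rep(c("F", "M"), 6)
  df$age <- 30
  df$bmi <- 25
  df$crp <- rep(c(1, 2, 3, 4, 2.5, 3.5), each = 2)
  for (d in domains) {
    # HC baseline values 10, 20, 30, 40 -> mean 25, sd = sqrt(500/3)
    df[[d]] <- rep(c(10, 20, 30, 40, 25, 35), each = 2)
  }
  df
}
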