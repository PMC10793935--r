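# Independent brute-force reference for the pair-restricted kNN overlap
# score: full pairwise distances per bin pair, stable sort per query point.
# Deliberately naive and separate from the package's compiled path.

naive_overlap_knn <- function(points_u, points_v, k) {
  pts <- rbind(points_u, points_v)
  n_u <- nrow(points_u)
  total <- 0L
  for (i in seq_len(n_u)) {
    d2 <- colSums((t(pts) - pts[i, ])^2)
    d2[i] <- Inf
    nn <- order(d2)[seq_len(k)]  # stable: ties -> ascending index
    total <- total + sum(nn > n_u)
  }
  total / (n_u * k)
}

naive_overlap_matrix <- function(cloud, labels, k) {
  groups <- split(seq_len(nrow(cloud)), labels)
  n <- length(groups)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      m[i, j] <- naive_overlap_knn(cloud[groups[[i]], , drop = FALSE],
                                   cloud[groups[[j]], , drop = FALSE], k)
    }
  }
  m
}

naive_si <- function(m) {
  n <- nrow(m)
  1 - (2 / (n^2 - n)) * sum(m)
}

# Well-separated Gaussian blobs: group centers far apart relative to spread.
make_blobs <- function(n_per, centers, sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(g) {
      sweep(matrix(stats::rnorm(n_per * ncol(centers), sd = sd),
                   ncol = ncol(centers)), 2, centers[g, ], `+`)
    }))
    list(points = pts, labels = rep(seq_len(nrow(centers)), each = n_per))
  })
}
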