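test_that("hand-enumerated 1D knn overlap scores are exact", {
  # both points of U have their nearest neighbor inside U
  expect_identical(overlap_score_knn(matrix(c(0, 1)), matrix(c(2.5, 3.5)),
                                     k = 1), 0)
  # each point of U is nearer a V point (tie at u = 2 resolved within V)
  expect_identical(overlap_score_knn(matrix(c(0, 2)), matrix(c(1, 3)),
                                     k = 1), 1)
})

test_that("hand-enumerated 1D radius overlap scores are exact", {
  u <- matrix(c(0, 1)); v <- matrix(c(5, 6))
  # r = 2: each beta holds only the same-group partner
  expect_identical(overlap_score_radius(u, v, r = 2), 0)
  # r = 10: each beta holds all 3 other points, 2 of them in V
  expect_equal(overlap_score_radius(u, v, r = 10), 2 / 3)
  # r below every pairwise distance: all neighborhoods empty, loud warning
  expect_warning(s <- overlap_score_radius(u, v, r = 0.5),
                 "every point has an empty radius neighborhood")
  expect_identical(s, 0)
})

test_that("radius average excludes (and warns about) isolated points only", {
  # 1D: U = {0, 1, 100}, V = {2, 3}; r = 3 isolates the point at 100
  u <- matrix(c(0, 1, 100)); v <- matrix(c(2, 3))
  expect_warning(s <- overlap_score_radius(u, v, r = 3),
                 "1 point\\(s\\) with empty radius neighborhoods")
  # u=0: beta {1,2,3} -> 2/3 in V; u=1: beta {0,2,3} -> 2/3
  expect_equal(s, 2 / 3)
})

test_that("knn overlap errors when the pair cannot supply k neighbors", {
  expect_error(overlap_score_knn(matrix(c(0, 1)), matrix(c(2, 3)), k = 4),
               "smaller k or a larger min_points")
})

test_that("fully separated groups have an exactly zero overlap matrix", {
  blobs <- make_blobs(30, rbind(c(0, 0), c(100, 0), c(0, 100)), sd = 0.5,
                      seed = 3)
  part <- assign_bins(as.character(blobs$labels))
  om <- overlap_matrix(blobs$points, part, neighbor_spec("knn", k = 10))
  expect_identical(om$m, matrix(0, 3, 3))
})

test_that("alternating 1D lattice gives full overlap in both directions", {
  cloud <- matrix(0:9, ncol = 1)
  part <- assign_bins(rep(c("u", "v"), 5))
  om <- overlap_matrix(cloud, part, neighbor_spec("knn", k = 1))
  expect_identical(om$m[1, 2], 1)
  expect_identical(om$m[2, 1], 1)
  expect_equal(structure_index(om)$si_raw, -1)
})

test_that("matrix entries follow the group relabeling", {
  withr::with_seed(11, {
    cloud <- matrix(runif(120), ncol = 2)
    lab <- sample(letters[1:3], 60, replace = TRUE)
  })
  sp <- neighbor_spec("knn", k = 4)
  om1 <- overlap_matrix(cloud, assign_bins(lab), sp)
  # rename labels so first-appearance order becomes a permutation p
  rename <- c(a = "z", b = "a", c = "m")
  om2 <- overlap_matrix(cloud, assign_bins(unname(rename[lab])), sp)
  p <- match(om2$node_labels, unname(rename[om1$node_labels]))
  expect_equal(om2$m, om1$m[p, p])
})

test_that("overlap matrix matches the brute-force oracle on random clouds", {
  withr::with_seed(99, {
    for (rep in 1:8) {
      n <- sample(60:160, 1)
      d <- sample(1:4, 1)
      k <- sample(1:8, 1)
      cloud <- matrix(rnorm(n * d), ncol = d)
      lab <- sample(3, n, replace = TRUE)
      part <- assign_bins(as.character(lab))
      om <- overlap_matrix(cloud, part, neighbor_spec("knn", k = k))
      ref <- naive_overlap_matrix(cloud, match(lab, unique(lab)), k)
      expect_equal(om$m, ref, tolerance = 1e-12)
    }
  })
})

test_that("euclidean overlap is invariant under rotation and translation", {
  withr::with_seed(21, {
    cloud <- matrix(rnorm(300), ncol = 3)
    lab <- sample(c("p", "q", "s"), 100, replace = TRUE)
    theta <- runif(1, 0, 2 * pi)
  })
  rot <- diag(3)
  rot[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)),
                          2, 2)
  moved <- sweep(cloud %*% rot, 2, c(5, -3, 11), `+`)
  sp <- neighbor_spec("knn", k = 5)
  om1 <- overlap_matrix(cloud, assign_bins(lab), sp)
  om2 <- overlap_matrix(moved, assign_bins(lab), sp)
  expect_equal(om1$m, om2$m, tolerance = 1e-9)
})

test_that("overlap entries stay in [0,1] with a zero diagonal on random runs", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      cloud <- matrix(runif(200), ncol = 2)
      f <- runif(100)
      om <- overlap_matrix(cloud, assign_bins(f, n_bins = 4),
                           neighbor_spec("knn", k = 3))
      expect_true(all(om$m >= 0 & om$m <= 1))
      expect_identical(diag(om$m), rep(0, nrow(om$m)))
    }
  })
})

test_that("knn and radius scores agree when neighborhoods coincide", {
  # 12 points equally spaced on a circle: everyone has exactly 2 points
  # within r just above the adjacent chord length, matching k = 2
  ang <- 2 * pi * (0:11) / 12
  cloud <- cbind(cos(ang), sin(ang))
  chord1 <- sqrt(sum((cloud[1, ] - cloud[2, ])^2))
  lab <- rep(c("u", "u", "v", "v"), 3)
  part <- assign_bins(lab)
  om_k <- overlap_matrix(cloud, part, neighbor_spec("knn", k = 2))
  om_r <- overlap_matrix(cloud, part,
                         neighbor_spec("radius", r = chord1 * 1.01))
  expect_equal(om_k$m, om_r$m, tolerance = 1e-12)
})

test_that("a precomputed euclidean distance matrix reproduces the metric path", {
  withr::with_seed(31, {
    cloud <- matrix(runif(150), ncol = 3)
    f <- runif(50)
  })
  part <- assign_bins(f, n_bins = 3)
  sp <- neighbor_spec("knn", k = 4)
  om1 <- overlap_matrix(cloud, part, sp)
  om2 <- overlap_matrix(cloud, part, sp,
                        dist_matrix = as.matrix(stats::dist(cloud)))
  expect_equal(om1$m, om2$m, tolerance = 1e-12)
})

test_that("geodesic distances follow the manifold, not ambient space", {
  # dense arc of 3/4 of a circle: geodesic between the arc ends must be
  # much longer than the euclidean chord
  ang <- seq(0, 1.5 * pi, length.out = 200)
  cloud <- cbind(cos(ang), sin(ang))
  gd <- geodesic_distances(cloud, graph_k = 5)
  expect_equal(dim(gd), c(200L, 200L))
  chord <- sqrt(sum((cloud[1, ] - cloud[200, ])^2))
  expect_gt(gd[1, 200], 2 * chord)
  # two far-apart clusters: the knn graph disconnects
  two <- rbind(matrix(rnorm(40, sd = 0.1), ncol = 2),
               matrix(rnorm(40, sd = 0.1) + 100, ncol = 2))
  expect_error(geodesic_distances(two, graph_k = 3), "disconnected")
})
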