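test_that("structure index evaluates the scaled mean out-degree exactly", {
  # perfectly separated distribution: zero matrix -> SI 1
  expect_identical(structure_index(matrix(0, 5, 5))$si, 1)
  # random-level overlap: all off-diagonal 0.5 -> SI 0
  for (n in c(2, 4, 7)) {
    m <- matrix(0.5, n, n); diag(m) <- 0
    expect_equal(structure_index(m)$si, 0)
    expect_equal(structure_index(m)$si_raw, 0)
  }
  # n = 2 with both entries 1: raw -1, clipped to 0
  m2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_identical(structure_index(m2)$si_raw, -1)
  expect_identical(structure_index(m2)$si, 0)
})

test_that("structure index validates its input", {
  expect_error(structure_index(matrix(0.5, 1, 1)), "at least 2")
  bad_diag <- matrix(0.5, 3, 3)
  expect_error(structure_index(bad_diag), "zero diagonal")
  m <- matrix(0, 3, 3); m[1, 2] <- 1.4
  expect_error(structure_index(m), "\\[0, 1\\]")
})

test_that("si is clipped at 0, si_raw bounded below by -1", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      n <- sample(2:8, 1)
      m <- matrix(runif(n * n), n, n); diag(m) <- 0
      res <- structure_index(m)
      expect_gte(res$si, 0)
      expect_lte(res$si, 1)
      expect_gte(res$si_raw, -1)
      expect_equal(res$si, max(res$si_raw, 0))
    }
  })
})

test_that("a feature gradient scores near 1 and a permuted feature near 0", {
  toy <- gradient_ellipsoid(1200, seed = 1)
  sp <- neighbor_spec("knn", k = 3)
  res <- compute_si(toy$points, toy$feature, spec = sp,
                    n_shuffles = 30, seed = 7)
  expect_gt(res$si, 0.9)
  expect_gt(res$si, res$null_percentile_99)
  expect_length(res$null_values, 30)
  expect_true(all(res$null_values >= 0 & res$null_values <= 1))
  expect_lt(mean(res$null_values), 0.05)

  shuf <- withr::with_seed(2, sample(toy$feature))
  res_s <- compute_si(toy$points, shuf, spec = sp)
  expect_lt(res_s$si, 0.05)
})

test_that("no shuffles means no null distribution", {
  toy <- gradient_ellipsoid(300, seed = 4)
  res <- compute_si(toy$points, toy$feature, spec = neighbor_spec("knn", k = 3))
  expect_length(res$null_values, 0)
  expect_null(res$null_percentile_99)
})

test_that("the shuffle null is reproducible from its seed", {
  toy <- gradient_ellipsoid(400, seed = 8)
  sp <- neighbor_spec("knn", k = 3)
  n1 <- shuffle_null(toy$points, toy$feature, spec = sp, n_shuffles = 5,
                     seed = 123)
  n2 <- shuffle_null(toy$points, toy$feature, spec = sp, n_shuffles = 5,
                     seed = 123)
  n3 <- shuffle_null(toy$points, toy$feature, spec = sp, n_shuffles = 5,
                     seed = 124)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
  expect_error(shuffle_null(toy$points, toy$feature, spec = sp,
                            n_shuffles = 5), "seed")
})

test_that("si is invariant to bin-group relabeling", {
  withr::with_seed(17, {
    cloud <- matrix(runif(400), ncol = 2)
    lab <- sample(c("a", "b", "c", "d"), 200, replace = TRUE)
  })
  sp <- neighbor_spec("knn", k = 4)
  si1 <- compute_si(cloud, lab, spec = sp)$si
  rename <- c(a = "d", b = "c", c = "b", d = "a")
  si2 <- compute_si(cloud, unname(rename[lab]), spec = sp)$si
  expect_equal(si1, si2)
})

test_that("translating one group away never decreases si", {
  blobs <- make_blobs(40, rbind(c(0, 0), c(1, 0)), sd = 0.5, seed = 6)
  sp <- neighbor_spec("knn", k = 5)
  lab <- as.character(blobs$labels)
  sis <- vapply(c(0, 1, 2, 4, 8), function(off) {
    pts <- blobs$points
    pts[blobs$labels == 2, 1] <- pts[blobs$labels == 2, 1] + off
    compute_si(pts, lab, spec = sp)$si
  }, numeric(1))
  expect_true(all(diff(sis) >= 0))
  expect_equal(sis[length(sis)], 1)
})

test_that("skewing the feature values barely moves the si of a gradient", {
  sp <- neighbor_spec("knn", k = 3)
  sis <- vapply(c(-2, -1, 0, 1, 2), function(sk) {
    toy <- gradient_ellipsoid(3000, skewness = sk, seed = 19)
    suppressWarnings(compute_si(toy$points, toy$feature, spec = sp)$si)
  }, numeric(1))
  expect_lt(diff(range(sis)), 0.1)
  toy0 <- gradient_ellipsoid(3000, seed = 19)
  nul <- shuffle_null(toy0$points, toy0$feature, spec = sp,
                      n_shuffles = 20, seed = 3)
  expect_true(all(sis > stats::quantile(nul, 0.99)))
})

test_that("sweep shares binning and reports one si per grid value", {
  lg <- local_and_global_patterns(800, n_tiles = 4, seed = 10)
  prof <- si_sweep(lg$points, lg$feature_local, grid = c(3, 10, 50),
                   n_bins = 8, n_shuffles = 5, seed = 2)
  expect_s3_class(prof, "sweep_profile")
  expect_equal(prof$grid, c(3, 10, 50))
  expect_true(all(prof$si >= 0 & prof$si <= 1))
  expect_true(all(prof$null_99 >= 0 & prof$null_99 <= 1))
  # local pattern: more structure at small k than large k
  expect_gt(prof$si[1], prof$si[3])
})

test_that("sweep rejects an infeasible k naming the offending value", {
  lg <- local_and_global_patterns(100, n_tiles = 2, seed = 10)
  expect_error(si_sweep(lg$points, lg$feature_global, grid = c(3, 500)),
               "k = 500 is infeasible")
})

test_that("cloud/feature length mismatch is a clear error", {
  expect_error(compute_si(matrix(runif(20), ncol = 2), runif(9)),
               "10 points but the feature has 9")
})

test_that("radius mode runs the full pipeline", {
  toy <- gradient_ellipsoid(600, seed = 23)
  res <- compute_si(toy$points, toy$feature, n_bins = 5,
                    spec = neighbor_spec("radius", r = 0.3))
  expect_gt(res$si, 0.5)
  expect_true(all(res$overlap$m >= 0 & res$overlap$m <= 1))
})

test_that("si results serialize to json with the overlap matrix as csv", {
  toy <- gradient_ellipsoid(300, seed = 5)
  res <- compute_si(toy$points, toy$feature, n_bins = 5,
                    spec = neighbor_spec("knn", k = 3),
                    n_shuffles = 3, seed = 1)
  tmp <- withr::local_tempdir()
  jpath <- file.path(tmp, "res.json")
  paths <- write_si_result(res, jpath)
  expect_true(all(file.exists(paths)))
  doc <- jsonlite::read_json(jpath)
  expect_equal(doc$si, res$si)
  expect_equal(doc$schema_version, "1.0")
  expect_equal(doc$params$k, 3)
  mm <- as.matrix(utils::read.csv(paths[2], row.names = 1, check.names = FALSE))
  expect_equal(unname(mm), res$overlap$m)
})
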