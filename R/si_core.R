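# The Structure Index: 1 minus the scaled mean weighted out-degree of the
# bin-group overlap graph. 0 = the feature is randomly distributed over the
# cloud (full overlap, every pair near 0.5); 1 = maximally separated
# bin-groups (zero overlap).

#' Structure Index from an overlap matrix
#'
#' `SI = 1 - (2 / (n^2 - n)) * sum(M)`, where `M` is the n x n overlap matrix
#' with zero diagonal. A random feature distribution gives pairwise overlaps
#' near 0.5 and hence SI near 0; perfectly separated bin-groups give SI = 1.
#' For small sets and small k, the asymmetry of k-neighborhoods can push the
#' raw value slightly below 0; the reported `si` is clipped at 0 and the
#' unclipped value kept as `si_raw`.
#'
#' @param m An `overlap_matrix` from [overlap_matrix()], or a plain square
#'   numeric matrix with zero diagonal and entries in `[0, 1]`.
#' @return List with `si` (clipped to `[0, 1]`) and `si_raw`.
#' @examples
#' structure_index(matrix(0, 5, 5))$si  # 1: zero overlap
#' m <- matrix(0.5, 4, 4); diag(m) <- 0
#' structure_index(m)$si                # 0: random-level overlap
#' @export
structure_index <- function(m) {
  if (inherits(m, "overlap_matrix")) m <- m$m
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m)) {
    stop("m must be a square numeric matrix", call. = FALSE)
  }
  n <- nrow(m)
  if (n < 2L) stop("the overlap matrix needs at least 2 bin-groups",
                   call. = FALSE)
  if (any(abs(diag(m)) > 1e-12)) {
    stop("the overlap matrix must have a zero diagonal (no self-edges)",
         call. = FALSE)
  }
  if (any(m < -1e-12) || any(m > 1 + 1e-12)) {
    stop("overlap scores must lie in [0, 1]", call. = FALSE)
  }
  si_raw <- 1 - (2 / (n^2 - n)) * sum(m)
  list(si = max(si_raw, 0), si_raw = si_raw)
}

#' Compute the Structure Index of a feature over a point cloud
#'
#' Full pipeline: bin the feature into bin-groups, drop under-populated
#' groups, compute the directed pairwise overlap matrix, and reduce it to the
#' Structure Index. Optionally builds a permutation null distribution by
#' shuffling the feature values over the points.
#'
#' @param cloud N x D numeric matrix of point coordinates.
#' @param feature Length-N feature: numeric vector, character/factor vector,
#'   or N x m numeric matrix for a vector feature (see [assign_bins()]).
#' @param n_bins Bins per feature dimension for continuous features
#'   (default 10).
#' @param spec A [neighbor_spec()]; defaults to k = 3 Euclidean nearest
#'   neighbors, the local regime.
#' @param min_points Bin-groups smaller than this are dropped (default 3).
#' @param n_shuffles Number of feature permutations for the null
#'   distribution; 0 (default) skips it.
#' @param seed Integer seed driving the shuffles; required when
#'   `n_shuffles > 0`.
#' @param custom_edges Optional custom bin limits (see [assign_bins()]).
#' @param dist_matrix Optional precomputed N x N distance matrix.
#' @return An object of class `si_result`: list with `si`, `si_raw`,
#'   `overlap` (the `overlap_matrix`), `partition_summary`, `params`,
#'   `null_values` and `null_percentile_99` (the significance threshold;
#'   `NULL` when no shuffles were run).
#' @examples
#' toy <- gradient_ellipsoid(500, seed = 1)
#' res <- compute_si(toy$points, toy$feature, spec = neighbor_spec("knn", k = 3))
#' res$si  # close to 1: the gradient is strongly structured
#' @export
compute_si <- function(cloud, feature, n_bins = 10L,
                       spec = neighbor_spec("knn", k = 3L),
                       min_points = 3L, n_shuffles = 0L, seed = NULL,
                       custom_edges = NULL, dist_matrix = NULL) {
  cloud <- validate_cloud(cloud)
  n_pts <- if (is.matrix(feature) || is.data.frame(feature)) {
    nrow(feature)
  } else {
    length(feature)
  }
  if (n_pts != nrow(cloud)) {
    stop("cloud has ", nrow(cloud), " points but the feature has ", n_pts,
         " values", call. = FALSE)
  }
  n_shuffles <- as.integer(n_shuffles)
  if (n_shuffles > 0L && is.null(seed)) {
    stop("a seed is required when n_shuffles > 0 so the null is reproducible",
         call. = FALSE)
  }

  part <- assign_bins(feature, n_bins = n_bins, custom_edges = custom_edges)
  part <- filter_small_groups(part, min_points = min_points)
  full_dm <- resolve_distance_matrix(cloud, spec, dist_matrix)
  om <- overlap_matrix(cloud, part, spec, dist_matrix = full_dm)
  si <- structure_index(om)

  null_values <- numeric(0)
  null_99 <- NULL
  if (n_shuffles > 0L) {
    null_values <- shuffle_null(cloud, feature, n_bins = n_bins, spec = spec,
                                n_shuffles = n_shuffles, seed = seed,
                                min_points = min_points,
                                custom_edges = custom_edges,
                                dist_matrix = full_dm)
    null_99 <- stats::quantile(null_values, 0.99, type = 7, names = FALSE)
  }

  structure(
    list(si = si$si,
         si_raw = si$si_raw,
         overlap = om,
         partition_summary = list(n_groups = part$n_groups,
                                  group_sizes = part$group_sizes,
                                  group_labels = part$group_labels,
                                  edges = part$edges,
                                  kind = part$kind),
         params = list(spec = spec, n_bins = n_bins, min_points = min_points,
                       n_shuffles = n_shuffles, seed = seed),
         null_values = null_values,
         null_percentile_99 = null_99),
    class = "si_result")
}

#' Permutation null distribution of the Structure Index
#'
#' Randomly permutes the feature values over the points (the cloud is left
#' untouched) and recomputes the SI with identical parameters, once per
#' shuffle. Permuting preserves the marginal feature distribution, so the
#' bin edges -- and hence the group sizes -- are reproduced exactly; only the
#' assignment of points to groups is destroyed. The 99th percentile of the
#' returned values is the customary significance threshold.
#'
#' @inheritParams compute_si
#' @param n_shuffles Number of permutations, >= 1.
#' @param seed Integer seed; the whole sequence is reproducible from it.
#' @return Numeric vector of `n_shuffles` SI values (clipped at 0).
#' @export
shuffle_null <- function(cloud, feature, n_bins = 10L,
                         spec = neighbor_spec("knn", k = 3L),
                         n_shuffles = 100L, seed = NULL,
                         min_points = 3L, custom_edges = NULL,
                         dist_matrix = NULL) {
  cloud <- validate_cloud(cloud)
  n_shuffles <- as.integer(n_shuffles)
  if (is.na(n_shuffles) || n_shuffles < 1L) {
    stop("n_shuffles must be >= 1", call. = FALSE)
  }
  if (is.null(seed)) stop("shuffle_null requires a seed", call. = FALSE)
  n <- nrow(cloud)
  perms <- withr::with_seed(seed, {
    lapply(seq_len(n_shuffles), function(i) sample.int(n))
  })
  full_dm <- resolve_distance_matrix(cloud, spec, dist_matrix)
  vapply(perms, function(p) {
    f <- if (is.matrix(feature)) feature[p, , drop = FALSE] else feature[p]
    part <- suppressWarnings(
      assign_bins(f, n_bins = n_bins, custom_edges = custom_edges))
    part <- suppressWarnings(filter_small_groups(part, min_points))
    om <- overlap_matrix(cloud, part, spec, dist_matrix = full_dm)
    structure_index(om)$si
  }, numeric(1))
}

#' Structure Index profile over a grid of neighborhood sizes
#'
#' Recomputes the SI at each value of a grid of `k` (or `r`) values, sharing
#' one binning across the grid. Small neighborhoods probe the local
#' organization of the feature; large ones probe its global trend, so the
#' shape of the profile separates locally from globally structured features:
#' a locally repeating pattern collapses sharply as the neighborhood grows,
#' while a global gradient decays smoothly and stays high.
#'
#' @inheritParams compute_si
#' @param grid Strictly increasing numeric vector of `k` values (mode
#'   `"knn"`) or radii (mode `"radius"`).
#' @param mode `"knn"` or `"radius"`.
#' @param metric Distance metric, as in [neighbor_spec()].
#' @param graph_k Graph neighbors for the geodesic metric.
#' @return An object of class `sweep_profile`: a data frame with columns
#'   `grid`, `si`, `si_raw`, and `null_99` when `n_shuffles > 0`.
#' @export
si_sweep <- function(cloud, feature, grid, mode = c("knn", "radius"),
                     n_bins = 10L, metric = "euclidean", min_points = 3L,
                     n_shuffles = 0L, seed = NULL, custom_edges = NULL,
                     dist_matrix = NULL, graph_k = 15L) {
  mode <- match.arg(mode)
  cloud <- validate_cloud(cloud)
  grid <- as.numeric(grid)
  if (length(grid) == 0L || any(diff(grid) <= 0)) {
    stop("grid must be a non-empty strictly increasing sequence",
         call. = FALSE)
  }
  n_shuffles <- as.integer(n_shuffles)
  if (n_shuffles > 0L && is.null(seed)) {
    stop("a seed is required when n_shuffles > 0", call. = FALSE)
  }

  part <- assign_bins(feature, n_bins = n_bins, custom_edges = custom_edges)
  part <- filter_small_groups(part, min_points = min_points)

  if (mode == "knn") {
    sizes <- sort(part$group_sizes)
    smallest_pair <- sizes[1L] + sizes[2L]
    bad <- grid[grid + 1 > smallest_pair]
    if (length(bad) > 0L) {
      stop("grid value k = ", bad[1L], " is infeasible: the smallest ",
           "bin-group pair has only ", smallest_pair, " points combined",
           call. = FALSE)
    }
  }

  make_spec <- function(v) {
    if (mode == "knn") {
      neighbor_spec("knn", k = as.integer(v), metric = metric,
                    graph_k = graph_k)
    } else {
      neighbor_spec("radius", r = v, metric = metric, graph_k = graph_k)
    }
  }
  base_spec <- make_spec(grid[1L])
  full_dm <- resolve_distance_matrix(cloud, base_spec, dist_matrix)

  res <- lapply(grid, function(v) {
    om <- overlap_matrix(cloud, part, make_spec(v), dist_matrix = full_dm)
    structure_index(om)
  })
  out <- data.frame(grid = grid,
                    si = vapply(res, `[[`, numeric(1), "si"),
                    si_raw = vapply(res, `[[`, numeric(1), "si_raw"))

  if (n_shuffles > 0L) {
    n <- nrow(cloud)
    perms <- withr::with_seed(seed, {
      lapply(seq_len(n_shuffles), function(i) sample.int(n))
    })
    out$null_99 <- vapply(grid, function(v) {
      sp <- make_spec(v)
      vals <- vapply(perms, function(p) {
        f <- if (is.matrix(feature)) feature[p, , drop = FALSE] else feature[p]
        sp_part <- suppressWarnings(filter_small_groups(
          suppressWarnings(assign_bins(f, n_bins, custom_edges)), min_points))
        structure_index(
          overlap_matrix(cloud, sp_part, sp, dist_matrix = full_dm))$si
      }, numeric(1))
      stats::quantile(vals, 0.99, type = 7, names = FALSE)
    }, numeric(1))
  }
  class(out) <- c("sweep_profile", "data.frame")
  out
}

#' @export
print.si_result <- function(x, ...) {
  cat("Structure Index: ", format(x$si, digits = 4),
      " (raw ", format(x$si_raw, digits = 4), ")\n", sep = "")
  cat("  bin-groups: ", x$partition_summary$n_groups, " (",
      x$partition_summary$kind, "), sizes ",
      paste(x$partition_summary$group_sizes, collapse = ", "), "\n", sep = "")
  print(x$params$spec)
  if (length(x$null_values) > 0L) {
    cat("  shuffle null (n = ", length(x$null_values), "): 99th percentile ",
        format(x$null_percentile_99, digits = 4), "\n", sep = "")
    verdict <- if (x$si > x$null_percentile_99) "above" else "NOT above"
    cat("  observed SI is ", verdict, " the null threshold\n", sep = "")
  }
  invisible(x)
}

#' Serialize an SI result to JSON (and the overlap matrix to CSV)
#'
#' @param result An `si_result` from [compute_si()].
#' @param path Output JSON path. The overlap matrix is additionally written
#'   next to it as `<path-sans-ext>_overlap.csv` unless `matrix_csv` says
#'   otherwise.
#' @param matrix_csv Optional explicit path for the matrix CSV; `NA` skips it.
#' @return Invisibly, the paths written.
#' @export
write_si_result <- function(result, path, matrix_csv = NULL) {
  stopifnot(inherits(result, "si_result"))
  if (is.null(matrix_csv)) {
    matrix_csv <- paste0(sub("\\.json$", "", path), "_overlap.csv")
  }
  doc <- list(
    schema_version = "1.0",
    si = result$si,
    si_raw = result$si_raw,
    params = list(
      mode = result$params$spec$mode,
      k = result$params$spec$k,
      r = result$params$spec$r,
      metric = result$params$spec$metric,
      n_bins = result$params$n_bins,
      min_points = result$params$min_points,
      n_shuffles = result$params$n_shuffles,
      seed = result$params$seed),
    partition = list(
      n_groups = result$partition_summary$n_groups,
      group_sizes = result$partition_summary$group_sizes,
      group_labels = result$partition_summary$group_labels),
    null = if (length(result$null_values) > 0L) {
      list(n = length(result$null_values),
           percentile_99 = result$null_percentile_99,
           mean = mean(result$null_values),
           values = result$null_values)
    },
    overlap_matrix = result$overlap$m)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  paths <- path
  if (!is.na(matrix_csv)) {
    mm <- result$overlap$m
    dimnames(mm) <- list(result$overlap$node_labels,
                         result$overlap$node_labels)
    utils::write.csv(mm, matrix_csv)
    paths <- c(paths, matrix_csv)
  }
  invisible(paths)
}
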