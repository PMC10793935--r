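# Directed pairwise overlap scores between bin-groups.
#
# The overlap score OS_{U->V}(k) is the fraction of the k-nearest neighbors of
# the points of U that belong to V, with neighbors searched ONLY within
# U union V minus the query point itself -- never the whole cloud. The radius
# variant replaces the k-neighborhood with all points within distance r.

#' Neighborhood specification for overlap scoring
#'
#' @param mode `"knn"` (k-nearest neighbors) or `"radius"` (fixed-radius
#'   neighborhoods, for clouds of uneven density).
#' @param k Number of neighbors (knn mode), integer >= 1.
#' @param r Neighborhood radius (radius mode), positive, in the units of the
#'   point-cloud coordinates.
#' @param metric `"euclidean"`, or `"geodesic"` for shortest-path distance on
#'   the symmetrized k-nearest-neighbor graph of the full cloud (useful for
#'   curved manifolds). Ignored when a precomputed distance matrix is
#'   supplied.
#' @param graph_k Number of neighbors used to build the graph for the
#'   geodesic metric.
#' @return An object of class `neighbor_spec`.
#' @export
neighbor_spec <- function(mode = c("knn", "radius"), k = NULL, r = NULL,
                          metric = "euclidean", graph_k = 15L) {
  mode <- match.arg(mode)
  if (mode == "knn") {
    if (is.null(k)) stop("knn mode requires k", call. = FALSE)
    k <- as.integer(k)
    if (is.na(k) || k < 1L) stop("k must be an integer >= 1", call. = FALSE)
    if (!is.null(r)) stop("set k or r, not both", call. = FALSE)
  } else {
    if (is.null(r)) stop("radius mode requires r", call. = FALSE)
    if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
      stop("r must be a positive number", call. = FALSE)
    }
    if (!is.null(k)) stop("set k or r, not both", call. = FALSE)
  }
  if (!metric %in% c("euclidean", "geodesic")) {
    stop("metric must be \"euclidean\" or \"geodesic\"", call. = FALSE)
  }
  structure(list(mode = mode, k = k, r = r, metric = metric,
                 graph_k = as.integer(graph_k)),
            class = "neighbor_spec")
}

#' @export
print.neighbor_spec <- function(x, ...) {
  if (x$mode == "knn") {
    cat("Neighborhood: k =", x$k, "nearest neighbors,", x$metric, "metric\n")
  } else {
    cat("Neighborhood: radius r =", x$r, ",", x$metric, "metric\n")
  }
  invisible(x)
}

validate_cloud <- function(cloud) {
  if (is.data.frame(cloud)) cloud <- as.matrix(cloud)
  if (is.vector(cloud)) cloud <- matrix(cloud, ncol = 1L)
  if (!is.matrix(cloud) || !is.numeric(cloud)) {
    stop("point cloud must be a numeric matrix (N x D)", call. = FALSE)
  }
  if (nrow(cloud) < 2L) stop("point cloud needs at least 2 points",
                             call. = FALSE)
  if (anyNA(cloud) || any(!is.finite(cloud))) {
    stop("point cloud coordinates must be finite", call. = FALSE)
  }
  cloud
}

#' Directed k-nearest-neighbor overlap score between two point sets
#'
#' Computes the fraction of the k nearest neighbors of the points of `U` that
#' belong to `V`, with the neighbor search restricted to the union of the two
#' sets (minus the query point). Not symmetric in general. Ties at the k-th
#' distance are broken by ascending point index (U first, then V).
#'
#' @param points_u,points_v Numeric matrices (rows are points) with the same
#'   number of columns. The two sets are treated as disjoint.
#' @param k Number of neighbors, with `nrow(points_u) + nrow(points_v) >= k + 1`.
#' @param metric `"euclidean"` (sets this small are scored directly).
#' @return A number in `[0, 1]`.
#' @examples
#' overlap_score_knn(matrix(c(0, 1)), matrix(c(2.5, 3.5)), k = 1)  # 0
#' overlap_score_knn(matrix(c(0, 2)), matrix(c(1, 3)), k = 1)      # 1
#' @export
overlap_score_knn <- function(points_u, points_v, k, metric = "euclidean") {
  points_u <- validate_set(points_u)
  points_v <- validate_set(points_v)
  in_v <- c(rep(FALSE, nrow(points_u)), rep(TRUE, nrow(points_v)))
  pair_scores_knn(rbind(points_u, points_v), in_v, as.integer(k),
                  pair_name = c("U", "V"), is_dm = FALSE)[["uv"]]
}

#' Directed radius overlap score between two point sets
#'
#' For each point `u` of `U` with a non-empty neighborhood
#' `beta_u(r) = {x in U union V - {u} : d(u, x) <= r}`, computes the fraction
#' of `beta_u(r)` belonging to `V`, and averages over those points. Points
#' with an empty neighborhood are excluded from the average with a warning;
#' if every neighborhood is empty the score is undefined and 0 is returned
#' with a prominent warning.
#'
#' @inheritParams overlap_score_knn
#' @param r Neighborhood radius, positive.
#' @return A number in `[0, 1]`.
#' @examples
#' overlap_score_radius(matrix(c(0, 1)), matrix(c(5, 6)), r = 2)   # 0
#' overlap_score_radius(matrix(c(0, 1)), matrix(c(5, 6)), r = 10)  # 2/3
#' @export
overlap_score_radius <- function(points_u, points_v, r, metric = "euclidean") {
  points_u <- validate_set(points_u)
  points_v <- validate_set(points_v)
  in_v <- c(rep(FALSE, nrow(points_u)), rep(TRUE, nrow(points_v)))
  res <- pair_scores_radius(rbind(points_u, points_v), in_v, r,
                            is_dm = FALSE)
  report_radius_exclusions(res$excluded_u + res$excluded_v,
                           nrow(points_u) + nrow(points_v))
  if (is.na(res$uv)) 0 else res$uv
}

validate_set <- function(x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) < 1L) {
    stop("each point set must be a non-empty numeric matrix", call. = FALSE)
  }
  x
}

# Both directed knn scores for one group pair. in_v flags rows belonging to
# V. `x` is either the coordinates of U union V (is_dm = FALSE; distances
# computed in the kernel) or a precomputed pairwise distance matrix over the
# pair set. Returns c(uv, vu).
pair_scores_knn <- function(x, in_v, k, pair_name, is_dm) {
  m <- nrow(x)
  if (m <= k) {
    stop("bin-group pair (", pair_name[1L], ", ", pair_name[2L], ") has only ",
         m, " points combined but k = ", k, " neighbors were requested; ",
         "use a smaller k or a larger min_points", call. = FALSE)
  }
  cv <- if (is_dm) {            # V-members among each row's k nearest
    knn_v_counts(x, in_v, k)
  } else {
    knn_v_counts_points(x, in_v, k)
  }
  hits_v <- sum(cv[!in_v])
  hits_u <- sum(k - cv[in_v])
  n_u <- sum(!in_v)
  n_v <- m - n_u
  c(uv = hits_v / (n_u * k), vu = hits_u / (n_v * k))
}

pair_scores_radius <- function(x, in_v, r, is_dm) {
  cnt <- if (is_dm) {
    radius_counts(x, in_v, r)
  } else {
    radius_counts_points(x, in_v, r)
  }
  n_neigh <- cnt$n_neigh
  n_in_v <- cnt$n_in_v
  ok <- n_neigh > 0
  frac_v <- ifelse(ok, n_in_v / n_neigh, NA_real_)
  u_idx <- !in_v
  score_dir <- function(sel, frac) {
    use <- sel & ok
    if (!any(use)) return(NA_real_)
    mean(frac[use])
  }
  list(uv = score_dir(u_idx, frac_v),
       vu = score_dir(in_v, 1 - frac_v),
       excluded_u = sum(u_idx & !ok),
       excluded_v = sum(in_v & !ok))
}

report_radius_exclusions <- function(n_excluded, n_total) {
  if (n_excluded >= n_total) {
    warning("every point has an empty radius neighborhood; the overlap ",
            "score is undefined and reported as 0 -- increase r",
            call. = FALSE)
  } else if (n_excluded > 0L) {
    warning(n_excluded, " point(s) with empty radius neighborhoods were ",
            "excluded from the overlap average", call. = FALSE)
  }
}

#' Pairwise overlap matrix between bin-groups
#'
#' Computes the n x n adjacency matrix whose entry (i, j) is the directed
#' overlap score from bin-group i to bin-group j, each pair scored
#' independently with the neighbor search restricted to that pair's points.
#' The diagonal is identically zero (no self-edges).
#'
#' @param cloud N x D numeric matrix of point coordinates.
#' @param partition A `bin_partition` over the same N points.
#' @param spec A [neighbor_spec()].
#' @param dist_matrix Optional precomputed N x N distance matrix (any user
#'   metric); overrides `spec$metric`.
#' @return An object of class `overlap_matrix`: list with `m` (the matrix),
#'   `node_labels`, `group_sizes` and `spec`.
#' @export
overlap_matrix <- function(cloud, partition, spec, dist_matrix = NULL) {
  cloud <- validate_cloud(cloud)
  stopifnot(inherits(partition, "bin_partition"),
            inherits(spec, "neighbor_spec"))
  if (length(partition$labels) != nrow(cloud)) {
    stop("partition covers ", length(partition$labels),
         " points but the cloud has ", nrow(cloud), call. = FALSE)
  }
  n <- partition$n_groups
  groups <- split(seq_len(nrow(cloud)), partition$labels)

  full_dm <- resolve_distance_matrix(cloud, spec, dist_matrix)

  m <- matrix(0, n, n)
  excluded <- 0L
  undef_pairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      idx <- c(groups[[i]], groups[[j]])
      is_dm <- !is.null(full_dm)
      x <- if (is_dm) {
        full_dm[idx, idx, drop = FALSE]
      } else {
        cloud[idx, , drop = FALSE]
      }
      in_v <- c(rep(FALSE, length(groups[[i]])),
                rep(TRUE, length(groups[[j]])))
      if (spec$mode == "knn") {
        sc <- pair_scores_knn(x, in_v, spec$k,
                              pair_name = partition$group_labels[c(i, j)],
                              is_dm = is_dm)
        m[i, j] <- sc[["uv"]]
        m[j, i] <- sc[["vu"]]
      } else {
        sc <- pair_scores_radius(x, in_v, spec$r, is_dm = is_dm)
        excluded <- excluded + sc$excluded_u + sc$excluded_v
        if (is.na(sc$uv) || is.na(sc$vu)) undef_pairs <- undef_pairs + 1L
        m[i, j] <- if (is.na(sc$uv)) 0 else sc$uv
        m[j, i] <- if (is.na(sc$vu)) 0 else sc$vu
      }
    }
  }
  if (undef_pairs > 0L) {
    warning(undef_pairs, " directed pair(s) had every neighborhood empty; ",
            "their overlap is undefined and reported as 0 -- increase r",
            call. = FALSE)
  } else if (excluded > 0L) {
    warning(excluded, " point-in-pair case(s) with empty radius ",
            "neighborhoods were excluded from the overlap averages",
            call. = FALSE)
  }
  structure(list(m = m,
                 node_labels = partition$group_labels,
                 group_sizes = partition$group_sizes,
                 spec = spec),
            class = "overlap_matrix")
}

# NULL for the plain euclidean case (per-pair distances are computed on the
# fly); otherwise a full N x N matrix to slice per pair.
resolve_distance_matrix <- function(cloud, spec, dist_matrix) {
  if (!is.null(dist_matrix)) {
    dist_matrix <- as.matrix(dist_matrix)
    if (nrow(dist_matrix) != nrow(cloud) ||
        ncol(dist_matrix) != nrow(cloud)) {
      stop("dist_matrix must be N x N with N = nrow(cloud)", call. = FALSE)
    }
    return(dist_matrix)
  }
  if (spec$metric == "geodesic") {
    return(geodesic_distances(cloud, spec$graph_k))
  }
  NULL
}

#' Geodesic distance matrix over a point cloud
#'
#' Shortest-path distances on the symmetrized k-nearest-neighbor graph of the
#' cloud, with Euclidean edge weights. Approximates distances along the
#' manifold the cloud samples, so the overlap search follows the data rather
#' than cutting across ambient space.
#'
#' @param cloud N x D numeric matrix.
#' @param graph_k Neighbors per point in the graph; must be large enough to
#'   connect the cloud.
#' @return N x N matrix of geodesic distances.
#' @export
geodesic_distances <- function(cloud, graph_k = 15L) {
  cloud <- validate_cloud(cloud)
  n <- nrow(cloud)
  graph_k <- min(as.integer(graph_k), n - 1L)
  dm <- as.matrix(stats::dist(cloud))
  diag(dm) <- Inf
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    nn <- order(dm[i, ])[seq_len(graph_k)]
    edges[[i]] <- cbind(i, nn, dm[i, nn])
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_data_frame(
    data.frame(from = e[, 1L], to = e[, 2L], weight = e[, 3L]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  g <- igraph::simplify(g, edge.attr.comb = "min")  # symmetrize kNN relation
  gd <- igraph::distances(g, weights = igraph::E(g)$weight)
  ord <- order(as.integer(igraph::V(g)$name))
  gd <- gd[ord, ord]
  if (any(!is.finite(gd))) {
    stop("the k-nearest-neighbor graph is disconnected at graph_k = ",
         graph_k, "; increase graph_k", call. = FALSE)
  }
  unname(gd)
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("Overlap matrix over", length(x$node_labels), "bin-groups\n")
  print(x$spec)
  mm <- x$m
  dimnames(mm) <- list(x$node_labels, x$node_labels)
  print(round(mm, 3))
  invisible(x)
}
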