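# Partitioning a point cloud into bin-groups according to feature values.
#
# A bin-group is the subset of points whose feature values fall in one bin.
# The bin-groups form a disjoint finite covering of the assigned points and
# become the nodes of the overlap graph.

#' Uniform bin edges over a feature range
#'
#' Computes `n_bins + 1` equally spaced bin limits spanning
#' `[feature_min, feature_max]`, i.e. `t_i = (i - 1) * (max - min) / n + min`.
#'
#' @param feature_min,feature_max Finite scalars with
#'   `feature_max > feature_min`.
#' @param n_bins Number of bins, an integer >= 2.
#' @return Numeric vector of length `n_bins + 1`, strictly increasing, with
#'   first element `feature_min` and last element `feature_max`.
#' @examples
#' uniform_bin_edges(0, 1, 2)   # 0.0 0.5 1.0
#' uniform_bin_edges(-1, 1, 4)  # -1 -0.5 0 0.5 1
#' @export
uniform_bin_edges <- function(feature_min, feature_max, n_bins) {
  if (!is.numeric(feature_min) || !is.numeric(feature_max) ||
      length(feature_min) != 1L || length(feature_max) != 1L ||
      !is.finite(feature_min) || !is.finite(feature_max)) {
    stop("feature_min and feature_max must be finite scalars", call. = FALSE)
  }
  if (feature_max == feature_min) {
    stop("constant feature has no structure to bin", call. = FALSE)
  }
  if (feature_max < feature_min) {
    stop("feature_max must exceed feature_min", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) {
    stop("n_bins must be an integer >= 2", call. = FALSE)
  }
  seq(feature_min, feature_max, length.out = n_bins + 1L)
}

#' Assign points to bin-groups by feature value
#'
#' Partitions the points into disjoint bin-groups. Continuous features are cut
#' into half-open intervals `[t_i, t_{i+1})`, the last bin closed at the
#' maximum so every point is covered. Categorical features get one bin-group
#' per distinct label, in order of first appearance. Vector (multi-column)
#' features are binned per dimension and grouped by the Cartesian product of
#' the per-dimension bins; empty product cells are dropped.
#'
#' @param feature Numeric vector (continuous), character/factor vector
#'   (categorical), or numeric matrix / data frame with one column per
#'   feature dimension (vector feature).
#' @param n_bins Bins per dimension for continuous/vector features; a single
#'   integer (recycled across dimensions) or one integer per dimension.
#'   Ignored for categorical features and when `custom_edges` is given.
#' @param custom_edges Optional ascending numeric vector of bin limits, or
#'   (vector features) a list with one such vector per dimension. Points
#'   falling outside the custom range are left unassigned with a warning.
#' @return An object of class `bin_partition`: a list with `labels`
#'   (integer bin-group index per point, 1-based, `NA` for unassigned points),
#'   `n_groups`, `group_sizes`, `group_labels` (human-readable descriptors),
#'   `edges` (list of per-dimension edge vectors, `NULL` for categorical),
#'   and `kind` (`"continuous"`, `"categorical"` or `"vector"`).
#' @examples
#' assign_bins(c(0, 0.25, 0.5, 0.75, 1), n_bins = 2)$labels  # 1 1 2 2 2
#' assign_bins(c("awake", "rem", "awake", "sws"))$labels     # 1 2 1 3
#' @export
assign_bins <- function(feature, n_bins = 10L, custom_edges = NULL) {
  if (is.data.frame(feature)) feature <- as.matrix(feature)
  if (is.factor(feature)) feature <- as.character(feature)

  if (is.matrix(feature) && ncol(feature) > 1L) {
    return(assign_bins_vector(feature, n_bins, custom_edges))
  }
  if (is.matrix(feature)) feature <- drop(feature)
  if (length(feature) == 0L) stop("feature is empty", call. = FALSE)

  if (is.character(feature)) {
    return(assign_bins_categorical(feature))
  }
  if (!is.numeric(feature)) {
    stop("feature must be numeric, character/factor, or a numeric matrix",
         call. = FALSE)
  }
  assign_bins_continuous(feature, n_bins, custom_edges)
}

assign_bins_continuous <- function(values, n_bins, custom_edges) {
  if (anyNA(values) || any(!is.finite(values))) {
    stop("continuous feature values must be finite", call. = FALSE)
  }
  if (is.null(custom_edges)) {
    edges <- uniform_bin_edges(min(values), max(values), n_bins)
  } else {
    edges <- validate_edges(custom_edges)
  }
  raw <- bin_index(values, edges)
  outside <- is.na(raw)
  if (any(outside)) {
    warning(sum(outside), " point(s) fall outside the custom bin range and ",
            "are left unassigned", call. = FALSE)
  }
  finalize_partition(raw, kind = "continuous", edges = list(edges),
                     group_labels_fn = function(keep) {
                       interval_labels(edges)[keep]
                     })
}

assign_bins_categorical <- function(values) {
  if (anyNA(values)) stop("categorical feature contains NA", call. = FALSE)
  lev <- unique(values)  # first-appearance order
  raw <- match(values, lev)
  finalize_partition(raw, kind = "categorical", edges = NULL,
                     group_labels_fn = function(keep) lev[keep])
}

assign_bins_vector <- function(values, n_bins, custom_edges) {
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    stop("vector feature entries must be finite numbers", call. = FALSE)
  }
  m <- ncol(values)
  if (!is.null(custom_edges)) {
    if (!is.list(custom_edges) || length(custom_edges) != m) {
      stop("custom_edges must be a list with one edge vector per feature ",
           "dimension (", m, " expected)", call. = FALSE)
    }
    edges <- lapply(custom_edges, validate_edges)
  } else {
    if (length(n_bins) == 1L) n_bins <- rep(n_bins, m)
    if (length(n_bins) != m) {
      stop("n_bins must have length 1 or one entry per feature dimension (",
           m, " expected)", call. = FALSE)
    }
    edges <- lapply(seq_len(m), function(d) {
      uniform_bin_edges(min(values[, d]), max(values[, d]), n_bins[[d]])
    })
  }
  per_dim <- lapply(seq_len(m), function(d) bin_index(values[, d], edges[[d]]))
  outside <- Reduce(`|`, lapply(per_dim, is.na))
  if (any(outside)) {
    warning(sum(outside), " point(s) fall outside the custom bin range and ",
            "are left unassigned", call. = FALSE)
  }
  # Lexicographic cell key over the per-dimension bin indices; empty product
  # cells never appear since keys are taken from the data.
  nb <- vapply(edges, function(e) length(e) - 1L, integer(1))
  key <- per_dim[[1L]]
  for (d in seq_len(m)[-1L]) key <- (key - 1L) * nb[[d]] + per_dim[[d]]
  occupied <- sort(unique(key[!is.na(key)]))
  raw <- match(key, occupied)
  dim_labels <- lapply(edges, interval_labels)
  cell_label <- function(cell_key) {
    idx <- integer(m)
    k <- cell_key - 1L
    for (d in rev(seq_len(m))) {
      idx[d] <- k %% nb[[d]] + 1L
      k <- k %/% nb[[d]]
    }
    paste(vapply(seq_len(m), function(d) dim_labels[[d]][idx[d]],
                 character(1)), collapse = " x ")
  }
  part <- finalize_partition(raw, kind = "vector", edges = edges,
                             group_labels_fn = function(keep) {
                               vapply(occupied[keep], cell_label, character(1))
                             })
  part$per_dim_labels <- do.call(cbind, per_dim)
  part
}

# Interval membership with the last bin closed at the maximum edge.
bin_index <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[idx == 0L | idx == length(edges)] <- NA_integer_
  idx
}

validate_edges <- function(edges) {
  edges <- as.numeric(edges)
  if (length(edges) < 3L || anyNA(edges) || any(!is.finite(edges)) ||
      any(diff(edges) <= 0)) {
    stop("custom edges must be a strictly increasing numeric vector ",
         "defining at least 2 bins", call. = FALSE)
  }
  edges
}

interval_labels <- function(edges) {
  n <- length(edges) - 1L
  lab <- sprintf("[%.4g, %.4g)", edges[-length(edges)], edges[-1L])
  lab[n] <- sprintf("[%.4g, %.4g]", edges[n], edges[n + 1L])
  lab
}

# Drop empty groups, re-index densely in ascending raw order, build object.
finalize_partition <- function(raw, kind, edges, group_labels_fn) {
  present <- sort(unique(raw[!is.na(raw)]))
  if (length(present) < 2L) {
    stop("fewer than 2 non-empty bin-groups; structure is undefined for a ",
         "single group (consider more bins or a different feature)",
         call. = FALSE)
  }
  labels <- match(raw, present)
  sizes <- tabulate(labels, nbins = length(present))
  keep_mask <- logical(max(present))
  keep_mask[present] <- TRUE
  structure(
    list(labels = labels,
         n_groups = length(present),
         group_sizes = sizes,
         group_labels = group_labels_fn(keep_mask),
         edges = edges,
         kind = kind),
    class = "bin_partition")
}

#' Drop under-populated bin-groups
#'
#' Removes bin-groups holding fewer than `min_points` points; their points are
#' marked unassigned and the surviving groups re-indexed densely. The
#' k-nearest-neighbor overlap score needs every point to have `k` neighbors
#' within each pair of groups, so tiny groups make small-`k` scores
#' meaningless.
#'
#' @param partition A `bin_partition` from [assign_bins()].
#' @param min_points Minimum group size to keep, an integer >= 1.
#' @return A `bin_partition` with the small groups dropped. A warning names
#'   the dropped groups; an error is raised if fewer than 2 groups survive.
#' @export
filter_small_groups <- function(partition, min_points = 3L) {
  stopifnot(inherits(partition, "bin_partition"))
  min_points <- as.integer(min_points)
  if (is.na(min_points) || min_points < 1L) {
    stop("min_points must be an integer >= 1", call. = FALSE)
  }
  keep <- partition$group_sizes >= min_points
  if (all(keep)) return(partition)
  if (sum(keep) < 2L) {
    stop("fewer than 2 bin-groups have at least ", min_points,
         " points; decrease min_points or use fewer bins", call. = FALSE)
  }
  dropped <- which(!keep)
  warning("dropping ", length(dropped), " bin-group(s) with fewer than ",
          min_points, " points: ",
          paste(partition$group_labels[dropped], collapse = ", "),
          call. = FALSE)
  new_index <- rep(NA_integer_, partition$n_groups)
  new_index[keep] <- seq_len(sum(keep))
  labels <- new_index[partition$labels]
  partition$labels <- labels
  partition$n_groups <- sum(keep)
  partition$group_sizes <- partition$group_sizes[keep]
  partition$group_labels <- partition$group_labels[keep]
  partition
}

#' @export
print.bin_partition <- function(x, ...) {
  cat("Bin partition (", x$kind, "): ", x$n_groups, " groups, ",
      sum(x$group_sizes), " assigned point(s)\n", sep = "")
  sizes <- paste0(x$group_labels, " (n=", x$group_sizes, ")")
  cat(paste0("  ", sizes, collapse = "\n"), "\n")
  invisible(x)
}
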