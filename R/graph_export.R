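# The overlap matrix as a weighted directed graph: nodes are bin-groups,
# edges the directed overlaps. Two feature layouts can share the same SI yet
# differ in graph topology, and edge asymmetry (which group infiltrates
# which) is itself a diagnostic, so the graph is exported verbatim, never
# symmetrized.

#' Weighted directed graph of bin-group overlaps
#'
#' Builds an [igraph][igraph::graph_from_adjacency_matrix] directed graph
#' from an overlap matrix. Every bin-group is a node (isolated nodes are
#' kept); the edges are the strictly positive off-diagonal entries above
#' `weight_threshold`, with the overlap score as edge weight. There are no
#' self-edges.
#'
#' @param m An `overlap_matrix` from [overlap_matrix()], or a plain square
#'   numeric matrix with zero diagonal.
#' @param weight_threshold Edges with weight `<= weight_threshold` are
#'   dropped; default 0 keeps all positive edges (pruning is opt-in, for
#'   display).
#' @return An `igraph` object with vertex attributes `label` (bin range or
#'   category) and `size` (points in the group), and edge attribute `weight`.
#' @examples
#' m <- matrix(0, 3, 3); m[1, 2] <- 0.7
#' g <- to_graph(m)
#' igraph::ecount(g)  # 1 directed edge
#' @export
to_graph <- function(m, weight_threshold = 0) {
  node_labels <- NULL
  group_sizes <- NULL
  if (inherits(m, "overlap_matrix")) {
    node_labels <- m$node_labels
    group_sizes <- m$group_sizes
    m <- m$m
  }
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("m must be a square matrix or an overlap_matrix", call. = FALSE)
  }
  if (!is.numeric(weight_threshold) || weight_threshold < 0 ||
      weight_threshold >= 1) {
    stop("weight_threshold must lie in [0, 1)", call. = FALSE)
  }
  n <- nrow(m)
  if (is.null(node_labels)) node_labels <- as.character(seq_len(n))
  mm <- m
  mm[mm <= weight_threshold] <- 0
  diag(mm) <- 0
  g <- igraph::graph_from_adjacency_matrix(mm, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n))
  igraph::V(g)$label <- node_labels
  if (!is.null(group_sizes)) igraph::V(g)$size <- group_sizes
  g
}

#' Write an overlap graph to disk
#'
#' @param g An `igraph` graph, typically from [to_graph()].
#' @param path Output file path.
#' @param format `"graphml"` (nodes with label/size attributes, edges with
#'   weight) or `"edgelist"` (3-column TSV `source target weight` with a
#'   commented header; weights to full precision).
#' @return Invisibly, `path`.
#' @export
write_graph_file <- function(g, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "igraph"))
  res <- tryCatch({
    if (format == "graphml") {
      igraph::write_graph(g, path, format = "graphml")
    } else {
      el <- igraph::as_edgelist(g)
      w <- if (igraph::ecount(g) > 0) igraph::E(g)$weight else numeric(0)
      lines <- "# source\ttarget\tweight"
      if (nrow(el) > 0L) {
        lines <- c(lines, paste(el[, 1L], el[, 2L],
                                formatC(w, digits = 17, format = "g"),
                                sep = "\t"))
      }
      writeLines(lines, path)
    }
    TRUE
  }, error = function(e) e)
  if (inherits(res, "error")) {
    stop("failed to write graph to '", path, "': ", conditionMessage(res),
         call. = FALSE)
  }
  invisible(path)
}

#' Structure Index recomputed from graph out-degrees
#'
#' The SI is 1 minus the scaled mean weighted out-degree of the overlap
#' graph; this helper recovers it from an unthresholded graph, as a
#' cross-check against [structure_index()] on the matrix.
#'
#' @param g An `igraph` graph whose edge weights are overlap scores.
#' @return The SI (clipped at 0).
#' @export
si_from_graph <- function(g) {
  stopifnot(inherits(g, "igraph"))
  n <- igraph::vcount(g)
  if (n < 2L) stop("the graph needs at least 2 nodes", call. = FALSE)
  total <- sum(igraph::strength(g, mode = "out",
                                weights = igraph::E(g)$weight))
  max(1 - (2 / (n^2 - n)) * total, 0)
}
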