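#' Build an undirected brain graph from adjacency and weights
#'
#' Nodes are atlas regions; edges are suprathreshold connections. The
#' binary adjacency drives degree and path-length metrics; the optional
#' weight matrix (conventionally the absolute group z values on the
#' suprathreshold edges) drives weighted degree. Self-loops are removed,
#' symmetry enforced.
#'
#' @param adjacency symmetric 0/1 matrix (from [threshold_z()]).
#' @param weights optional symmetric nonnegative weight matrix; defaults
#'   to the adjacency.
#' @param region_ids node ids; defaults to rownames or 1..n.
#' @return object of class `brain_graph` with fields `A`, `W`, `nodes`,
#'   and the `igraph` object `g`.
#' @export
brain_graph <- function(adjacency, weights = NULL, region_ids = NULL) {
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  A <- (A != 0 & !is.na(A)) * 1
  A <- pmax(A, t(A))
  diag(A) <- 0
  if (is.null(weights)) weights <- A
  W <- as.matrix(weights)
  W[is.na(W)] <- 0
  if (any(W < 0)) stop("edge weights must be nonnegative")
  W <- W * A                            # weights live only on edges
  W <- (W + t(W)) / 2
  if (is.null(region_ids))
    region_ids <- rownames(A) %||% as.character(seq_len(nrow(A)))
  dimnames(A) <- dimnames(W) <- list(region_ids, region_ids)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  structure(list(A = A, W = W, nodes = region_ids, g = g),
            class = "brain_graph")
}

#' @export
print.brain_graph <- function(x, ...) {
  cat(sprintf("<brain_graph> %d nodes, %d edges\n",
              length(x$nodes), sum(x$A) / 2))
  invisible(x)
}

#' Degree centrality: connections per node
#'
#' The number of edges incident to each node — the row sums of the binary
#' adjacency.
#'
#' @param g a [brain_graph()].
#' @return named integer vector of degrees.
#' @export
degree_centrality <- function(g) {
  stats::setNames(as.integer(rowSums(g$A)), g$nodes)
}

#' Weighted degree: total connection strength per node
#'
#' The sum of incident edge weights; with all weights 1 it reduces to
#' [degree_centrality()].
#'
#' @param g a [brain_graph()].
#' @return named numeric vector.
#' @export
weighted_degree <- function(g) {
  stats::setNames(rowSums(g$W), g$nodes)
}

#' Global graph metrics: degree, density, path length, weighted degree
#'
#' `density = 2 |E| / (n (n - 1))`, `average_degree = 2 |E| / n`,
#' `average_weighted_degree = mean of weighted degrees`, and
#' `average_path_length` as the mean unweighted shortest-path length. On a
#' disconnected graph the default averages over connected pairs only and
#' reports the number of disconnected ordered pairs;
#' `path_length = "largest_component"` instead restricts to the largest
#' connected component. An edgeless graph has no defined path length
#' (`NA`).
#'
#' @param g a [brain_graph()] with >= 2 nodes.
#' @param path_length `"connected_pairs"` (default) or
#'   `"largest_component"`.
#' @return list of class `graph_metrics`: `n_nodes`, `n_edges`,
#'   `average_degree`, `density`, `average_path_length`,
#'   `average_weighted_degree`, `n_disconnected_pairs`.
#' @export
global_metrics <- function(g, path_length = c("connected_pairs",
                                              "largest_component")) {
  path_length <- match.arg(path_length)
  n <- length(g$nodes)
  if (n < 2L) stop("graph metrics need at least 2 nodes")
  n_edges <- sum(g$A) / 2
  dmat <- igraph::distances(g$g)
  off <- dmat[upper.tri(dmat)]
  n_disc <- 2L * sum(is.infinite(off))
  apl <- if (n_edges == 0) {
    NA_real_
  } else if (path_length == "connected_pairs") {
    mean(off[is.finite(off)])
  } else {
    comp <- igraph::components(g$g)
    keep <- comp$membership == which.max(comp$csize)
    sub <- dmat[keep, keep, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }
  structure(list(n_nodes = n, n_edges = n_edges,
                 average_degree = 2 * n_edges / n,
                 density = 2 * n_edges / (n * (n - 1)),
                 average_path_length = apl,
                 average_weighted_degree = mean(rowSums(g$W)),
                 n_disconnected_pairs = n_disc,
                 path_length_rule = path_length),
            class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf(
    "<graph_metrics> n=%d  avg degree %.3f  density %.3f  avg path length %s  avg weighted degree %.3f\n",
    x$n_nodes, x$average_degree, x$density,
    if (is.na(x$average_path_length)) "NA" else sprintf("%.3f", x$average_path_length),
    x$average_weighted_degree))
  invisible(x)
}

#' Degree distributions per macro-region
#'
#' Splits the per-node degree list by the 11 macro-region groups of the
#' region table — the per-group dot-plot / group-test payload.
#'
#' @param g a [brain_graph()] whose nodes are region ids.
#' @param region_table region table mapping `region_id` to `macro_region`.
#' @return named list: macro-region to named vector of member degrees.
#' @export
macro_region_degrees <- function(g, region_table) {
  deg <- degree_centrality(g)
  idx <- match(g$nodes, as.character(region_table$region_id))
  if (any(is.na(idx)))
    stop(sprintf("node(s) missing from the region table: %s",
                 paste(g$nodes[is.na(idx)], collapse = ", ")))
  split(deg, region_table$macro_region[idx])
}

#' Extract the subnetwork incident to designated hub nodes
#'
#' All edges touching any hub node, the union of partner nodes reached,
#' and the total connection count — the radial hub-connectivity view
#' (e.g. all connections to a set of deep nuclei).
#'
#' @param g a [brain_graph()].
#' @param hub_nodes nonempty subset of `g$nodes`.
#' @return list: `edges` (data.frame source/target/weight),
#'   `partners` (non-hub nodes reached), `n_connections`.
#' @export
hub_subnetwork <- function(g, hub_nodes) {
  hub_nodes <- as.character(hub_nodes)
  if (!length(hub_nodes)) stop("hub_nodes must be nonempty")
  if (!all(hub_nodes %in% g$nodes))
    stop(sprintf("hub node(s) not in the graph: %s",
                 paste(setdiff(hub_nodes, g$nodes), collapse = ", ")))
  hub_idx <- match(hub_nodes, g$nodes)
  idx <- which(g$A > 0 & upper.tri(g$A), arr.ind = TRUE)
  touch <- idx[, 1] %in% hub_idx | idx[, 2] %in% hub_idx
  idx <- idx[touch, , drop = FALSE]
  edges <- data.frame(source = g$nodes[idx[, 1]], target = g$nodes[idx[, 2]],
                      weight = g$W[idx], stringsAsFactors = FALSE)
  partners <- setdiff(unique(c(edges$source, edges$target)), hub_nodes)
  list(edges = edges, partners = partners, n_connections = nrow(edges))
}
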