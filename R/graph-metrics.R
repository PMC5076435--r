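#' Node degree
#'
#' Number of nonzero off-diagonal connections per node.
#'
#' @param g a [network_graph()].
#' @return Named integer vector.
#' @export
node_degree <- function(g) {
  stopifnot(inherits(g, "network_graph"))
  w <- g$weights
  diag(w) <- 0
  setNames(as.integer(rowSums(w > 0)), g$node_labels)
}

#' Node strength
#'
#' Sum of edge weights per node.
#'
#' @param g a [network_graph()].
#' @return Named numeric vector.
#' @export
node_strength <- function(g) {
  stopifnot(inherits(g, "network_graph"))
  w <- g$weights
  diag(w) <- 0
  setNames(rowSums(w), g$node_labels)
}

# shortest-path distance matrix with edge length = 1/weight
graph_distances <- function(g) {
  w <- g$weights
  n <- nrow(w)
  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  if (igraph::ecount(ig) == 0) {
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    dimnames(d) <- dimnames(w)
    return(d)
  }
  igraph::distances(ig, weights = 1 / igraph::E(ig)$weight,
                    algorithm = "dijkstra")
}

#' Nodal path-length
#'
#' Mean shortest-path distance from each node to the other nodes it can
#' reach, with each edge weight `w > 0` contributing length `1/w`.
#' Unreachable nodes are excluded from the mean; an isolated node has no
#' defined path-length and is reported as `NA`.
#'
#' @param g a [network_graph()].
#' @return Named numeric vector (possibly containing `NA`).
#' @export
nodal_path_length <- function(g) {
  stopifnot(inherits(g, "network_graph"))
  d <- graph_distances(g)
  diag(d) <- NA
  d[!is.finite(d)] <- NA
  pl <- rowMeans(d, na.rm = TRUE)
  pl[!is.finite(pl)] <- NA
  setNames(pl, g$node_labels)
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path distance,
#' with unreachable pairs contributing zero. With edge lengths `1/w` a
#' two-node graph of weight `w` has efficiency `w`, and a complete
#' unit-weight graph has efficiency 1.
#'
#' @param g a [network_graph()].
#' @return Single number; 0 for an empty or single-node graph.
#' @export
global_efficiency <- function(g) {
  stopifnot(inherits(g, "network_graph"))
  n <- nrow(g$weights)
  if (n < 2) return(0)
  d <- graph_distances(g)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Inter-hemispheric network similarity
#'
#' Pearson correlation between the within-left and within-right edge
#' vectors of a connectivity matrix under the homotopic node
#' correspondence: right nodes are ordered by their left partners, both
#' within-hemisphere submatrices are reduced to their upper triangles, and
#' the two vectors are correlated. Midline / unpaired nodes are excluded.
#'
#' @param m a [connectivity_matrix()] or [network_graph()].
#' @param atlas list with `hemisphere` and `homotopic_pair` (see
#'   [ground_truth_network()]).
#' @return Correlation in `[-1, 1]`.
#' @export
interhemispheric_similarity <- function(m, atlas) {
  v <- if (inherits(m, "network_graph")) m$weights else m$values
  left <- which(atlas$hemisphere == "left" & !is.na(atlas$homotopic_pair))
  if (length(left) < 3)
    stop("need at least 3 homotopically paired left nodes")
  right <- atlas$homotopic_pair[left]
  ll <- v[left, left, drop = FALSE]
  rr <- v[right, right, drop = FALSE]
  a <- upper_tri_values(ll)
  b <- upper_tri_values(rr)
  if (length(a) < 3) stop("fewer than 3 within-hemisphere edges per side")
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero-variance within-hemisphere edge vector")
  cor(a, b)
}

#' Network-level summary metrics
#'
#' Average node degree, average node strength, global efficiency, and
#' (when an atlas with homotopic pairing is supplied together with a
#' connectivity matrix) the inter-hemispheric similarity.
#'
#' @param g a [network_graph()].
#' @param m optional [connectivity_matrix()] for the similarity (the
#'   unthresholded matrix by default; pass `g` itself to use thresholded
#'   weights).
#' @param atlas optional atlas descriptor with homotopic pairing.
#' @return List of class `network_metrics`: `average_degree`,
#'   `average_strength`, `global_efficiency`,
#'   `interhemispheric_similarity` (`NA` if not computable).
#' @export
network_summary <- function(g, m = NULL, atlas = NULL) {
  sim <- NA_real_
  if (!is.null(m) && !is.null(atlas))
    sim <- tryCatch(interhemispheric_similarity(m, atlas),
                    error = function(e) NA_real_)
  structure(list(average_degree = mean(node_degree(g)),
                 average_strength = mean(node_strength(g)),
                 global_efficiency = global_efficiency(g),
                 interhemispheric_similarity = sim),
            class = "network_metrics")
}

#' Binarise a weighted network
#'
#' Replaces every positive weight with 1 (the "binarised" variant used for
#' degree-based summaries).
#'
#' @param g a [network_graph()].
#' @return A [network_graph()].
#' @export
binarize_network <- function(g) {
  stopifnot(inherits(g, "network_graph"))
  w <- (g$weights > 0) * 1
  network_graph(w, kind = g$kind,
                provenance = paste0(g$provenance, "; binarized"))
}

#' Restrict a graph or connectivity matrix to a subnetwork
#'
#' @param x a [network_graph()] or [connectivity_matrix()].
#' @param nodes node labels (or indices) to keep.
#' @return Object of the same class on the subset.
#' @export
subnetwork <- function(x, nodes) {
  if (inherits(x, "network_graph")) {
    idx <- if (is.character(nodes)) match(nodes, x$node_labels) else nodes
    if (anyNA(idx)) stop("unknown node labels: ",
                         paste(nodes[is.na(idx)], collapse = ", "))
    network_graph(x$weights[idx, idx, drop = FALSE], kind = x$kind,
                  provenance = paste0(x$provenance, "; subnetwork"))
  } else if (inherits(x, "connectivity_matrix")) {
    idx <- if (is.character(nodes)) match(nodes, x$node_labels) else nodes
    if (anyNA(idx)) stop("unknown node labels: ",
                         paste(nodes[is.na(idx)], collapse = ", "))
    connectivity_matrix(x$values[idx, idx, drop = FALSE], kind = x$kind)
  } else stop("unsupported input")
}
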