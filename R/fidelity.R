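# Embedding fidelity metrics: graph shortest-path metric, average distortion
# (global, distance-value based) and mean average precision (local,
# rank based).

#' All-pairs shortest-path distances of a connected graph
#'
#' @param g a [binary_graph()] or igraph; must be connected (extract the
#'   largest component first).
#' @return symmetric integer hop-count matrix with zero diagonal.
#' @export
graph_metric <- function(g) {
  bg <- as_binary_graph(g)
  d <- igraph::distances(bg$graph)
  if (any(!is.finite(d)))
    stop_hc("graph is disconnected; embed the largest connected component ",
            "(see largest_component())", class = "hypercon_disconnected")
  d
}

#' Average distortion of an embedding
#'
#' Mean over unordered pairs of `|d_V - d_U| / d_U`, where `d_U` are graph
#' distances and `d_V` embedded distances. Zero means the embedding
#' preserves every pairwise distance exactly; values above 1 are possible.
#'
#' @param embedded symmetric matrix of embedded-space distances.
#' @param graph symmetric matrix of graph distances (positive off-diagonal).
#' @return nonnegative scalar.
#' @export
distortion <- function(embedded, graph) {
  embedded <- as.matrix(embedded); graph <- as.matrix(graph)
  if (!all(dim(embedded) == dim(graph)))
    stop_hc("distance matrices must have matching dimensions")
  iu <- upper.tri(graph)
  if (any(graph[iu] <= 0))
    stop_hc("graph distances must be positive off-diagonal")
  mean(abs(embedded[iu] - graph[iu]) / graph[iu])
}

#' Mean average precision of an embedding
#'
#' For each node a and each of its graph neighbors b, let `R` be the
#' smallest set of nodes nearest to a (in the embedding) that contains b;
#' the precision is the fraction of `R` that are true neighbors of a.
#' Averaging precisions per node over its neighbors and then over nodes
#' gives the mAP. A rank-preserving embedding (every neighbor nearer than
#' every non-neighbor) scores exactly 1. Exact distance ties are broken by a
#' deterministic jitter of `1e-9 * node index` so the measure is defined.
#'
#' @param g a [binary_graph()] or igraph with no isolated nodes.
#' @param embedded symmetric matrix of embedded-space distances.
#' @return scalar in `(0, 1]`.
#' @export
mean_average_precision <- function(g, embedded) {
  bg <- as_binary_graph(g)
  n <- igraph::vcount(bg$graph)
  d <- as.matrix(embedded)
  if (nrow(d) != n) stop_hc("distance matrix does not match the graph")
  adj <- as.matrix(igraph::as_adjacency_matrix(bg$graph, sparse = FALSE)) > 0
  if (any(rowSums(adj) == 0))
    stop_hc("graph has isolated nodes; extract the largest connected ",
            "component first", class = "hypercon_isolated")
  scale <- max(d[upper.tri(d)], 1)
  ap <- vapply(seq_len(n), function(a) {
    others <- setdiff(seq_len(n), a)
    dv <- d[a, others] + 1e-9 * scale * others   # deterministic tie-break
    ord <- others[order(dv)]
    is_nb <- adj[a, ord]
    ranks <- which(is_nb)                        # ranks of neighbors
    mean(seq_along(ranks) / ranks)
  }, numeric(1))
  mean(ap)
}
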