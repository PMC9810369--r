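# Shared fixtures, all built in code at test time.

# small named igraph from an edge list matrix (1-based)
mk_graph <- function(edges, n = max(edges)) {
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::V(g)$name <- sprintf("n%03d", seq_len(igraph::vcount(g)))
  g
}

path_graph <- function(n) mk_graph(cbind(seq_len(n - 1), seq_len(n - 1) + 1))

ring_graph <- function(n) {
  g <- igraph::make_ring(n)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  g
}

complete_graph <- function(n) {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  g
}

# Fisher-Lee circular correlation, rotation-invariant; reflection handled by
# the caller via abs().
circ_cor <- function(a, b) {
  sa <- sin(a - atan2(mean(sin(a)), mean(cos(a))))
  sb <- sin(b - atan2(mean(sin(b)), mean(cos(b))))
  sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
}

# independent brute-force mAP oracle: literal R-set enumeration
map_oracle <- function(adj, d) {
  n <- nrow(adj)
  scale <- max(d[upper.tri(d)], 1)
  aps <- numeric(0)
  for (a in seq_len(n)) {
    nbrs <- which(adj[a, ] > 0)
    if (length(nbrs) == 0) next
    others <- setdiff(seq_len(n), a)
    dv <- d[a, others] + 1e-9 * scale * others
    precs <- numeric(length(nbrs))
    for (bi in seq_along(nbrs)) {
      b <- nbrs[bi]
      # smallest set of nearest-to-a nodes containing b
      db <- dv[match(b, others)]
      R <- others[dv <= db]
      precs[bi] <- length(intersect(nbrs, R)) / length(R)
    }
    aps <- c(aps, mean(precs))
  }
  mean(aps)
}

# ground-truth disc distances for an S1 ground truth restricted to nodes kept
truth_distances <- function(gt, keep) {
  disc <- to_disc(gt$kappa[keep], gt$theta[keep], gt$beta, mu = gt$mu)
  disc_distances(disc)
}
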