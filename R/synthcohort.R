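# Synthetic-data generators: block-correlated multivariate normal series and
# S1 geometric networks with known ground truth, plus control cohorts and
# topological anomaly injection. These emulate the statistical structure of
# ROI-averaged resting-state series and their thresholded graphs; they make no
# attempt to model hemodynamics or scanner noise spectra.

#' Generate block-correlated multivariate normal time series
#'
#' Draws a node x timepoint matrix from a zero-mean multivariate normal whose
#' correlation matrix has `within_r` inside the given blocks and `between_r`
#' everywhere else. Blocks emulate modular functional systems whose members
#' co-fluctuate; after correlation thresholding such matrices yield modular,
#' heavy-tailed graphs.
#'
#' With `within_r = 1` the target matrix is singular but still positive
#' semi-definite: series within a block are exact duplicates (documented
#' perfect-correlation limit).
#'
#' @param n_nodes number of nodes (rows), >= 2.
#' @param n_timepoints number of samples (columns), >= 3.
#' @param block_sizes integer vector summing to `n_nodes`.
#' @param within_r correlation inside blocks, in `[0, 1]`.
#' @param between_r correlation between blocks; the implied matrix must be
#'   positive semi-definite.
#' @param seed integer seed; the draw is deterministic given `seed`.
#' @param node_labels optional node labels.
#' @return a `series_matrix`: list with `values` (node x timepoint matrix),
#'   `node_labels`, `n_timepoints`, and the target correlation matrix
#'   `target_rho`.
#' @export
gen_block_timeseries <- function(n_nodes, n_timepoints, block_sizes,
                                 within_r, between_r = 0, seed = 1L,
                                 node_labels = NULL) {
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 2L)
  n_timepoints <- assert_count(n_timepoints, "n_timepoints", min = 3L)
  assert_scalar_number(within_r, "within_r", lo = 0, hi = 1)
  assert_scalar_number(between_r, "between_r", lo = -1, hi = 1)
  if (sum(block_sizes) != n_nodes)
    stop_hc("block_sizes must sum to n_nodes (",
            sum(block_sizes), " != ", n_nodes, ")",
            class = "hypercon_param_error")

  block_id <- rep(seq_along(block_sizes), block_sizes)
  rho <- matrix(between_r, n_nodes, n_nodes)
  same <- outer(block_id, block_id, "==")
  rho[same] <- within_r
  diag(rho) <- 1

  ev <- eigen(rho, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop_hc("target correlation matrix is not positive semi-definite ",
            "(smallest eigenvalue ", format(min(ev$values), digits = 4), ")",
            class = "hypercon_param_error")
  lam <- pmax(ev$values, 0)
  root <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))   # symmetric sqrt

  values <- with_seed(seed, {
    z <- matrix(stats::rnorm(n_nodes * n_timepoints), n_nodes, n_timepoints)
    root %*% z
  })
  labels <- node_labels %||% sprintf("n%03d", seq_len(n_nodes))
  rownames(values) <- labels
  structure(list(values = values, node_labels = labels,
                 n_timepoints = n_timepoints, target_rho = rho),
            class = "series_matrix")
}

#' @export
print.series_matrix <- function(x, ...) {
  cat(sprintf("<series_matrix> %d nodes x %d timepoints\n",
              nrow(x$values), x$n_timepoints))
  invisible(x)
}

#' Sample power-law hidden degrees for the S1 model
#'
#' Pareto sample with exponent `gamma`, truncated at
#' `kappa_max = n_nodes^(1/(gamma - 1))` (the natural finite-size cutoff that
#' avoids degree condensation), then rescaled so the sample mean equals
#' `mean_degree` — under the standard `mu` normalization the mean-field
#' expected degree of node i is then `kappa_i`.
#'
#' @param n_nodes number of nodes.
#' @param gamma power-law exponent (> 2 for finite mean).
#' @param mean_degree target mean degree.
#' @param seed integer seed.
#' @return numeric vector of hidden degrees.
#' @export
sample_powerlaw_kappa <- function(n_nodes, gamma = 2.7, mean_degree = 10,
                                  seed = 1L) {
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 2L)
  assert_scalar_number(gamma, "gamma", lo = 2, lo_open = TRUE)
  assert_scalar_number(mean_degree, "mean_degree", lo = 0, lo_open = TRUE)
  kappa_max <- n_nodes^(1 / (gamma - 1))
  kappa <- with_seed(seed, {
    u <- stats::runif(n_nodes)
    # inverse CDF of a Pareto(1, gamma - 1) truncated to [1, kappa_max]
    (1 - u * (1 - kappa_max^(1 - gamma)))^(-1 / (gamma - 1))
  })
  kappa * mean_degree / mean(kappa)
}

#' Standard S1 connection-scale normalization
#'
#' `mu = beta * sin(pi / beta) / (2 * pi * mean_degree)`: with hidden degrees
#' rescaled to mean `mean_degree` this ties the mean-field expected degree of
#' node i to `kappa_i`.
#'
#' @param beta inverse temperature (> 1).
#' @param mean_degree target mean degree.
#' @return the scalar `mu`.
#' @export
s1_mu <- function(beta, mean_degree) {
  assert_scalar_number(beta, "beta", lo = 1, lo_open = TRUE)
  assert_scalar_number(mean_degree, "mean_degree", lo = 0, lo_open = TRUE)
  beta * sin(pi / beta) / (2 * pi * mean_degree)
}

#' Convenience constructor for S1 ground truth with power-law hidden degrees
#'
#' @param n_nodes number of nodes.
#' @param gamma power-law exponent of the hidden degrees.
#' @param beta inverse temperature (> 1).
#' @param mean_degree target mean degree.
#' @param seed integer seed (hidden degrees and angles).
#' @return an [s1_ground_truth()] with uniform angles.
#' @export
gen_s1_ground_truth <- function(n_nodes, gamma = 2.7, beta = 2.5,
                                mean_degree = 10, seed = 1L) {
  kappa <- sample_powerlaw_kappa(n_nodes, gamma, mean_degree,
                                 seed = child_seed(seed, 1L))
  theta <- with_seed(child_seed(seed, 2L),
                     stats::runif(n_nodes, 0, 2 * pi))
  s1_ground_truth(kappa, theta, beta, s1_mu(beta, mean_degree))
}

# Connection probabilities for all unordered pairs under the S1 model:
# p = 1 / (1 + chi^beta), chi = R * dtheta / (mu * kappa_i * kappa_j),
# R = N / (2 * pi). Returns a full symmetric matrix.
s1_probability_matrix <- function(gt) {
  n <- gt$n_nodes
  r_circ <- n / (2 * pi)
  dt <- angular_separation(matrix(gt$theta, n, n),
                           matrix(gt$theta, n, n, byrow = TRUE))
  chi <- r_circ * dt / (gt$mu * outer(gt$kappa, gt$kappa))
  p <- 1 / (1 + chi^gt$beta)
  diag(p) <- 0
  p
}

#' Draw a binary graph from the S1 geometric model
#'
#' Connects each unordered pair independently with probability
#' `1 / (1 + chi^beta)` where `chi = R * dtheta / (mu * kappa_i * kappa_j)`
#' and `R = n_nodes / (2 * pi)`. At `chi = 1` the connection probability is
#' exactly 1/2.
#'
#' @param gt an [s1_ground_truth()].
#' @param seed integer seed; deterministic given seed.
#' @return a [binary_graph()] with the ground truth attached as attribute
#'   `ground_truth`.
#' @export
gen_s1_network <- function(gt, seed = 1L) {
  if (!inherits(gt, "s1_ground_truth")) stop_hc("gt must be s1_ground_truth")
  if (gt$n_nodes < 10L)
    stop_hc("need at least 10 nodes", class = "hypercon_param_error")
  if (gt$beta <= 1)
    stop_hc("beta <= 1 (non-clustered regime) is unsupported",
            class = "hypercon_param_error")
  p <- s1_probability_matrix(gt)
  n <- gt$n_nodes
  pr <- upper_pairs(n)
  a <- with_seed(seed, stats::runif(nrow(pr)) < p[pr])
  g <- igraph::graph_from_edgelist(cbind(pr[a, 1L], pr[a, 2L]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  bg <- binary_graph(g)
  attr(bg, "ground_truth") <- gt
  bg
}

#' Generate a control cohort of independent S1 draws
#'
#' Draws `n_subjects` independent networks from the same ground truth, then
#' applies independent edge flips (presence toggles over all node pairs) at
#' rate `edge_noise` to each subject, emulating measurement noise on top of a
#' shared generative geometry.
#'
#' @param gt an [s1_ground_truth()].
#' @param n_subjects cohort size.
#' @param edge_noise per-pair flip probability in `[0, 0.5)`.
#' @param seed integer seed.
#' @return a [synthetic_cohort()] of `binary_graph` subjects.
#' @export
gen_control_cohort <- function(gt, n_subjects, edge_noise = 0, seed = 1L) {
  n_subjects <- assert_count(n_subjects, "n_subjects", min = 1L)
  assert_scalar_number(edge_noise, "edge_noise", lo = 0, hi = 0.5,
                       hi_open = TRUE)
  subjects <- lapply(seq_len(n_subjects), function(s) {
    bg <- gen_s1_network(gt, seed = child_seed(seed, 2L * s))
    if (edge_noise > 0) {
      n <- gt$n_nodes
      pr <- upper_pairs(n)
      adj <- as.matrix(igraph::as_adjacency_matrix(bg$graph, sparse = FALSE))
      flips <- with_seed(child_seed(seed, 2L * s + 1L),
                         stats::runif(nrow(pr)) < edge_noise)
      av <- adj[pr]
      av[flips] <- 1 - av[flips]
      adj[pr] <- av
      adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      igraph::V(g)$name <- igraph::V(bg$graph)$name
      bg <- binary_graph(g)
    }
    bg
  })
  synthetic_cohort(subjects, gt)
}

#' Inject topological anomalies into one cohort subject
#'
#' Perturbs the adjacency of one subject so that the listed node pairs become
#' anomalously distant (`lengthen`) or anomalously close (`shorten`) after
#' re-embedding, while the rest of the cohort is untouched. `lengthen`
#' disconnects each pair and decouples their angular neighborhoods by removing
#' the edges from each endpoint to the other endpoint's neighbors; `shorten`
#' connects each pair and additionally connects each endpoint to the other
#' endpoint's neighbors. The perturbation acts on topology only, so it is
#' visible to the full embedding + detection pipeline.
#'
#' @param cohort a [synthetic_cohort()].
#' @param subject index of the subject to perturb.
#' @param pairs two-column matrix (or list of length-2 vectors) of node
#'   indices.
#' @param mode `"lengthen"` or `"shorten"`.
#' @param seed unused placeholder for interface stability (the rewiring is
#'   deterministic), kept so perturbations are reproducibly logged.
#' @return the cohort with the perturbed subject and an updated
#'   `perturbation_log`.
#' @export
inject_anomaly <- function(cohort, subject, pairs,
                           mode = c("lengthen", "shorten"), seed = 1L) {
  mode <- match.arg(mode)
  if (!inherits(cohort, "synthetic_cohort"))
    stop_hc("cohort must be a synthetic_cohort")
  if (!is.numeric(subject) || length(subject) != 1L ||
      subject < 1 || subject > length(cohort$subjects))
    stop_hc("unknown subject: ", subject, class = "hypercon_id_error")
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || length(pairs) == 0L) return(cohort)
  pairs <- matrix(as.integer(pairs), ncol = 2L)

  bg <- cohort$subjects[[subject]]
  n <- igraph::vcount(bg$graph)
  if (any(pairs < 1L | pairs > n))
    stop_hc("node pair outside node set (n = ", n, ")",
            class = "hypercon_id_error")

  adj <- as.matrix(igraph::as_adjacency_matrix(bg$graph, sparse = FALSE))
  base_adj <- adj  # neighborhoods are taken in the unperturbed graph
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    ni <- which(base_adj[i, ] > 0); nj <- which(base_adj[j, ] > 0)
    if (mode == "lengthen") {
      adj[i, j] <- adj[j, i] <- 0
      adj[i, nj] <- adj[nj, i] <- 0
      adj[j, ni] <- adj[ni, j] <- 0
    } else {
      adj[i, j] <- adj[j, i] <- 1
      adj[i, setdiff(nj, i)] <- adj[setdiff(nj, i), i] <- 1
      adj[j, setdiff(ni, j)] <- adj[setdiff(ni, j), j] <- 1
    }
  }
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- igraph::V(bg$graph)$name
  cohort$subjects[[subject]] <- binary_graph(g, threshold = bg$threshold)
  cohort$perturbation_log <- rbind(
    cohort$perturbation_log,
    data.frame(subject = subject, i = pairs[, 1L], j = pairs[, 2L],
               mode = mode, stringsAsFactors = FALSE))
  cohort
}
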