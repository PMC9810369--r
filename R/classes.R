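#' Binary graph with threshold provenance
#'
#' Light S3 container used throughout the pipeline: an undirected simple
#' [igraph][igraph::igraph-package] graph together with the correlation
#' threshold that produced it (if any) and a logical mask marking members of
#' the largest connected component.
#'
#' @param g an undirected `igraph` object (simple: no loops, no multi-edges).
#' @param threshold correlation threshold used to build the graph, or `NA`.
#'
#' @return an object of class `binary_graph` with elements `graph`,
#'   `threshold` and `lcc_mask` (named logical vector; ties between equal-size
#'   components are broken towards the component containing the smallest node
#'   id, so the mask always marks exactly one component).
#' @export
binary_graph <- function(g, threshold = NA_real_) {
  if (!igraph::is_igraph(g)) stop_hc("g must be an igraph object")
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  if (any(igraph::which_loop(g)) || any(igraph::which_multiple(g)))
    g <- igraph::simplify(g)
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  structure(
    list(graph = g, threshold = threshold, lcc_mask = lcc_mask(g)),
    class = "binary_graph")
}

# Largest-component membership; ties broken by smallest minimum node index.
lcc_mask <- function(g) {
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    first_member <- vapply(best, function(cc) min(which(comp$membership == cc)),
                           integer(1))
    best <- best[which.min(first_member)]
  }
  mask <- comp$membership == best
  names(mask) <- igraph::V(g)$name
  mask
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges, threshold = %s, LCC = %d\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              ifelse(is.na(x$threshold), "none", format(x$threshold)),
              sum(x$lcc_mask)))
  invisible(x)
}

as_binary_graph <- function(x) {
  if (inherits(x, "binary_graph")) return(x)
  if (igraph::is_igraph(x)) return(binary_graph(x))
  stop_hc("expected a binary_graph or igraph object")
}

#' Ground truth for an S1 geometric network
#'
#' Hidden variables of the S1 model: per-node hidden degrees `kappa`
#' (popularity), angles `theta` on the circle (similarity), the inverse
#' temperature `beta` (> 1, clustered regime) controlling clustering
#' strength, and the connection-scale parameter `mu`.
#'
#' @param kappa positive per-node hidden degrees.
#' @param theta per-node angles; reduced modulo `2*pi` into `[0, 2*pi)`.
#' @param beta inverse temperature, must exceed 1.
#' @param mu positive connection-scale parameter.
#' @return an object of class `s1_ground_truth`.
#' @export
s1_ground_truth <- function(kappa, theta, beta, mu) {
  if (length(kappa) != length(theta))
    stop_hc("kappa and theta must have equal length")
  if (any(!is.finite(kappa)) || any(kappa <= 0))
    stop_hc("all kappa must be finite and > 0")
  assert_scalar_number(beta, "beta", lo = 1, lo_open = TRUE)
  assert_scalar_number(mu, "mu", lo = 0, lo_open = TRUE)
  structure(
    list(kappa = as.numeric(kappa), theta = as.numeric(theta %% (2 * pi)),
         beta = beta, mu = mu, n_nodes = length(kappa)),
    class = "s1_ground_truth")
}

#' @export
print.s1_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<s1_ground_truth> N = %d, beta = %.3g, mu = %.3g, <kappa> = %.3g\n",
    x$n_nodes, x$beta, x$mu, mean(x$kappa)))
  invisible(x)
}

#' Synthetic cohort of subjects sharing a node set
#'
#' @param subjects list of `binary_graph` (or series matrices) sharing one
#'   node set.
#' @param ground_truth the generating `s1_ground_truth` (or block spec).
#' @param perturbation_log data frame recording injected perturbations
#'   (subject, node pair, description).
#' @return an object of class `synthetic_cohort`.
#' @export
synthetic_cohort <- function(subjects, ground_truth,
                             perturbation_log = empty_perturbation_log()) {
  structure(list(subjects = subjects, ground_truth = ground_truth,
                 perturbation_log = perturbation_log),
            class = "synthetic_cohort")
}

empty_perturbation_log <- function() {
  data.frame(subject = integer(), i = integer(), j = integer(),
             mode = character(), stringsAsFactors = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d logged perturbations\n",
              length(x$subjects), nrow(x$perturbation_log)))
  invisible(x)
}

#' Hyperbolic disc embedding of a graph
#'
#' Product of the S1/H2 embedding: per-node radial coordinates `r` and angles
#' `theta` on the hyperbolic disc, the inferred hidden degrees, inverse
#' temperature, and the outermost radial coordinate `r_hat` which is the
#' midpoint of the connection-probability sigmoid.
#'
#' @param r nonnegative radial coordinates.
#' @param theta angles, reduced into `[0, 2*pi)`.
#' @param kappa positive hidden degrees.
#' @param beta inverse temperature (> 1).
#' @param mu connection-scale parameter.
#' @param labels node labels.
#' @param loglik Bernoulli log-likelihood of the embedded graph, if known.
#' @return an object of class `hyperbolic_disc`.
#' @export
hyperbolic_disc <- function(r, theta, kappa, beta, mu,
                            labels = as.character(seq_along(r)),
                            loglik = NA_real_) {
  n <- length(r)
  if (length(theta) != n || length(kappa) != n || length(labels) != n)
    stop_hc("r, theta, kappa and labels must have equal length")
  if (any(r < 0)) stop_hc("radial coordinates must be >= 0")
  assert_scalar_number(beta, "beta", lo = 1, lo_open = TRUE)
  structure(
    list(r = as.numeric(r), theta = as.numeric(theta %% (2 * pi)),
         kappa = as.numeric(kappa), beta = beta, mu = mu,
         r_hat = max(r), n_nodes = n, labels = as.character(labels),
         loglik = loglik),
    class = "hyperbolic_disc")
}

#' @export
print.hyperbolic_disc <- function(x, ...) {
  cat(sprintf(
    "<hyperbolic_disc> N = %d, beta = %.3f, R_hat = %.3f, loglik = %.2f\n",
    x$n_nodes, x$beta, x$r_hat, x$loglik))
  invisible(x)
}
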