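# S1/H2 maximum-likelihood hyperbolic-disc embedding, re-implemented in the
# Mercator style: infer the inverse temperature beta by clustering matching,
# hidden degrees by mean-field degree matching, angular coordinates by
# spectral initialization plus likelihood sweeps, then change variables to
# disc polar coordinates.

#' Angular separation of two angles on the circle
#'
#' `pi - |pi - |theta_i - theta_j| mod 2pi|`, in `[0, pi]`. Vectorized.
#'
#' @param theta_i,theta_j angles in radians.
#' @return separation(s) in `[0, pi]`.
#' @export
angular_separation <- function(theta_i, theta_j) {
  pi - abs(pi - abs(theta_i - theta_j) %% (2 * pi))
}

#' Hyperbolic distance between disc points (approximate or exact kernel)
#'
#' Default kernel: the large-distance approximation
#' `r_i + r_j + 2 log(dtheta / 2)` combined smoothly with its
#' coincident-angle floor `|r_i - r_j|` as
#' `log(exp(a) + exp(b))` — the genuine asymptotic form of the hyperbolic
#' law of cosines (`cosh d ~ cosh(r_i - r_j) + sinh r_i sinh r_j
#' (1 - cos dtheta)` splits into exactly these two exponentials), of which
#' the often-quoted hard maximum is the zero-temperature limit. At
#' `dtheta = 0` the kernel equals `|r_i - r_j|` exactly, and it agrees with
#' the exact kernel within 1% whenever the approximation exceeds 10 and
#' `dtheta <= 0.2` (the hard maximum misses that bound near the floor
#' crossover). With `exact = TRUE` the hyperbolic law of cosines
#' `acosh(cosh r_i cosh r_j - sinh r_i sinh r_j cos dtheta)` is used
#' instead. Vectorized over its arguments.
#'
#' @param r_i,r_j nonnegative radial coordinates.
#' @param dtheta angular separation(s) in `[0, pi]`.
#' @param exact use the law-of-cosines kernel.
#' @return nonnegative distance(s).
#' @export
hyperbolic_distance <- function(r_i, r_j, dtheta, exact = FALSE) {
  if (any(r_i < 0) || any(r_j < 0)) stop_hc("radial coordinates must be >= 0")
  if (exact) {
    arg <- cosh(r_i) * cosh(r_j) - sinh(r_i) * sinh(r_j) * cos(dtheta)
    return(acosh(pmax(arg, 1)))
  }
  a <- r_i + r_j + 2 * log(dtheta / 2)
  a[dtheta == 0] <- -Inf
  b <- abs(r_i - r_j)
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  d <- hi + log1p(exp(lo - hi))
  d[is.infinite(hi) & hi < 0] <- 0   # both terms -Inf: coincident points
  d
}

#' Connection probability on the hyperbolic disc
#'
#' `1 / (1 + exp((beta / 2) * (d - r_hat)))`, computed overflow-safely; at
#' `d = r_hat` the probability is exactly 1/2.
#'
#' @param d hyperbolic distance(s).
#' @param beta inverse temperature (> 0).
#' @param r_hat outermost radial coordinate (sigmoid midpoint).
#' @return probability(ies) in `(0, 1)`.
#' @export
connection_probability <- function(d, beta, r_hat) {
  assert_scalar_number(beta, "beta", lo = 0, lo_open = TRUE)
  z <- (beta / 2) * (d - r_hat)
  # stable logistic
  p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

# ---- hidden-degree inference -------------------------------------------

# Mean-field expected degrees under the S1 model for hidden degrees kappa:
# E[k_i] = sum_j pbar_ij with pbar the angular average of 1/(1 + chi^beta).
# With y = mu kappa_i kappa_j / R and X = pi / y:
#   pbar = (y / pi) * I_beta(X),  I_beta(X) = int_0^X du / (1 + u^beta),
# approximated by I_inf - X^(1-beta)/(beta-1) for X >= 2 and by Simpson
# quadrature otherwise.
s1_expected_degrees <- function(kappa, beta, mu, n) {
  r_circ <- n / (2 * pi)
  y <- mu * outer(kappa, kappa) / r_circ
  x <- pi / y
  i_inf <- (pi / beta) / sin(pi / beta)
  iv <- i_inf - pmin(x, Inf)^(1 - beta) / (beta - 1)
  small <- which(x < 2)
  if (length(small)) {
    grid <- seq(0, 1, length.out = 21L)
    simp_w <- c(1, rep(c(4, 2), 9), 4, 1) / 3 / 20
    xs <- x[small]
    f <- vapply(seq_along(xs), function(ii) {
      u <- grid * xs[ii]
      xs[ii] * sum(simp_w / (1 + u^beta))
    }, numeric(1))
    iv[small] <- f
  }
  pbar <- pmin(y * iv / pi, 1)
  diag(pbar) <- 0
  rowSums(pbar)
}

#' Infer hidden degrees by mean-field degree matching
#'
#' Initializes `kappa_i` at the observed degree `k_i` and iterates damped
#' corrections `kappa_i <- max(kappa_i + eta (k_i - E[k_i | kappa, beta]),
#' eps)` with mean-field expected degrees until the largest mismatch drops
#' below `tol` or `max_iter` is reached (non-convergence returns the best
#' iterate with a `converged = FALSE` flag).
#'
#' @param g connected [binary_graph()] or igraph.
#' @param beta inverse temperature (> 1).
#' @param tol maximum allowed `|k_i - E[k_i]|`.
#' @param max_iter iteration cap.
#' @param eta damping factor of the additive correction.
#' @return numeric vector of hidden degrees with attributes `converged`,
#'   `mu`, `max_mismatch`.
#' @export
infer_kappa <- function(g, beta, tol = 0.2, max_iter = 500L, eta = 0.3) {
  assert_scalar_number(beta, "beta", lo = 1, lo_open = TRUE)
  bg <- as_binary_graph(g)
  k <- igraph::degree(bg$graph)
  n <- length(k)
  mu <- s1_mu(beta, mean(k))
  kap <- pmax(k, 1e-3)
  best <- kap; best_mis <- Inf
  for (it in seq_len(max_iter)) {
    ek <- s1_expected_degrees(kap, beta, mu, n)
    mis <- max(abs(k - ek))
    if (mis < best_mis) { best <- kap; best_mis <- mis }
    if (mis < tol) break
    kap <- pmax(kap + eta * (k - ek), 1e-3)
  }
  out <- best
  names(out) <- igraph::V(bg$graph)$name
  attr(out, "converged") <- best_mis < tol
  attr(out, "mu") <- mu
  attr(out, "max_mismatch") <- best_mis
  out
}

# ---- inverse-temperature inference -------------------------------------

# Mean local clustering of synthetic S1 draws at the given parameters.
s1_synthetic_clustering <- function(kappa, beta, mu, seed, n_draws = 2L) {
  n <- length(kappa)
  gt_like <- list(kappa = kappa, beta = beta, mu = mu, n_nodes = n)
  cs <- vapply(seq_len(n_draws), function(d) {
    theta <- with_seed(child_seed(seed, 7L * d),
                       stats::runif(n, 0, 2 * pi))
    gt <- s1_ground_truth(kappa, theta, beta, mu)
    bg <- gen_s1_network(gt, seed = child_seed(seed, 7L * d + 1L))
    mean_local_clustering(bg)
  }, numeric(1))
  mean(cs)
}

mean_local_clustering <- function(bg) {
  ct <- igraph::transitivity(bg$graph, type = "local", isolates = "NaN")
  mean(ct, na.rm = TRUE)
}

#' Infer the inverse temperature by clustering matching
#'
#' Bisection on `beta` in `(1, 25]`: for each candidate, hidden degrees are
#' re-fitted (coarsely), synthetic S1 networks are drawn with uniform angles,
#' and their mean local clustering coefficient is compared with the observed
#' one — clustering increases monotonically with `beta`. If no `beta` in
#' range matches within `tol`, the nearer boundary is returned with a
#' `boundary = TRUE` attribute and a warning.
#'
#' @param g connected [binary_graph()] or igraph with mean degree >= 2.
#' @param tol clustering-coefficient matching tolerance.
#' @param seed integer seed (synthetic draws); the result is deterministic
#'   given seed and input.
#' @param beta_range search interval.
#' @param n_draws synthetic draws averaged per bisection candidate.
#' @return scalar `beta` estimate with attribute `boundary`.
#' @export
infer_beta <- function(g, tol = 0.003, seed = 1L, beta_range = c(1.05, 25),
                       n_draws = 4L) {
  bg <- as_binary_graph(g)
  k <- igraph::degree(bg$graph)
  if (mean(k) < 2)
    stop_hc("mean degree < 2: too sparse for beta inference",
            class = "hypercon_param_error")
  c_obs <- mean_local_clustering(bg)
  lo <- beta_range[1L]; hi <- beta_range[2L]
  cl_at <- function(b) {
    kap <- infer_kappa(bg, b, tol = 0.5, max_iter = 100L)
    s1_synthetic_clustering(kap, b, attr(kap, "mu"), seed = seed,
                            n_draws = n_draws)
  }
  c_lo <- cl_at(lo); c_hi <- cl_at(hi)
  boundary <- FALSE
  if (c_obs <= c_lo + tol && c_obs < c_lo) {
    warning("observed clustering below the clustered regime; ",
            "returning lower boundary beta")
    res <- lo; boundary <- TRUE
  } else if (c_obs >= c_hi) {
    warning("observed clustering above the searchable range; ",
            "returning upper boundary beta")
    res <- hi; boundary <- TRUE
  } else {
    res <- NA_real_
    for (it in seq_len(40L)) {
      mid <- (lo + hi) / 2
      c_mid <- cl_at(mid)
      if (abs(c_mid - c_obs) < tol) { res <- mid; break }
      if (c_mid < c_obs) lo <- mid else hi <- mid
      if (hi - lo < 0.01) break
    }
    if (is.na(res)) res <- (lo + hi) / 2
  }
  attr(res, "boundary") <- boundary
  res
}

# ---- angular-coordinate inference --------------------------------------

total_s1_loglik <- function(adj, theta, kappa, beta, mu, n) {
  total_loglik_cpp(theta, storage_int(adj), kappa, beta, mu, n / (2 * pi))
}

# spectral initialization: leading nontrivial eigenpair of the normalized
# adjacency, angles from the two-argument arctangent. `alpha` down-weights
# edges between high-degree nodes (w_ij = a_ij / (k_i k_j)^alpha): hub-hub
# edges carry little similarity information in the S1 model, but how much to
# discount them depends on the realized hub structure, so several values are
# tried and the sweeps pick the best basin by likelihood.
spectral_angles <- function(adj, alpha = 0) {
  k <- pmax(rowSums(adj), 1)
  w <- if (alpha == 0) adj else adj / outer(k, k)^alpha
  dg <- pmax(rowSums(w), 1e-12)
  a_norm <- w / sqrt(outer(dg, dg))
  ev <- eigen(a_norm, symmetric = TRUE)
  atan2(ev$vectors[, 3L], ev$vectors[, 2L]) %% (2 * pi)
}

# one full likelihood sweep over the nodes in the given order (compiled
# kernel): each node's angle is re-optimized over a coarse global grid plus
# a fine local grid around the coarse winner, and a move is accepted only if
# it beats the current angle, so a sweep never decreases the likelihood.
sweep_angles_once <- function(theta, adj, kappa, beta, mu, r_circ, ord,
                              cand_base, gap, n_fine = 17L) {
  sweep_angles_cpp(theta, storage_int(adj), kappa, beta, mu, r_circ,
                   as.integer(ord), cand_base, gap, as.integer(n_fine))
}

storage_int <- function(m) {
  storage.mode(m) <- "integer"
  m
}

#' Infer angular coordinates by maximum likelihood
#'
#' Multi-start spectral initialization followed by likelihood sweeps. Three
#' initial layouts are produced from the leading nontrivial eigenpair of the
#' normalized adjacency with hub-hub edges discounted at rates
#' `alpha = 0, 0.5, 1` (hub-hub edges carry little similarity information,
#' but the right discount depends on the realized hub structure). Each start
#' is refined by node sweeps — the first in decreasing degree order, since
#' hub placement anchors the rest, the others in seeded random order — until
#' a full pass improves the log-likelihood by less than `1e-4` (or `passes`
#' passes); the best refined layout by Bernoulli log-likelihood is returned.
#' In each sweep a node's angle is re-optimized over `n_candidates`
#' equispaced candidates plus golden-section polish, holding all other
#' angles fixed, so the total log-likelihood never decreases across
#' accepted moves.
#'
#' @param g connected [binary_graph()] or igraph.
#' @param kappa hidden degrees (see [infer_kappa()]).
#' @param beta inverse temperature.
#' @param passes maximum number of sweep passes per initialization.
#' @param seed integer seed (sweep order); deterministic given seed.
#' @param mu connection-scale parameter; defaults to the standard
#'   normalization at the observed mean degree.
#' @param n_candidates angular grid size per node update.
#' @return numeric vector of angles in `[0, 2pi)` with attribute `loglik`.
#' @export
infer_angles <- function(g, kappa, beta, passes = 16L, seed = 1L, mu = NULL,
                         n_candidates = 72L) {
  bg <- as_binary_graph(g)
  adj <- as.matrix(igraph::as_adjacency_matrix(bg$graph, sparse = FALSE))
  n <- nrow(adj)
  if (!all(lcc_mask(bg$graph))) stop_hc("graph must be connected",
                                        class = "hypercon_disconnected")
  if (length(kappa) != n) stop_hc("kappa length must match node count")
  mu <- mu %||% s1_mu(beta, mean(rowSums(adj)))
  r_circ <- n / (2 * pi)
  cand_base <- seq(0, 2 * pi,
                   length.out = n_candidates + 1L)[-(n_candidates + 1L)]
  gap <- 2 * pi / n_candidates
  passes <- assert_count(passes, "passes", min = 1L)

  deg_order <- order(rowSums(adj), decreasing = TRUE)
  refined <- lapply(seq_along(c(0, 0.5, 1)), function(si) {
    alpha <- c(0, 0.5, 1)[si]
    th <- spectral_angles(adj, alpha)
    ll <- total_s1_loglik(adj, th, kappa, beta, mu, n)
    for (p in seq_len(passes)) {
      ord <- if (p == 1L) deg_order else
        with_seed(child_seed(seed, 100L * si + p), sample.int(n))
      th <- sweep_angles_once(th, adj, kappa, beta, mu, r_circ, ord,
                              cand_base, gap)
      new_ll <- total_s1_loglik(adj, th, kappa, beta, mu, n)
      gain <- new_ll - ll
      ll <- new_ll
      if (gain < 1e-4) break
    }
    list(theta = th, ll = ll)
  })
  best <- refined[[which.max(vapply(refined, `[[`, numeric(1), "ll"))]]
  theta <- best$theta
  attr(theta, "loglik") <- best$ll
  theta
}

# ---- disc construction --------------------------------------------------

#' Map S1 coordinates to hyperbolic-disc polar coordinates
#'
#' Radial map anchored at the observed minimum hidden degree:
#' `r_i = R_disc - 2 log(kappa_i / kappa_min)` with
#' `R_disc = 2 log(n_nodes / (mu pi kappa_min^2))`. Nodes with larger hidden
#' degree sit closer to the disc center; doubling a node's `kappa` decreases
#' its radius by exactly `2 log 2`. Radial coordinates are floored at 0 (the
#' floor only binds for hidden degrees far above the disc scale).
#'
#' @param kappa positive hidden degrees.
#' @param theta angles.
#' @param beta inverse temperature.
#' @param n_nodes node count.
#' @param mu connection-scale parameter; defaults to the standard
#'   normalization with mean degree `mean(kappa)`.
#' @param labels node labels.
#' @param loglik optional log-likelihood to record.
#' @return a [hyperbolic_disc()].
#' @export
to_disc <- function(kappa, theta, beta, n_nodes = length(kappa), mu = NULL,
                    labels = names(kappa) %||% as.character(seq_along(kappa)),
                    loglik = NA_real_) {
  if (any(kappa <= 0)) stop_hc("all kappa must be > 0")
  mu <- mu %||% s1_mu(beta, mean(kappa))
  kmin <- min(kappa)
  r_disc <- 2 * log(n_nodes / (mu * pi * kmin^2))
  r <- pmax(r_disc - 2 * log(kappa / kmin), 0)
  hyperbolic_disc(r, theta, kappa, beta, mu, labels = labels,
                  loglik = loglik)
}

#' Full S1/H2 maximum-likelihood embedding of a connected graph
#'
#' Composition `infer_beta` -> `infer_kappa` -> `infer_angles` -> `to_disc`.
#' Deterministic given `seed`.
#'
#' @param g connected [binary_graph()] or igraph (>= 10 nodes; use the
#'   largest connected component).
#' @param seed integer seed.
#' @param beta optional known inverse temperature; skips `infer_beta`.
#' @param passes sweep passes for [infer_angles()].
#' @return a [hyperbolic_disc()] with the final log-likelihood recorded.
#' @export
embed_s1h2 <- function(g, seed = 1L, beta = NULL, passes = 16L) {
  bg <- as_binary_graph(g)
  if (igraph::vcount(bg$graph) < 10L)
    stop_hc("need at least 10 nodes", class = "hypercon_param_error")
  if (!all(lcc_mask(bg$graph)))
    stop_hc("graph must be connected; extract the largest component first",
            class = "hypercon_disconnected")
  if (is.null(beta))
    beta <- as.numeric(infer_beta(bg, seed = child_seed(seed, 1L)))
  kappa <- infer_kappa(bg, beta)
  mu <- attr(kappa, "mu")
  theta <- infer_angles(bg, as.numeric(kappa), beta, passes = passes,
                        seed = child_seed(seed, 2L), mu = mu)
  to_disc(as.numeric(kappa), as.numeric(theta), beta,
          n_nodes = length(kappa), mu = mu,
          labels = igraph::V(bg$graph)$name,
          loglik = attr(theta, "loglik"))
}

#' Pairwise hyperbolic distances of a disc
#'
#' @param disc a [hyperbolic_disc()].
#' @param exact use the law-of-cosines kernel instead of the approximation.
#' @return symmetric distance matrix (class `dist_matrix`, with the source
#'   disc's `r_hat` attached as attribute).
#' @export
disc_distances <- function(disc, exact = FALSE) {
  n <- disc$n_nodes
  dt <- angular_separation(matrix(disc$theta, n, n),
                           matrix(disc$theta, n, n, byrow = TRUE))
  d <- hyperbolic_distance(matrix(disc$r, n, n),
                           matrix(disc$r, n, n, byrow = TRUE), dt,
                           exact = exact)
  diag(d) <- 0
  dimnames(d) <- list(disc$labels, disc$labels)
  attr(d, "r_hat") <- disc$r_hat
  d
}

#' Rotate (and optionally reflect) a disc so a reference set points to 0
#'
#' Applies the optional reflection `theta -> -theta` first, then rotates all
#' angles by minus the circular mean of the reference nodes' angles, so that
#' the reference set's circular mean becomes 0. Radial coordinates are
#' untouched, so all pairwise distances are preserved exactly.
#'
#' @param disc a [hyperbolic_disc()].
#' @param reference_nodes node indices or labels of the reference set.
#' @param reflect apply the reflection before rotating.
#' @return the aligned [hyperbolic_disc()].
#' @export
align_disc <- function(disc, reference_nodes, reflect = FALSE) {
  if (length(reference_nodes) == 0L) stop_hc("reference set is empty")
  idx <- if (is.character(reference_nodes))
    match(reference_nodes, disc$labels) else as.integer(reference_nodes)
  if (anyNA(idx) || any(idx < 1L | idx > disc$n_nodes))
    stop_hc("unknown reference node(s)", class = "hypercon_id_error")
  theta <- disc$theta
  if (reflect) theta <- (-theta) %% (2 * pi)
  s <- mean(sin(theta[idx])); c <- mean(cos(theta[idx]))
  if (sqrt(s^2 + c^2) < 1e-9)
    stop_hc("circular mean of the reference set is undefined ",
            "(resultant length < 1e-9)", class = "hypercon_degenerate_mean")
  disc$theta <- (theta - atan2(s, c)) %% (2 * pi)
  disc
}
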