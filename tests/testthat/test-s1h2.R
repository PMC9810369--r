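test_that("angular_separation handles wrap-around and identity", {
  expect_equal(angular_separation(0, pi), pi)
  expect_equal(angular_separation(0.1, 2 * pi - 0.1), 0.2)
  expect_equal(angular_separation(1.0, 1.0), 0)
  # symmetry and range over random pairs
  set.seed(1)
  a <- runif(200, -10, 10); b <- runif(200, -10, 10)
  expect_equal(angular_separation(a, b), angular_separation(b, a))
  expect_true(all(angular_separation(a, b) >= 0 &
                    angular_separation(a, b) <= pi))
})

test_that("hyperbolic_distance kernels: limits and law-of-cosines oracle", {
  expect_equal(hyperbolic_distance(10, 10, 2), 20.0)
  expect_equal(hyperbolic_distance(10, 10, 0), 0.0)
  expect_equal(hyperbolic_distance(12, 15, 0), 3.0)
  # exact kernel against the closed form
  oracle <- acosh(cosh(12) * cosh(15) - sinh(12) * sinh(15) * cos(0.05))
  expect_equal(hyperbolic_distance(12, 15, 0.05, exact = TRUE), oracle,
               tolerance = 1e-12)
  # approximation vs exact within 1% in the stated regime
  set.seed(2)
  r1 <- runif(100, 6, 16); r2 <- runif(100, 6, 16)
  dt <- runif(100, 0.01, 0.2)
  appr <- hyperbolic_distance(r1, r2, dt)
  ex <- hyperbolic_distance(r1, r2, dt, exact = TRUE)
  reg <- r1 + r2 + 2 * log(dt / 2) > 10
  expect_true(any(reg))
  expect_lt(max(abs(appr[reg] - ex[reg]) / ex[reg]), 0.01)
})

test_that("connection_probability: midpoint, saturation, inversion", {
  expect_equal(connection_probability(12, 2.5, 12), 0.5)
  expect_lt(connection_probability(1e6, 2.5, 12), 1e-10)
  expect_gt(connection_probability(-1e6, 2.5, 12), 1 - 1e-10)
  # algebraic inversion: p = 1/4 at d = r_hat + (2/beta) log 3
  beta <- 3.2; rh <- 10
  expect_equal(connection_probability(rh + 2 / beta * log(3), beta, rh),
               0.25, tolerance = 1e-12)
  # strictly decreasing in d
  d <- seq(0, 30, by = 0.5)
  expect_true(all(diff(connection_probability(d, 2, 15)) < 0))
})

test_that("infer_kappa: symmetry on regular graphs, monotone in degree,
           recovery on S1 draws", {
  ring <- igraph::make_lattice(c(20), nei = 3, periodic = TRUE)
  kap <- infer_kappa(ring, beta = 2.5)
  expect_lt(diff(range(kap)) / mean(kap), 0.01)

  gt <- gen_s1_ground_truth(200, seed = 31)
  bg <- gen_s1_network(gt, seed = 31)
  lc <- largest_component(bg)$graph
  kap2 <- infer_kappa(lc, beta = 2.5)
  k <- igraph::degree(lc$graph)
  expect_gte(cor(as.numeric(kap2), k, method = "spearman"), 0.99)
  keep <- match(igraph::V(lc$graph)$name, sprintf("n%03d", seq_len(200)))
  expect_gte(cor(as.numeric(kap2), gt$kappa[keep]), 0.9)
})

test_that("infer_beta recovers the generative value and is deterministic", {
  gt <- gen_s1_ground_truth(300, gamma = 2.7, beta = 2.5, mean_degree = 10,
                            seed = 17)
  bg <- gen_s1_network(gt, seed = 17)
  lc <- largest_component(bg)$graph
  b1 <- infer_beta(lc, seed = 4)
  b2 <- infer_beta(lc, seed = 4)
  expect_identical(b1, b2)
  expect_gte(as.numeric(b1), 2.0)
  expect_lte(as.numeric(b1), 3.0)
})

test_that("infer_beta pins near-zero-clustering graphs at the boundary", {
  g <- with(list(), {
    set.seed(9)
    igraph::sample_gnp(300, 10 / 299)
  })
  g <- largest_component(g)$graph
  expect_warning(b <- infer_beta(g, seed = 2), "boundary|clustering")
  expect_true(attr(b, "boundary"))
})

test_that("to_disc radial map: anchor, doubling rule, degree ordering", {
  # large nominal n_nodes keeps the disc radius away from the r >= 0 floor
  kap <- c(2, 4, 8, 2)
  disc <- to_disc(kap, c(0, 1, 2, 3), beta = 2.5, n_nodes = 400)
  r_disc <- 2 * log(400 / (disc$mu * pi * min(kap)^2))
  expect_equal(disc$r[1], r_disc)               # kappa_min node outermost
  expect_equal(disc$r[1] - disc$r[2], 2 * log(2))
  expect_equal(disc$r[2] - disc$r[3], 2 * log(2))
  expect_equal(disc$r_hat, max(disc$r))

  gt <- gen_s1_ground_truth(200, seed = 13)
  bg <- gen_s1_network(gt, seed = 13)
  lc <- largest_component(bg)$graph
  disc2 <- embed_s1h2(lc, seed = 13, beta = 2.5, passes = 4)
  k <- igraph::degree(lc$graph)
  expect_lte(cor(k, disc2$r, method = "spearman"), -0.9)
})

test_that("align_disc rotates the reference mean to zero and is an isometry", {
  gt <- gen_s1_ground_truth(40, seed = 3)
  disc <- to_disc(gt$kappa, gt$theta, gt$beta, mu = gt$mu)
  refs <- c(3, 7, 11, 20)
  ald <- align_disc(disc, refs)
  m <- atan2(mean(sin(ald$theta[refs])), mean(cos(ald$theta[refs])))
  expect_lt(abs(m), 1e-9)
  expect_lt(max(abs(disc_distances(ald) - disc_distances(disc))), 1e-12)
  # idempotent
  expect_equal(align_disc(ald, refs)$theta, ald$theta, tolerance = 1e-12)
  # reflection preserves distances too
  refl <- align_disc(disc, refs, reflect = TRUE)
  expect_lt(max(abs(disc_distances(refl) - disc_distances(disc))), 1e-12)
  # degenerate reference set
  disc0 <- to_disc(c(1, 1, 2), c(0, pi, 1), 2.5, n_nodes = 3)
  expect_error(align_disc(disc0, c(1, 2)),
               class = "hypercon_degenerate_mean")
})

test_that("connection_probability . hyperbolic_distance is invariant under
           disc rotation and reflection", {
  gt <- gen_s1_ground_truth(30, seed = 19)
  disc <- to_disc(gt$kappa, gt$theta, gt$beta, mu = gt$mu)
  p0 <- connection_probability(disc_distances(disc), disc$beta, disc$r_hat)
  rot <- disc; rot$theta <- (rot$theta + 1.234) %% (2 * pi)
  refl <- disc; refl$theta <- (-refl$theta) %% (2 * pi)
  for (other in list(rot, refl)) {
    p1 <- connection_probability(disc_distances(other), disc$beta,
                                 disc$r_hat)
    expect_equal(p1, p0, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("embed_s1h2 is deterministic, demands connectivity and >= 10 nodes,
           and relabeling commutes with embedding", {
  gt <- gen_s1_ground_truth(60, seed = 23)
  bg <- gen_s1_network(gt, seed = 23)
  lc <- largest_component(bg)$graph
  d1 <- embed_s1h2(lc, seed = 5, beta = 2.5, passes = 3)
  d2 <- embed_s1h2(lc, seed = 5, beta = 2.5, passes = 3)
  expect_identical(d1, d2)
  expect_error(embed_s1h2(mk_graph(c(1,2, 3,4), n = 12), seed = 1),
               class = "hypercon_disconnected")
  expect_error(embed_s1h2(path_graph(5), seed = 1),
               class = "hypercon_param_error")

  # node relabeling: same seed => permuted coordinates
  n <- igraph::vcount(lc$graph)
  perm <- with(list(), { set.seed(77); sample.int(n) })
  gp <- igraph::permute(lc$graph, perm)
  dp <- embed_s1h2(gp, seed = 5, beta = 2.5, passes = 3)
  # distances between the same labelled nodes must match closely (sweep
  # order differs, so allow loose agreement on a rank basis)
  m1 <- disc_distances(d1); m2 <- disc_distances(dp)
  common <- intersect(rownames(m1), rownames(m2))
  ui <- upper.tri(m1[common, common])
  expect_gte(cor(m1[common, common][ui], m2[common, common][ui],
                 method = "spearman"), 0.85)
})

test_that("connected pairs sit closer on the disc than unconnected pairs", {
  gt <- gen_s1_ground_truth(150, seed = 41)
  bg <- gen_s1_network(gt, seed = 41)
  lc <- largest_component(bg)$graph
  disc <- embed_s1h2(lc, seed = 2, beta = 2.5, passes = 6)
  d <- disc_distances(disc)
  adj <- igraph::as_adjacency_matrix(lc$graph, sparse = FALSE)
  ui <- upper.tri(d)
  expect_lt(mean(d[ui][adj[ui] > 0]), mean(d[ui][adj[ui] == 0]))
})
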