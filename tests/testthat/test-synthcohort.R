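test_that("gen_block_timeseries hits the target correlations", {
  ts <- gen_block_timeseries(4, 10000, c(2, 2), within_r = 0.8,
                             between_r = 0.0, seed = 1)
  rho <- pearson_matrix(ts)
  expect_equal(rho[1, 2], 0.8, tolerance = 0.02 / 0.8)
  expect_equal(rho[3, 4], 0.8, tolerance = 0.02 / 0.8)
  expect_lt(abs(rho[1, 3]), 0.05)

  # independent pair: off-diagonal within 3 standard errors of 0
  ts2 <- gen_block_timeseries(2, 100, c(2), within_r = 0, seed = 7)
  expect_lt(abs(pearson_matrix(ts2)[1, 2]), 3 / sqrt(100))

  # perfect-correlation limit: exact duplication of the block series
  ts3 <- gen_block_timeseries(3, 50, c(3), within_r = 1, seed = 2)
  expect_equal(ts3$values[1, ], ts3$values[2, ], tolerance = 1e-6,
               ignore_attr = TRUE)

  # determinism
  expect_identical(gen_block_timeseries(6, 50, c(3, 3), 0.5, 0.1, seed = 9),
                   gen_block_timeseries(6, 50, c(3, 3), 0.5, 0.1, seed = 9))
})

test_that("gen_block_timeseries validates block sizes and PSD", {
  expect_error(gen_block_timeseries(5, 100, c(2, 2), 0.5),
               class = "hypercon_param_error")
  # strongly negative between-block correlation with many blocks is non-PSD
  err <- expect_error(
    gen_block_timeseries(6, 100, c(2, 2, 2), 0.9, -0.9),
    class = "hypercon_param_error")
  expect_match(conditionMessage(err), "eigenvalue")
})

test_that("generated correlation targets are symmetric with unit diagonal and
           sample correlations converge at O(1/sqrt(T))", {
  ts <- gen_block_timeseries(6, 10000, c(3, 3), 0.6, 0.2, seed = 21)
  expect_equal(ts$target_rho, t(ts$target_rho))
  expect_equal(diag(ts$target_rho), rep(1, 6))
  rho <- pearson_matrix(ts)
  expect_lt(max(abs(rho - ts$target_rho)), 0.03)
})

test_that("S1 connection probability is 1/2 at chi = 1 and follows the
           kernel in binned frequency", {
  # chi = 1 symmetry point: same-kappa pair at separation mu*k^2/R
  gt <- s1_ground_truth(kappa = c(5, 5), theta = c(0, 0), beta = 10, mu = 0.02)
  # direct kernel evaluation through the probability matrix machinery
  n <- 2; r_circ <- n / (2 * pi)
  dtheta <- gt$mu * 25 / r_circ
  gt2 <- s1_ground_truth(kappa = c(5, 5), theta = c(0, dtheta), beta = 10,
                         mu = 0.02)
  p <- hypercon:::s1_probability_matrix(gt2)
  expect_equal(p[1, 2], 0.5, tolerance = 1e-12)

  # binned connection frequency reproduces 1/(1 + chi^10) at N=100
  gt3 <- gen_s1_ground_truth(100, gamma = 2.7, beta = 10, mean_degree = 10,
                             seed = 4)
  gt3$kappa[] <- 10     # all kappa equal
  gt3 <- s1_ground_truth(gt3$kappa, gt3$theta, 10, s1_mu(10, 10))
  pmat <- hypercon:::s1_probability_matrix(gt3)
  pr <- hypercon:::upper_pairs(100)
  emp <- vapply(1:30, function(s) {
    bg <- gen_s1_network(gt3, seed = s)
    adj <- igraph::as_adjacency_matrix(bg$graph, sparse = FALSE)
    adj[pr]
  }, numeric(nrow(pr)))
  pexp <- pmat[pr]
  bins <- cut(pexp, c(0, 0.25, 0.5, 0.75, 1), include.lowest = TRUE)
  for (b in levels(bins)) {
    sel <- bins == b
    if (!any(sel)) next
    n_draws <- sum(sel) * 30
    se <- sqrt(mean(pexp[sel]) * (1 - mean(pexp[sel])) / n_draws)
    expect_lt(abs(mean(emp[sel, ]) - mean(pexp[sel])), 4 * se + 1e-3)
  }
})

test_that("realized mean degree matches the target within 10%", {
  md <- vapply(1:20, function(s) {
    gt <- gen_s1_ground_truth(500, gamma = 2.7, beta = 2.5, mean_degree = 10,
                              seed = s)
    bg <- gen_s1_network(gt, seed = s + 1000)
    mean(igraph::degree(bg$graph))
  }, numeric(1))
  expect_lt(abs(mean(md) - 10) / 10, 0.1)
})

test_that("S1 generation commutes with node relabeling under matched seeds", {
  gt <- gen_s1_ground_truth(40, seed = 5)
  perm <- with(list(), { set.seed(99); sample.int(40) })
  gt_p <- s1_ground_truth(gt$kappa[perm], gt$theta[perm], gt$beta, gt$mu)
  p1 <- hypercon:::s1_probability_matrix(gt)
  p2 <- hypercon:::s1_probability_matrix(gt_p)
  expect_equal(p2, p1[perm, perm], tolerance = 1e-12)
})

test_that("S1 draws with power-law kappa pass the scale-free check in >= 80%
           of seeds", {
  pass <- vapply(1:10, function(s) {
    gt <- gen_s1_ground_truth(500, gamma = 2.7, beta = 2.5, mean_degree = 10,
                              seed = s)
    bg <- gen_s1_network(gt, seed = s + 500)
    scale_free_check(igraph::degree(bg$graph), gof_reps = 30,
                     seed = s)$passes
  }, logical(1))
  expect_gte(mean(pass), 0.8)
})

test_that("gen_control_cohort: determinism, size, and flip-noise level", {
  gt <- gen_s1_ground_truth(200, seed = 8)
  c1 <- gen_control_cohort(gt, 2, edge_noise = 0, seed = 3)
  c2 <- gen_control_cohort(gt, 2, edge_noise = 0, seed = 3)
  expect_identical(igraph::as_edgelist(c1$subjects[[1]]$graph),
                   igraph::as_edgelist(c2$subjects[[1]]$graph))
  expect_length(gen_control_cohort(gt, 5, seed = 1)$subjects, 5)

  # Hamming distance to the noise-free draw ~ Binomial(C(200,2), 0.05)
  noisy <- gen_control_cohort(gt, 3, edge_noise = 0.05, seed = 3)
  n_pairs <- choose(200, 2)
  hd <- vapply(1:3, function(s) {
    a0 <- igraph::as_adjacency_matrix(c1_sub <- gen_s1_network(
      gt, seed = hypercon:::child_seed(3L, 2L * s))$graph, sparse = FALSE)
    a1 <- igraph::as_adjacency_matrix(noisy$subjects[[s]]$graph,
                                      sparse = FALSE)
    sum(a0 != a1) / 2
  }, numeric(1))
  expected <- 0.05 * n_pairs
  se <- sqrt(n_pairs * 0.05 * 0.95)
  expect_true(all(abs(hd - expected) < 4 * se))
})

test_that("inject_anomaly perturbs topology as documented and logs it", {
  gt <- gen_s1_ground_truth(60, seed = 2)
  coh <- gen_control_cohort(gt, 3, seed = 2)
  # empty pair list: unchanged
  expect_identical(inject_anomaly(coh, 1, matrix(numeric(0), ncol = 2),
                                  "lengthen"),
                   coh)
  # pick an edge present in subject 2
  el <- igraph::as_edgelist(coh$subjects[[2]]$graph, names = FALSE)
  pair <- el[1, , drop = FALSE]
  pert <- inject_anomaly(coh, 2, pair, "lengthen")
  a <- igraph::as_adjacency_matrix(pert$subjects[[2]]$graph, sparse = FALSE)
  expect_equal(a[pair[1], pair[2]], 0)
  expect_equal(nrow(pert$perturbation_log), 1)
  expect_equal(pert$perturbation_log$mode, "lengthen")
  # shorten connects the pair and its neighborhood
  far <- which(a[10, ] == 0 & seq_len(60) != 10)[1]
  pert2 <- inject_anomaly(pert, 2, cbind(10, far), "shorten")
  a2 <- igraph::as_adjacency_matrix(pert2$subjects[[2]]$graph, sparse = FALSE)
  expect_equal(a2[10, far], 1)
  # other subjects untouched
  expect_identical(igraph::as_edgelist(pert2$subjects[[1]]$graph),
                   igraph::as_edgelist(coh$subjects[[1]]$graph))
  # unknown ids rejected
  expect_error(inject_anomaly(coh, 99, pair, "lengthen"),
               class = "hypercon_id_error")
  expect_error(inject_anomaly(coh, 1, cbind(1, 900), "lengthen"),
               class = "hypercon_id_error")
})
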