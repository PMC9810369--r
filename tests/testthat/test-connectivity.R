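test_that("sample_variance matches hand-computed values and rejects n < 2", {
  expect_equal(sample_variance(c(1, 2, 3)), 1.0)
  expect_equal(sample_variance(c(5, 5, 5, 5)), 0.0)
  expect_equal(sample_variance(c(0, 2)), 2.0)
  expect_error(sample_variance(3), class = "hypercon_param_error")
})

test_that("pearson_matrix recovers exact correlations and flags constants", {
  m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  rho <- pearson_matrix(m)
  expect_equal(rho["a", "b"], 1.0)
  expect_equal(rho["a", "c"], -1.0)
  expect_equal(diag(rho), c(a = 1, b = 1, c = 1))

  m2 <- rbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4))
  expect_equal(pearson_matrix(m2)["x", "y"], 0.8)

  m3 <- rbind(a = c(1, 2, 3), flat = c(7, 7, 7))
  err <- expect_error(pearson_matrix(m3), class = "hypercon_constant_row")
  expect_match(conditionMessage(err), "flat")
})

test_that("pearson_matrix is invariant to positive affine maps, flips sign
           under negative slope", {
  set.seed(42)
  m <- matrix(rnorm(5 * 60), 5, 60)
  base <- pearson_matrix(m)
  m2 <- m; m2[2, ] <- 3.7 * m[2, ] + 11
  expect_equal(pearson_matrix(m2), base, tolerance = 1e-12,
               ignore_attr = TRUE)
  m3 <- m; m3[2, ] <- -2 * m[2, ] + 1
  flipped <- pearson_matrix(m3)
  expect_equal(flipped[2, -2], -base[2, -2], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("threshold_graph uses strict |rho| > tau and records provenance", {
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- 0.5
  rho[1, 3] <- rho[3, 1] <- -0.45
  rho[2, 3] <- rho[3, 2] <- 0.2
  bg <- threshold_graph(rho, 0.4, use_abs = TRUE)
  el <- igraph::as_edgelist(bg$graph, names = FALSE)
  expect_equal(el[order(el[, 1]), , drop = FALSE],
               rbind(c(1, 2), c(1, 3)))
  expect_equal(bg$threshold, 0.4)
  # signed mode drops the negative edge
  bg2 <- threshold_graph(rho, 0.4, use_abs = FALSE)
  expect_equal(igraph::ecount(bg2$graph), 1)
  # extreme thresholds
  expect_equal(igraph::ecount(threshold_graph(rho, 1.0)$graph), 0)
  expect_equal(igraph::ecount(threshold_graph(rho, 0.0)$graph), 3)
  # strictness: |rho| == tau is not an edge
  expect_equal(igraph::ecount(threshold_graph(rho, 0.5)$graph), 0 + 0 +
                 sum(abs(rho[upper.tri(rho)]) > 0.5))
})

test_that("threshold_graph with use_abs is invariant to global sign flip", {
  set.seed(7)
  ts <- gen_block_timeseries(10, 200, c(5, 5), 0.6, 0.1, seed = 7)
  rho <- pearson_matrix(ts)
  neg <- -rho; diag(neg) <- 1
  g1 <- threshold_graph(rho, 0.3, use_abs = TRUE)
  g2 <- threshold_graph(neg, 0.3, use_abs = TRUE)
  expect_equal(igraph::as_edgelist(g1$graph), igraph::as_edgelist(g2$graph))
})

test_that("edge sets are nested and retention non-increasing in tau", {
  ts <- gen_block_timeseries(20, 300, c(10, 10), 0.7, 0.2, seed = 3)
  rho <- pearson_matrix(ts)
  taus <- c(0.1, 0.3, 0.5, 0.7)
  graphs <- lapply(taus, function(t) threshold_graph(rho, t))
  for (k in seq_len(length(taus) - 1)) {
    e_hi <- igraph::as_edgelist(graphs[[k + 1]]$graph)
    e_lo <- igraph::as_edgelist(graphs[[k]]$graph)
    key <- function(e) paste(e[, 1], e[, 2])
    expect_true(all(key(e_hi) %in% key(e_lo)))
    expect_lte(largest_component(graphs[[k + 1]])$retention,
               largest_component(graphs[[k]])$retention)
  }
})

test_that("largest_component agrees with exhaustive enumeration on small
           graphs and breaks ties deterministically", {
  # two components of sizes 5 and 3
  g <- mk_graph(c(1,2, 2,3, 3,4, 4,5, 1,5, 6,7, 7,8))
  lc <- largest_component(g)
  expect_equal(lc$retention, 5 / 8)
  expect_equal(igraph::vcount(lc$graph$graph), 5)

  # edgeless graph: singleton components, tie broken to smallest node id
  g0 <- mk_graph(integer(0), n = 4)
  lc0 <- largest_component(g0)
  expect_equal(lc0$retention, 0.25)
  expect_equal(igraph::V(lc0$graph$graph)$name, "n001")

  # oracle: for n <= 6 compare against brute-force reachability
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    adj <- matrix(0, n, n)
    pairs <- which(upper.tri(adj), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < 0.35
    adj[pairs[on, , drop = FALSE]] <- 1
    adj <- adj + t(adj)
    reach <- (diag(n) + adj)
    for (k in 1:n) reach <- (reach %*% (diag(n) + adj) > 0) * 1
    sizes <- rowSums(reach)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(largest_component(g)$retention, max(sizes) / n)
  }
})

test_that("min_nodes_for_retention ceilings correctly", {
  expect_identical(min_nodes_for_retention(274, 0.95), 261L)
  expect_identical(min_nodes_for_retention(100, 1.0), 100L)
  expect_identical(min_nodes_for_retention(10, 0.95), 10L)
})

test_that("scale_free_check calibrates on its own generative model", {
  # power-law samples should pass in >= 90% of seeds
  # exact discrete power law alpha = 2.5 from k = 1 (independent sampler:
  # normalized probability table)
  ks <- 1:100000
  pk <- ks^(-2.5); pk <- pk / sum(pk)
  pass <- vapply(1:20, function(s) {
    set.seed(s)
    k <- sample(ks, 500, replace = TRUE, prob = pk)
    scale_free_check(k, gof_reps = 30, seed = s)$passes
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})

test_that("scale_free_check rejects degenerate and peaked distributions", {
  expect_false(scale_free_check(rep(6L, 100), seed = 1)$passes)
  # binomial degrees (peaked curve) must fail in >= 90% of seeds
  fails <- vapply(1:20, function(s) {
    set.seed(s)
    k <- rbinom(500, 200, 0.05)
    !scale_free_check(k, gof_reps = 30, seed = s)$passes
  }, logical(1))
  expect_gte(mean(fails), 0.9)
  expect_error(scale_free_check(rep(3L, 10)),
               class = "hypercon_insufficient_data")
})

test_that("threshold_window evaluates the documented grid and finds planted
           bands", {
  ts <- gen_block_timeseries(12, 120, c(6, 6), 0.8, 0.1, seed = 5)
  tw <- threshold_window(pearson_matrix(ts), 0.15, 0.65, 0.01,
                         gof_reps = 2, seed = 1)
  expect_length(tw$grid, 51)
  expect_equal(nrow(tw$per_threshold), 51)

  # degenerate complete-graph correlation: no window below 0.9
  rho <- matrix(0.9, 30, 30); diag(rho) <- 1
  tw2 <- threshold_window(rho, 0.15, 0.65, 0.1, gof_reps = 5, seed = 1)
  expect_null(tw2$window)
})

test_that("group_threshold stabs the most windows, ties to larger value", {
  grid <- seq(0.15, 0.65, by = 0.01)
  mk_win <- function(lo, hi) structure(
    list(grid = grid, per_threshold = NULL,
         window = if (is.null(lo)) NULL else c(lo, hi)),
    class = "threshold_window")
  expect_equal(group_threshold(list(mk_win(0.30, 0.40), mk_win(0.35, 0.45),
                                    mk_win(0.35, 0.38))), 0.38)
  expect_equal(group_threshold(list(mk_win(0.36, 0.36))), 0.36)
  expect_equal(group_threshold(list(mk_win(0.20, 0.30), mk_win(0.50, 0.60))),
               0.60)
  expect_error(group_threshold(list(mk_win(NULL, NULL))),
               class = "hypercon_no_threshold")
})
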