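# Connectivity module: Pearson correlation matrices from node x time series,
# absolute-value thresholding to binary graphs, largest-component retention,
# and threshold selection by the scale-free + retention window procedure.

#' Sample variance
#'
#' `sum((x - mean(x))^2) / (length(x) - 1)`.
#'
#' @param x numeric series of length >= 2.
#' @return nonnegative scalar.
#' @export
sample_variance <- function(x) {
  if (!is.numeric(x) || length(x) < 2L)
    stop_hc("variance undefined for series of length < 2",
            class = "hypercon_param_error")
  sum((x - mean(x))^2) / (length(x) - 1)
}

#' Pearson correlation matrix of a series matrix
#'
#' Entry (i, j) is the sample Pearson correlation of rows i and j of the
#' series matrix; the diagonal is exactly 1. Rows with zero variance are
#' rejected explicitly (naming the offending node) rather than silently
#' mapped to zero correlation.
#'
#' @param ts a `series_matrix` from [gen_block_timeseries()], or a plain
#'   node x timepoint numeric matrix.
#' @return a symmetric correlation matrix with node labels as dimnames, of
#'   class `corr_matrix`.
#' @export
pearson_matrix <- function(ts) {
  values <- if (inherits(ts, "series_matrix")) ts$values else as.matrix(ts)
  if (anyNA(values)) stop_hc("series contain missing values")
  if (ncol(values) < 3L)
    stop_hc("need at least 3 timepoints", class = "hypercon_param_error")
  labels <- rownames(values) %||% sprintf("n%03d", seq_len(nrow(values)))
  v <- apply(values, 1L, stats::var)
  if (any(v == 0))
    stop_hc("constant series for node(s): ",
            paste(labels[v == 0], collapse = ", "),
            class = "hypercon_constant_row")
  rho <- stats::cor(t(values))
  diag(rho) <- 1
  dimnames(rho) <- list(labels, labels)
  class(rho) <- c("corr_matrix", class(rho))
  rho
}

validate_corr <- function(c) {
  c <- unclass(as.matrix(c))
  if (nrow(c) != ncol(c) || max(abs(c - t(c))) > 1e-8)
    stop_hc("correlation matrix must be square and symmetric")
  if (max(abs(c)) > 1 + 1e-8) stop_hc("correlation entries must be in [-1, 1]")
  c
}

#' Threshold a correlation matrix into a binary graph
#'
#' An edge joins i and j iff `|rho_ij| > tau` (strict inequality), or
#' `rho_ij > tau` when `use_abs = FALSE`. The diagonal is ignored. Absolute
#' thresholding treats anticorrelated region pairs as connected.
#'
#' @param c correlation matrix (symmetric, unit diagonal).
#' @param tau threshold in `[0, 1]`.
#' @param use_abs threshold `|rho|` (default) or signed `rho`.
#' @return a [binary_graph()] carrying `tau` as provenance.
#' @export
threshold_graph <- function(c, tau, use_abs = TRUE) {
  assert_scalar_number(tau, "tau", lo = 0, hi = 1)
  m <- validate_corr(c)
  w <- if (use_abs) abs(m) else m
  adj <- (w > tau) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- rownames(m) %||% as.character(seq_len(nrow(m)))
  binary_graph(g, threshold = tau)
}

#' Largest connected component and retention fraction
#'
#' @param g a [binary_graph()] or igraph object.
#' @return list with `graph` (a `binary_graph` induced on the largest
#'   component; ties broken towards the component containing the smallest
#'   node id) and `retention` = |LCC| / |V|.
#' @export
largest_component <- function(g) {
  bg <- as_binary_graph(g)
  n <- igraph::vcount(bg$graph)
  if (n == 0L) stop_hc("graph has no nodes")
  sub <- igraph::induced_subgraph(bg$graph, which(bg$lcc_mask))
  list(graph = binary_graph(sub, threshold = bg$threshold),
       retention = sum(bg$lcc_mask) / n)
}

#' Minimum node count satisfying a retention fraction
#'
#' Smallest integer m with `m >= fraction * n_nodes`; at the default 95%
#' retention a 274-node network must keep at least 261 nodes.
#'
#' @param n_nodes total node count.
#' @param fraction retention fraction in `(0, 1]`.
#' @return integer node count.
#' @export
min_nodes_for_retention <- function(n_nodes, fraction = 0.95) {
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 1L)
  assert_scalar_number(fraction, "fraction", lo = 0, hi = 1, lo_open = TRUE)
  as.integer(ceiling(fraction * n_nodes - 1e-9))
}

#' Scale-free (power-law) check of a degree sequence
#'
#' Operationalizes the by-eye "does the degree distribution follow a power
#' law" judgment: maximum-likelihood discrete power-law fit (exponent and
#' lower cutoff, Clauset-style via [igraph::fit_power_law()]) followed by a
#' semi-parametric bootstrap goodness-of-fit test on the Kolmogorov-Smirnov
#' statistic. The sequence passes when the bootstrap p-value is at least
#' `p_threshold` and the fitted tail covers at least `min_tail_frac` of the
#' nonzero degrees (a power law fitted to a vanishing tail of a peaked
#' distribution is not scale-freeness).
#'
#' @param degrees nonnegative integer degree sequence (>= 20 nonzero).
#' @param gof_reps bootstrap replicates for the goodness-of-fit p-value.
#' @param seed integer seed for the bootstrap.
#' @param p_threshold pass cutoff on the bootstrap p-value (default 0.1).
#' @param min_tail_frac minimum fraction of nonzero degrees at or above the
#'   fitted cutoff (default 0.1).
#' @param alpha_range plausible exponent range for a scale-free network; a
#'   fit outside it fails regardless of goodness of fit (peaked
#'   distributions fit power laws with absurdly steep exponents).
#' @return a `degree_check` list: `degrees`, `alpha_hat`, `k_min_hat`,
#'   `gof_p`, `passes`, `tail_frac`.
#' @export
scale_free_check <- function(degrees, gof_reps = 50L, seed = 1L,
                             p_threshold = 0.1, min_tail_frac = 0.1,
                             alpha_range = c(1.5, 6)) {
  gof_reps <- assert_count(gof_reps, "gof_reps", min = 1L)
  k <- as.integer(round(degrees))
  if (any(k < 0)) stop_hc("degrees must be nonnegative")
  kz <- k[k > 0]
  if (length(kz) < 20L)
    stop_hc("need at least 20 nonzero degrees (got ", length(kz), ")",
            class = "hypercon_insufficient_data")
  out <- list(degrees = k)
  if (length(unique(kz)) < 3L) {
    # (near-)degenerate distribution: a regular graph is not scale-free
    out <- c(out, list(alpha_hat = NA_real_, k_min_hat = NA_real_,
                       gof_p = 0, tail_frac = 1, passes = FALSE))
    class(out) <- "degree_check"
    return(out)
  }
  fit <- igraph::fit_power_law(kz, implementation = "plfit")
  ks_obs <- fit$KS.stat
  xmin <- fit$xmin
  alpha <- fit$alpha
  tail_frac <- mean(kz >= xmin)
  body <- kz[kz < xmin]
  p_tail <- 1 - length(body) / length(kz)
  n <- length(kz)
  ks_boot <- with_seed(seed, vapply(seq_len(gof_reps), function(rep) {
    from_tail <- stats::runif(n) < p_tail
    synth <- integer(n)
    if (any(!from_tail))
      synth[!from_tail] <- sample(body, sum(!from_tail), replace = TRUE)
    if (any(from_tail))
      synth[from_tail] <- rplaw_discrete(sum(from_tail), alpha, xmin)
    f <- tryCatch(igraph::fit_power_law(synth, implementation = "plfit"),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$KS.stat
  }, numeric(1)))
  ks_boot <- ks_boot[is.finite(ks_boot)]
  gof_p <- if (length(ks_boot)) mean(ks_boot >= ks_obs) else NA_real_
  out <- c(out, list(alpha_hat = alpha, k_min_hat = xmin, gof_p = gof_p,
                     tail_frac = tail_frac,
                     passes = isTRUE(gof_p >= p_threshold) &&
                       tail_frac >= min_tail_frac &&
                       alpha >= alpha_range[1L] && alpha <= alpha_range[2L]))
  class(out) <- "degree_check"
  out
}

#' @export
print.degree_check <- function(x, ...) {
  cat(sprintf(
    "<degree_check> alpha = %.3g, k_min = %s, gof_p = %.3g, tail = %.2f -> %s\n",
    x$alpha_hat, format(x$k_min_hat), x$gof_p, x$tail_frac,
    if (x$passes) "PASS" else "FAIL"))
  invisible(x)
}

# Discrete power-law sampler for k >= xmin, P(k) ~ k^(-alpha). Exact inverse
# CDF over a table for the bulk, continuous approximation for the far tail
# (beyond the table the two agree to high accuracy).
rplaw_discrete <- function(n, alpha, xmin, table_span = 10000L) {
  ks <- xmin:(xmin + table_span)
  w <- ks^(-alpha)
  # total tail mass beyond the table, from the continuous approximation
  rest <- ((xmin + table_span + 0.5)^(1 - alpha)) / (alpha - 1)
  cdf <- cumsum(w) / (sum(w) + rest)
  u <- stats::runif(n)
  out <- ks[findInterval(u, cdf) + 1L]
  far <- is.na(out)
  if (any(far))
    out[far] <- floor((xmin - 0.5) * (1 - u[far])^(-1 / (alpha - 1)) + 0.5)
  out
}

#' Evaluate a threshold grid: retention and scale-freeness per threshold
#'
#' For each threshold on the grid, builds the binary graph, records the
#' largest-component retention fraction and the scale-free check, and
#' returns the maximal contiguous run of thresholds where retention is at
#' least `retention_fraction` and the scale-free check passes (the subject's
#' admissible threshold window; possibly empty). The default grid 0.15-0.65
#' in steps of 0.01 evaluates 51 thresholds.
#'
#' @param c correlation matrix.
#' @param grid_lo,grid_hi,step threshold grid specification.
#' @param retention_fraction minimum largest-component retention.
#' @param gof_reps,seed passed to [scale_free_check()].
#' @param use_abs threshold on `|rho|` (default TRUE).
#' @return a `threshold_window` list: `grid`, `per_threshold` (data frame
#'   with threshold, retention, alpha_hat, gof_p, pass columns), `window`
#'   (length-2 numeric or NULL).
#' @export
threshold_window <- function(c, grid_lo = 0.15, grid_hi = 0.65, step = 0.01,
                             retention_fraction = 0.95, gof_reps = 25L,
                             seed = 1L, use_abs = TRUE) {
  if (!(grid_lo < grid_hi) || step <= 0)
    stop_hc("need grid_lo < grid_hi and step > 0",
            class = "hypercon_param_error")
  m <- validate_corr(c)
  grid <- seq(grid_lo, grid_hi, by = step)
  rec <- lapply(seq_along(grid), function(gi) {
    tau <- grid[gi]
    bg <- threshold_graph(m, tau, use_abs = use_abs)
    lc <- largest_component(bg)
    degs <- igraph::degree(bg$graph)
    chk <- tryCatch(
      scale_free_check(degs, gof_reps = gof_reps,
                       seed = child_seed(seed, gi)),
      hypercon_insufficient_data = function(e) NULL)
    data.frame(threshold = tau,
               retention = lc$retention,
               alpha_hat = if (is.null(chk)) NA_real_ else chk$alpha_hat,
               gof_p = if (is.null(chk)) NA_real_ else chk$gof_p,
               pass = if (is.null(chk)) FALSE else chk$passes)
  })
  per <- do.call(rbind, rec)
  ok <- per$retention >= retention_fraction & per$pass
  window <- NULL
  if (any(ok)) {
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    idx <- which(runs$values)
    best <- idx[which.max(runs$lengths[idx])]
    window <- c(grid[starts[best]], grid[ends[best]])
  }
  structure(list(grid = grid, per_threshold = per, window = window),
            class = "threshold_window")
}

#' @export
print.threshold_window <- function(x, ...) {
  cat(sprintf("<threshold_window> %d thresholds, window = %s\n",
              length(x$grid),
              if (is.null(x$window)) "empty"
              else paste(format(x$window), collapse = " - ")))
  invisible(x)
}

#' Group threshold: the grid value covered by the most subject windows
#'
#' Interval stabbing over the subjects' admissible windows; ties are broken
#' towards the larger threshold (the sparser network), matching the
#' preference for the highest threshold at which scale-freeness holds.
#'
#' @param windows list of `threshold_window` objects sharing one grid.
#' @return the selected threshold (scalar).
#' @export
group_threshold <- function(windows) {
  if (length(windows) < 1L) stop_hc("need at least one window")
  if (inherits(windows, "threshold_window")) windows <- list(windows)
  grid <- windows[[1L]]$grid
  for (w in windows)
    if (!isTRUE(all.equal(w$grid, grid)))
      stop_hc("all windows must share the same threshold grid")
  counts <- rowSums(vapply(windows, function(w) {
    if (is.null(w$window)) rep(FALSE, length(grid))
    else grid >= w$window[1L] - 1e-12 & grid <= w$window[2L] + 1e-12
  }, logical(length(grid))))
  if (max(counts) == 0L)
    stop_hc("all subject windows are empty: no valid group threshold",
            class = "hypercon_no_threshold")
  grid[max(which(counts == max(counts)))]
}
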