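# Reproducibility quantification (coefficient of variation of a distance
# analog over repeated embeddings) and edge-level anomaly detection of one
# subject against a control cohort's per-edge distributions.

#' Distance analog of a hyperbolic distance matrix
#'
#' `D_ij = exp((d_ij - r_hat) / 2)`: a strictly increasing transform of
#' hyperbolic distance that equals 1 exactly at `d = r_hat` and is inversely
#' related to connection probability.
#'
#' @param d hyperbolic distance matrix (or vector).
#' @param r_hat outermost radial coordinate; defaults to the `r_hat`
#'   attribute attached by [disc_distances()].
#' @return transformed matrix/vector of positive values.
#' @export
distance_analog <- function(d, r_hat = attr(d, "r_hat")) {
  if (is.null(r_hat) || !is.finite(r_hat))
    stop_hc("r_hat must be supplied (finite scalar)")
  exp((d - r_hat) / 2)
}

#' Reproducibility of the embedding: per-edge CV over repeated embeddings
#'
#' Embeds the graph `n_rep` times with consecutive seeds
#' `base_seed ... base_seed + n_rep - 1`, computes the distance analog for
#' every repetition, and reports the coefficient of variation
#' `sd(D_ij) / mean(D_ij)` across repetitions for every graph edge, plus each
#' node's mean CV over its incident edges. Failed repetitions are recorded
#' and excluded; at least 80% must succeed.
#'
#' @param g connected [binary_graph()] or igraph.
#' @param n_rep number of repeated embeddings (>= 2).
#' @param base_seed first seed of the consecutive block.
#' @param beta optional fixed inverse temperature passed to [embed_s1h2()]
#'   (inferred once from the graph when `NULL`, since beta inference is
#'   deterministic apart from its seed).
#' @param passes sweep passes per embedding.
#' @return a `cv_report`: `edge_cv` (data frame i, j, cv), `node_cv`,
#'   `n_repetitions`, `failed_seeds`.
#' @export
repeat_embed_cv <- function(g, n_rep = 100L, base_seed = 1L, beta = NULL,
                            passes = 8L) {
  n_rep <- assert_count(n_rep, "n_rep", min = 2L)
  bg <- as_binary_graph(g)
  seeds <- base_seed + seq_len(n_rep) - 1L
  if (anyDuplicated(seeds)) stop_hc("repetition seeds must differ")
  if (is.null(beta))
    beta <- as.numeric(infer_beta(bg, seed = child_seed(base_seed, 99L)))
  el <- igraph::as_edgelist(bg$graph, names = FALSE)
  dvals <- matrix(NA_real_, nrow(el), n_rep)
  failed <- integer(0)
  for (k in seq_len(n_rep)) {
    disc <- tryCatch(embed_s1h2(bg, seed = seeds[k], beta = beta,
                                passes = passes),
                     error = function(e) NULL)
    if (is.null(disc)) { failed <- c(failed, seeds[k]); next }
    dmat <- disc_distances(disc)
    dvals[, k] <- distance_analog(dmat)[el]
  }
  ok <- setdiff(seq_len(n_rep), match(failed, seeds))
  if (length(ok) < 0.8 * n_rep)
    stop_hc("fewer than 80% of repetitions embedded successfully (",
            length(ok), "/", n_rep, ")", class = "hypercon_repeat_failure")
  dv <- dvals[, ok, drop = FALSE]
  edge_cv <- apply(dv, 1L, stats::sd) / rowMeans(dv)
  n <- igraph::vcount(bg$graph)
  node_cv <- vapply(seq_len(n), function(v) {
    inc <- el[, 1L] == v | el[, 2L] == v
    if (!any(inc)) NA_real_ else mean(edge_cv[inc])
  }, numeric(1))
  names(node_cv) <- igraph::V(bg$graph)$name
  structure(list(
    edge_cv = data.frame(i = el[, 1L], j = el[, 2L], cv = edge_cv),
    node_cv = node_cv, n_repetitions = length(ok), failed_seeds = failed),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d repetitions, median edge CV = %.3f\n",
              x$n_repetitions, stats::median(x$edge_cv$cv)))
  invisible(x)
}

#' Build per-edge control distributions from a cohort
#'
#' Stores, for every node pair, the control subjects' values (hyperbolic
#' distances or correlations), their mean and SD, empirical cut points at the
#' configured tails (inclusive order statistics with linear interpolation,
#' i.e. quantile type 6), and a Shapiro-Wilk normality p-value kept as QC
#' metadata (not used for exclusion).
#'
#' @param cohort_values list of symmetric node-pair matrices, one per control
#'   subject, sharing one node set.
#' @param tail lower/upper tail mass for the cut points (default 0.025).
#' @param min_subjects minimum cohort size (default 20).
#' @return a `control_distribution`: `samples` (pairs x subjects matrix),
#'   `pairs`, `mean`, `sd`, `lo_cut`, `hi_cut`, `normality_p`, `tail`,
#'   `n_nodes`, `labels`, `n_subjects`.
#' @export
build_control <- function(cohort_values, tail = 0.025, min_subjects = 20L) {
  assert_scalar_number(tail, "tail", lo = 0, hi = 0.5, lo_open = TRUE,
                       hi_open = TRUE)
  s <- length(cohort_values)
  if (s < min_subjects)
    stop_hc("need at least ", min_subjects, " control subjects (got ", s, ")",
            class = "hypercon_param_error")
  dims <- vapply(cohort_values, function(m) nrow(as.matrix(m)), integer(1))
  labs <- lapply(cohort_values, function(m) rownames(as.matrix(m)))
  if (length(unique(dims)) != 1L)
    stop_hc("control subjects do not share a node set (sizes ",
            paste(unique(dims), collapse = ", "), "); offending subjects: ",
            paste(which(dims != dims[1L]), collapse = ", "),
            class = "hypercon_alignment_error")
  n <- dims[1L]
  pr <- upper_pairs(n)
  samples <- vapply(cohort_values, function(m) as.matrix(m)[pr],
                    numeric(nrow(pr)))
  mu <- rowMeans(samples)
  sdv <- apply(samples, 1L, stats::sd)
  qs <- t(apply(samples, 1L, stats::quantile, probs = c(tail, 1 - tail),
                type = 6, names = FALSE))
  norm_p <- apply(samples, 1L, function(v) {
    if (length(unique(v)) < 3L) return(NA_real_)
    stats::shapiro.test(v)$p.value
  })
  structure(list(samples = samples, pairs = pr, mean = mu, sd = sdv,
                 lo_cut = qs[, 1L], hi_cut = qs[, 2L], normality_p = norm_p,
                 tail = tail, n_nodes = n,
                 labels = labs[[1L]] %||% as.character(seq_len(n)),
                 n_subjects = s),
            class = "control_distribution")
}

#' @export
print.control_distribution <- function(x, ...) {
  cat(sprintf(
    "<control_distribution> %d subjects, %d node pairs, tails at %.3g\n",
    x$n_subjects, nrow(x$pairs), x$tail))
  invisible(x)
}

flag_against_control <- function(test_values, control, tail, mode) {
  m <- as.matrix(test_values)
  if (nrow(m) != control$n_nodes)
    stop_hc("test subject node set does not match the control cohort",
            class = "hypercon_alignment_error")
  pr <- control$pairs
  v <- m[pr]
  if (!isTRUE(all.equal(tail, control$tail))) {
    qs <- t(apply(control$samples, 1L, stats::quantile,
                  probs = c(tail, 1 - tail), type = 6, names = FALSE))
    lo <- qs[, 1L]; hi <- qs[, 2L]
  } else {
    lo <- control$lo_cut; hi <- control$hi_cut
  }
  pct <- rowMeans(control$samples < v) +
    0.5 * rowMeans(control$samples == v)
  long <- v > hi     # strict inequality at the cut points
  short <- v < lo
  structure(list(
    long_edges = pr[long, , drop = FALSE],
    short_edges = pr[short, , drop = FALSE],
    per_edge = data.frame(i = pr[, 1L], j = pr[, 2L], value = v,
                          percentile = pct,
                          flag = ifelse(long, "long",
                                        ifelse(short, "short", "none"))),
    mode = mode, tail = tail, labels = control$labels),
    class = "anomaly_report")
}

#' Flag anomalous edges of one subject against the control cohort
#'
#' An edge is flagged `long` when the test subject's hyperbolic distance
#' exceeds the control cohort's upper empirical cut (the `1 - tail`
#' quantile) and `short` when it falls below the lower cut. Comparisons are
#' strict, per-edge percentiles are empirical CDF positions, and no multiple
#' comparison correction is applied by default (an optional
#' Benjamini-Hochberg mode is available via [bh_filter()]).
#'
#' @param test symmetric distance matrix of the test subject.
#' @param control a [build_control()] object.
#' @param tail tail mass (default 0.025, the upper/lower 2.5%).
#' @return an `anomaly_report`: `long_edges`, `short_edges`, `per_edge`
#'   (data frame with value, percentile, flag), `mode`, `tail`.
#' @export
flag_edges <- function(test, control, tail = 0.025) {
  assert_scalar_number(tail, "tail", lo = 0, hi = 0.5, lo_open = TRUE,
                       hi_open = TRUE)
  flag_against_control(test, control, tail, mode = "hyperbolic")
}

#' Flag anomalous edges by correlation values
#'
#' Identical machinery to [flag_edges()] with per-edge correlation values in
#' place of hyperbolic distances: `long` marks an anomalously high value and
#' `short` an anomalously low one (note that high correlation corresponds to
#' short hyperbolic distance).
#'
#' @param test correlation matrix of the test subject.
#' @param control_cohort list of control correlation matrices, or a
#'   prebuilt [build_control()] object.
#' @param tail tail mass (default 0.025).
#' @return an `anomaly_report` with `mode = "correlation"`.
#' @export
flag_edges_correlation <- function(test, control_cohort, tail = 0.025) {
  assert_scalar_number(tail, "tail", lo = 0, hi = 0.5, lo_open = TRUE,
                       hi_open = TRUE)
  control <- if (inherits(control_cohort, "control_distribution"))
    control_cohort else build_control(control_cohort, tail = tail)
  flag_against_control(test, control, tail, mode = "correlation")
}

#' @export
print.anomaly_report <- function(x, ...) {
  cat(sprintf("<anomaly_report> mode = %s, tail = %.3g: %d long, %d short\n",
              x$mode, x$tail, nrow(x$long_edges), nrow(x$short_edges)))
  invisible(x)
}

#' Optional Benjamini-Hochberg filtering of an anomaly report
#'
#' Converts per-edge percentiles to two-sided empirical p-values, applies BH
#' at level `alpha`, and drops flags that do not survive. Off by default in
#' the pipeline, matching the no-correction default of the detector.
#'
#' @param report an `anomaly_report`.
#' @param alpha false-discovery level.
#' @return the filtered `anomaly_report`.
#' @export
bh_filter <- function(report, alpha = 0.05) {
  pe <- report$per_edge
  pvals <- 2 * pmin(pe$percentile, 1 - pe$percentile)
  keep <- stats::p.adjust(pvals, method = "BH") <= alpha
  pe$flag[!keep] <- "none"
  report$per_edge <- pe
  sel <- function(fl) as.matrix(pe[pe$flag == fl, c("i", "j")])
  report$long_edges <- sel("long")
  report$short_edges <- sel("short")
  report
}

#' Aggregate flagged edges into region-pair counts
#'
#' @param report an `anomaly_report`.
#' @param grouping named character vector (or factor) mapping each node
#'   index/label to a region label; must cover all flagged nodes.
#' @return data frame (region_a, region_b, n_long, n_short) over unordered
#'   region pairs with at least one flag.
#' @export
aggregate_regions <- function(report, grouping) {
  pe <- report$per_edge[report$per_edge$flag != "none", , drop = FALSE]
  if (nrow(pe) == 0L)
    return(data.frame(region_a = character(), region_b = character(),
                      n_long = integer(), n_short = integer()))
  gmap <- as.character(grouping)
  nodes <- unique(c(pe$i, pe$j))
  if (any(nodes > length(gmap)) || anyNA(gmap[nodes]))
    stop_hc("grouping does not cover flagged node(s): ",
            paste(nodes[nodes > length(gmap) | is.na(gmap[nodes])],
                  collapse = ", "), class = "hypercon_id_error")
  ra <- gmap[pe$i]; rb <- gmap[pe$j]
  key <- ifelse(ra <= rb, paste(ra, rb, sep = "\r"), paste(rb, ra, sep = "\r"))
  agg <- tapply(pe$flag, key, function(f)
    c(long = sum(f == "long"), short = sum(f == "short")))
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  counts <- do.call(rbind, agg)
  data.frame(region_a = parts[, 1L], region_b = parts[, 2L],
             n_long = as.integer(counts[, "long"]),
             n_short = as.integer(counts[, "short"]),
             row.names = NULL)
}
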