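# Plain-text readers/writers for the pipeline's artifact formats. All
# numeric round trips are lossless to at least 12 significant digits.

fmt_num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

#' Write / read a node x timepoint series matrix (TSV)
#'
#' First column holds the node label; remaining columns the timepoints.
#'
#' @param ts a `series_matrix` or plain matrix with row names.
#' @param path file path.
#' @return `read_series` returns a `series_matrix`.
#' @export
write_series <- function(ts, path) {
  values <- if (inherits(ts, "series_matrix")) ts$values else as.matrix(ts)
  labels <- rownames(values) %||% sprintf("n%03d", seq_len(nrow(values)))
  df <- data.frame(node = labels, apply(values, 2L, fmt_num),
                   check.names = FALSE)
  colnames(df) <- c("node", sprintf("t%d", seq_len(ncol(values))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 4L)
    stop_hc("series file must have a label column and >= 3 timepoints")
  values <- apply(as.matrix(df[, -1L, drop = FALSE]), c(1L, 2L), as.numeric)
  if (anyNA(values)) {
    bad <- which(apply(is.na(values), 1L, any))[1L]
    stop_hc("malformed numeric value in series row ", bad + 1L,
            class = "hypercon_format_error")
  }
  rownames(values) <- df[[1L]]
  structure(list(values = values, node_labels = df[[1L]],
                 n_timepoints = ncol(values), target_rho = NULL),
            class = "series_matrix")
}

#' Write / read a square symmetric matrix (CSV with labeled header)
#'
#' @param m square symmetric numeric matrix.
#' @param path file path.
#' @param tol symmetry tolerance enforced on read.
#' @return `read_matrix` returns the matrix with dimnames.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  labels <- rownames(m) %||% sprintf("n%03d", seq_len(nrow(m)))
  out <- cbind(label = labels, apply(m, 2L, fmt_num))
  colnames(out) <- c("label", labels)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, tol = 1e-9) {
  df <- utils::read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  m <- apply(as.matrix(df[, -1L, drop = FALSE]), c(1L, 2L), as.numeric)
  if (nrow(m) != ncol(m))
    stop_hc("matrix file is not square", class = "hypercon_format_error")
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1L]
    stop_hc("malformed numeric value in matrix row ", bad + 1L,
            class = "hypercon_format_error")
  }
  if (max(abs(m - t(m))) > tol)
    stop_hc("matrix file is not symmetric (max asymmetry ",
            format(max(abs(m - t(m)))), ")", class = "hypercon_format_error")
  dimnames(m) <- list(df[[1L]], df[[1L]])
  m
}

#' Write / read an edge list (two-column, whitespace-separated, 0-based)
#'
#' An optional sidecar TSV (`<path>.nodes.tsv`) stores the id-to-label
#' mapping (columns id, label, and optionally group).
#'
#' @param g a [binary_graph()] or igraph.
#' @param path file path.
#' @param write_labels also write the sidecar node-label table.
#' @return `read_edgelist` returns a [binary_graph()].
#' @export
write_edgelist <- function(g, path, write_labels = TRUE) {
  bg <- as_binary_graph(g)
  el <- igraph::as_edgelist(bg$graph, names = FALSE) - 1L
  utils::write.table(el, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (write_labels) {
    utils::write.table(
      data.frame(id = seq_len(igraph::vcount(bg$graph)) - 1L,
                 label = igraph::V(bg$graph)$name),
      paste0(path, ".nodes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_edgelist
#' @param n_nodes optional node count (for isolated trailing nodes).
#' @export
read_edgelist <- function(path, n_nodes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  for (ln in seq_along(parts)) {
    p <- parts[[ln]]
    if (length(p) != 2L || anyNA(suppressWarnings(as.integer(p))))
      stop_hc("malformed edge list row at line ", ln,
              class = "hypercon_format_error")
    if (p[1L] == p[2L])
      stop_hc("self-loop at line ", ln, class = "hypercon_format_error")
  }
  el <- do.call(rbind, lapply(parts, as.integer)) + 1L
  n <- max(el, n_nodes %||% 0L)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  side <- paste0(path, ".nodes.tsv")
  if (file.exists(side)) {
    lab <- utils::read.table(side, sep = "\t", header = TRUE,
                             colClasses = "character")
    igraph::V(g)$name <- lab$label[order(as.integer(lab$id))]
  } else {
    igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  }
  binary_graph(g)
}

#' Write / read a hyperbolic disc (CSV with metadata header)
#'
#' Header comment lines carry `beta`, `mu`, `r_hat`, `n_nodes` and `loglik`;
#' the body has columns id, label, kappa, r, theta.
#'
#' @param disc a [hyperbolic_disc()].
#' @param path file path.
#' @return `read_disc` returns a [hyperbolic_disc()].
#' @export
write_disc <- function(disc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# beta=%s", fmt_num(disc$beta)),
    sprintf("# mu=%s", fmt_num(disc$mu)),
    sprintf("# r_hat=%s", fmt_num(disc$r_hat)),
    sprintf("# n_nodes=%d", disc$n_nodes),
    sprintf("# loglik=%s", fmt_num(disc$loglik))), con)
  utils::write.table(
    data.frame(id = seq_len(disc$n_nodes) - 1L, label = disc$labels,
               kappa = fmt_num(disc$kappa), r = fmt_num(disc$r),
               theta = fmt_num(disc$theta)),
    con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_disc
#' @export
read_disc <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=")[[1L]]
    meta[[kv[1L]]] <- as.numeric(kv[2L])
  }
  for (need in c("beta", "mu", "r_hat"))
    if (is.null(meta[[need]]))
      stop_hc("disc file missing required header '", need, "'",
              class = "hypercon_schema_error")
  body <- utils::read.table(text = lines[!grepl("^#", lines)], sep = ",",
                            header = TRUE, colClasses = "character")
  hyperbolic_disc(as.numeric(body$r), as.numeric(body$theta),
                  as.numeric(body$kappa), meta$beta, meta$mu,
                  labels = body$label,
                  loglik = meta$loglik %||% NA_real_)
}

#' Write a threshold-window report (TSV)
#'
#' @param tw a `threshold_window`.
#' @param path file path.
#' @export
write_threshold_report <- function(tw, path) {
  utils::write.table(tw$per_threshold, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an anomaly report (TSV)
#'
#' @param report an `anomaly_report`.
#' @param path file path.
#' @param all_pairs include unflagged pairs too.
#' @export
write_anomaly_report <- function(report, path, all_pairs = FALSE) {
  pe <- report$per_edge
  if (!all_pairs) pe <- pe[pe$flag != "none", , drop = FALSE]
  utils::write.table(pe, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a control distribution (wide TSV)
#'
#' Columns: i, j, mean, sd, lo_cut, hi_cut, normality_p.
#'
#' @param control a [build_control()] object.
#' @param path file path.
#' @export
write_control <- function(control, path) {
  utils::write.table(
    data.frame(i = control$pairs[, 1L], j = control$pairs[, 2L],
               mean = fmt_num(control$mean), sd = fmt_num(control$sd),
               lo_cut = fmt_num(control$lo_cut),
               hi_cut = fmt_num(control$hi_cut),
               normality_p = fmt_num(control$normality_p)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write embedding coordinates (CSV with a space tag)
#'
#' Columns: id, label, the ambient coordinates (x1, x2, ...), and the
#' compact space tag (e.g. `H2`).
#'
#' @param result an `embedding_result` from [rsgd_embed()].
#' @param path file path.
#' @param labels optional node labels.
#' @export
write_embedding <- function(result, path, labels = NULL) {
  x <- result$coordinates
  tag <- paste0(toupper(substr(result$space$curvature, 1L, 1L)),
                result$space$dim)
  df <- data.frame(id = seq_len(nrow(x)) - 1L,
                   label = labels %||% as.character(seq_len(nrow(x))))
  for (c_ in seq_len(ncol(x))) df[[paste0("x", c_)]] <- fmt_num(x[, c_])
  df$space <- tag
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a synthetic cohort (edge lists + YAML manifest)
#'
#' Each subject becomes `subject_<k>.edgelist` (with node-label sidecar);
#' `manifest.yaml` lists the subject files and the perturbation log.
#'
#' @param cohort a [synthetic_cohort()].
#' @param dir output directory (created if missing).
#' @return `read_cohort` returns a [synthetic_cohort()] (without the
#'   generating ground truth, which the manifest does not serialize).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(seq_along(cohort$subjects), function(k) {
    f <- sprintf("subject_%03d.edgelist", k)
    write_edgelist(cohort$subjects[[k]], file.path(dir, f))
    f
  }, character(1))
  yaml::write_yaml(
    list(schema = "hypercon_cohort/1",
         subjects = as.list(files),
         perturbation_log = lapply(seq_len(nrow(cohort$perturbation_log)),
                                   function(r) as.list(cohort$perturbation_log[r, ]))),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  subjects <- lapply(man$subjects, function(f)
    read_edgelist(file.path(dir, f)))
  log <- if (length(man$perturbation_log))
    do.call(rbind, lapply(man$perturbation_log, as.data.frame)) else
      empty_perturbation_log()
  synthetic_cohort(subjects, ground_truth = NULL, perturbation_log = log)
}
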