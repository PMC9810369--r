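# Umbrella pipeline: validated configuration, stage sequencing, artifact
# writing and a machine-readable run log.

config_schema <- list(
  schema_version = "1",
  series = NULL,              # input series TSV (or NULL with simulate block)
  out_dir = "hypercon_out",
  tau = NULL,                 # fixed threshold; NULL -> window selection
  use_abs = TRUE,
  grid_lo = 0.15, grid_hi = 0.65, grid_step = 0.01,
  retention_fraction = 0.95,
  gof_reps = 25,
  seed = 1,
  passes = 12,
  exact_distance = FALSE,
  cv_reps = 0,                # 0 disables the reproducibility stage
  tail = 0.025,
  controls = NULL,            # directory of control disc CSVs (detect stage)
  mode = "hyperbolic"
)

#' Load and validate a pipeline configuration
#'
#' YAML document with a versioned schema; unknown keys are rejected and all
#' numeric ranges validated at load. Defaults mirror the analysis defaults:
#' grid 0.15-0.65 step 0.01, retention 0.95, 100 repetitions when the CV
#' stage is enabled, tails at 0.025.
#'
#' @param path YAML file, or a named list of overrides.
#' @return validated config list of class `pipeline_config`.
#' @export
load_config <- function(path) {
  user <- if (is.list(path)) path else yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(config_schema))
  if (length(unknown))
    stop_hc("unknown config key(s): ", paste(unknown, collapse = ", "),
            class = "hypercon_config_error")
  cfg <- utils::modifyList(config_schema, user)
  assert_scalar_number(cfg$retention_fraction, "retention_fraction",
                       lo = 0, hi = 1, lo_open = TRUE)
  assert_scalar_number(cfg$tail, "tail", lo = 0, hi = 0.5,
                       lo_open = TRUE, hi_open = TRUE)
  if (!is.null(cfg$tau))
    assert_scalar_number(cfg$tau, "tau", lo = 0, hi = 1)
  assert_count(cfg$seed, "seed", min = 0L)
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline from a configuration
#'
#' Sequences connect (series to correlation to thresholded graph) ->
#' largest component -> S1/H2 embed -> optional reproducibility CV ->
#' optional anomaly detection, writing every intermediate artifact into
#' `out_dir` together with a JSON run log holding seeds, parameters,
#' package version and per-artifact checksums. Any stage failure halts with
#' the stage name; artifacts written so far are preserved.
#'
#' @param config a `pipeline_config`, path to one, or a named list.
#' @return invisibly, the artifact directory path.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    load_config(config)
  if (is.null(cfg$series))
    stop_hc("config must name an input 'series' file",
            class = "hypercon_config_error")
  if (!file.exists(cfg$series))
    stop_hc("input series file does not exist: ", cfg$series,
            class = "hypercon_config_error")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(schema_version = cfg$schema_version,
              package_version = as.character(utils::packageVersion("hypercon")),
              parameters = unclass(cfg), stages = list())
  artifact <- function(name) file.path(cfg$out_dir, name)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop_hc("pipeline stage '", name, "' failed: ", conditionMessage(e),
              class = "hypercon_stage_error"))
    log$stages[[name]] <<- list(
      wall_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  ts <- stage("read_series", read_series(cfg$series))
  rho <- stage("correlate", pearson_matrix(ts))
  write_matrix(rho, artifact("correlation.csv"))

  tau <- cfg$tau
  if (is.null(tau)) {
    tw <- stage("window", threshold_window(
      rho, cfg$grid_lo, cfg$grid_hi, cfg$grid_step,
      retention_fraction = cfg$retention_fraction,
      gof_reps = cfg$gof_reps, seed = cfg$seed, use_abs = cfg$use_abs))
    write_threshold_report(tw, artifact("threshold_report.tsv"))
    tau <- stage("group_threshold", group_threshold(list(tw)))
  }
  bg <- stage("threshold", threshold_graph(rho, tau, use_abs = cfg$use_abs))
  lc <- stage("largest_component", largest_component(bg))
  write_edgelist(lc$graph, artifact("graph.edgelist"))

  disc <- stage("embed", embed_s1h2(lc$graph, seed = cfg$seed,
                                    passes = cfg$passes))
  write_disc(disc, artifact("disc.csv"))
  dmat <- disc_distances(disc, exact = cfg$exact_distance)
  write_matrix(dmat, artifact("distances.csv"))

  if (cfg$cv_reps >= 2) {
    cv <- stage("cv", repeat_embed_cv(lc$graph, n_rep = cfg$cv_reps,
                                      base_seed = cfg$seed,
                                      beta = disc$beta))
    utils::write.table(cv$edge_cv, artifact("edge_cv.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if (!is.null(cfg$controls)) {
    ctrl_files <- list.files(cfg$controls, pattern = "\\.csv$",
                             full.names = TRUE)
    ctrl <- stage("build_control", build_control(
      lapply(ctrl_files, read_matrix), tail = cfg$tail))
    rep_ <- stage("detect", flag_edges(dmat, ctrl, tail = cfg$tail))
    write_anomaly_report(rep_, artifact("anomaly_report.tsv"))
  }

  files <- list.files(cfg$out_dir, full.names = TRUE)
  log$checksums <- as.list(tools::md5sum(files[!grepl("run_log", files)]))
  log$threshold <- tau
  jsonlite::write_json(log, artifact("run_log.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(cfg$out_dir)
}
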