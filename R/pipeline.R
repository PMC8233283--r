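#' Pipeline configuration
#'
#' Assembles (and validates) everything `run_pipeline()` needs. Either file
#' paths to existing trace/window CSVs, or a simulation config for the
#' synthetic generator. A YAML round trip of this object is lossless for
#' all scalar fields.
#'
#' @param traces_csv,background_csv,windows_csv input paths (ignored when
#'   `simulate` is given).
#' @param simulate optional [trace_sim_config()]; when present the traces
#'   are generated rather than read.
#' @param windows a [protocol_windows()] used with `simulate`.
#' @param params a [calibration_params()].
#' @param thresholds a [responder_thresholds()].
#' @param agonist optional agonist restriction for classification.
#' @param seed integer master seed; overrides the simulation config seed.
#' @param out_dir output directory for the report bundle.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(traces_csv = NULL, background_csv = NULL,
                            windows_csv = NULL,
                            simulate = NULL, windows = default_windows(),
                            params = calibration_params(),
                            thresholds = responder_thresholds(),
                            agonist = NULL, seed = 1,
                            out_dir = tempfile("trpkit_report_")) {
  if (is.null(simulate)) {
    for (p in c(traces_csv, background_csv, windows_csv)) {
      if (is.null(p) || !file.exists(p)) {
        stop("input file missing: ", if (is.null(p)) "(unset path)" else p)
      }
    }
  }
  structure(list(traces_csv = traces_csv, background_csv = background_csv,
                 windows_csv = windows_csv, simulate = simulate,
                 windows = windows, params = params, thresholds = thresholds,
                 agonist = agonist, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the calcium-imaging pipeline end to end
#'
#' Calibrates (simulated or loaded) traces, classifies responders,
#' aggregates per-experiment and cohort summaries and writes a report
#' bundle: `calls.csv`, `experiment_summaries.csv`, `cohort_summary.csv`,
#' `calcium.csv` and a machine-readable `report.json` recording package
#' version, seed and thresholds. The pipeline is a pure function of
#' (inputs, config, seed).
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `calls`, `experiment_summaries`,
#'   `cohort`, `report` (the parsed JSON content) and `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- config$seed
    windows <- config$windows
    say("simulating traces (seed ", config$seed, ")")
    sim <- run_stage("simulate", simulate_calcium_traces(sim_cfg, windows))
    ts <- sim$traces
  } else {
    say("reading traces")
    ts <- run_stage("read", read_traces(config$traces_csv,
                                        config$background_csv))
    windows <- run_stage("read", read_windows(config$windows_csv))
  }

  say("calibrating")
  ca <- run_stage("calibrate", calibrate_traces(ts, config$params))
  n_cells <- nrow(unique(ca[c("experiment_id", "cell_id")]))

  if (n_cells == 0) {
    report <- list(package = "trpkit",
                   version = as.character(utils::packageVersion("trpkit")),
                   r_version = R.version.string,
                   seed = config$seed, n_cells = 0,
                   note = "no cells in input; nothing to classify")
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("no cells; empty report written")
    return(invisible(list(calls = NULL, experiment_summaries = NULL,
                          cohort = NULL, report = report,
                          out_dir = config$out_dir)))
  }

  say("classifying ", n_cells, " cells")
  calls <- run_stage("classify",
                     classify_responders(ca, windows, config$thresholds,
                                         config$agonist))
  summaries <- run_stage("summarize", summarize_experiments(calls))
  cohort <- run_stage("pool", pool_cohort(summaries))

  write_calcium(ca, file.path(config$out_dir, "calcium.csv"))
  write_calls(calls, file.path(config$out_dir, "calls.csv"))
  utils::write.csv(summaries,
                   file.path(config$out_dir, "experiment_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(cohort),
                   file.path(config$out_dir, "cohort_summary.csv"),
                   row.names = FALSE)

  report <- list(
    package = "trpkit",
    version = as.character(utils::packageVersion("trpkit")),
    r_version = R.version.string,
    seed = config$seed,
    thresholds = unclass(config$thresholds),
    calibration = unclass(config$params),
    n_cells = n_cells,
    n_excluded = sum(calls$excluded),
    cohort = as.data.frame(cohort)
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("report written to ", config$out_dir)
  invisible(list(calls = calls, experiment_summaries = summaries,
                 cohort = cohort, report = report, out_dir = config$out_dir))
}

#' Serialize / restore a pipeline configuration as YAML
#'
#' Scalar fields round-trip losslessly; the windows table is stored
#' inline.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- list(
    traces_csv = config$traces_csv, background_csv = config$background_csv,
    windows_csv = config$windows_csv,
    simulate = if (!is.null(config$simulate)) {
      unclass(config$simulate[setdiff(names(config$simulate), "params")])
    },
    windows = lapply(seq_len(nrow(config$windows)), function(i) {
      as.list(config$windows[i, c("label", "agonist", "t_start", "t_end")])
    }),
    params = unclass(config$params),
    thresholds = unclass(config$thresholds),
    agonist = config$agonist, seed = config$seed, out_dir = config$out_dir
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  windows <- do.call(rbind, lapply(obj$windows, as.data.frame))
  windows <- protocol_windows(windows$label, windows$t_start,
                              windows$t_end, windows$agonist)
  sim <- NULL
  if (!is.null(obj$simulate)) {
    sim <- do.call(trace_sim_config,
                   c(obj$simulate[!vapply(obj$simulate, is.null, logical(1))],
                     list(params = do.call(calibration_params, obj$params))))
  }
  pipeline_config(
    traces_csv = obj$traces_csv, background_csv = obj$background_csv,
    windows_csv = obj$windows_csv, simulate = sim, windows = windows,
    params = do.call(calibration_params, obj$params),
    thresholds = do.call(responder_thresholds, obj$thresholds),
    agonist = obj$agonist, seed = obj$seed, out_dir = obj$out_dir
  )
}
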