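#' Pipeline run configuration
#'
#' Collects the tunable parameters of the end-to-end workflow with their
#' defaults: aortic inlet pressure 100 mmHg, blood viscosity 0.0035 Pa·s,
#' calibration tolerance 1% (the intraoperative calibration criterion),
#' interval variability 15% (the upper probe margin), HABR gain 0
#' (physics-only, conservative prediction).
#'
#' @param inlet_pressure aortic pressure, mmHg.
#' @param viscosity blood viscosity, Pa·s.
#' @param tolerance calibration tolerance (fraction).
#' @param variability prediction-interval half-width (fraction).
#' @param habr_gain HABR gain for clamp scenarios.
#' @param seed integer seed recorded with every run.
#' @param output_dir optional output directory.
#' @param log_level one of `"quiet"`, `"info"`.
#' @return a `run_config` list.
#' @export
run_config <- function(inlet_pressure = 100, viscosity = 0.0035,
                       tolerance = 0.01, variability = 0.15, habr_gain = 0,
                       seed = 1L, output_dir = NULL, log_level = "info") {
  cfg <- list(inlet_pressure = as.numeric(inlet_pressure),
              viscosity = as.numeric(viscosity),
              tolerance = as.numeric(tolerance),
              variability = as.numeric(variability),
              habr_gain = as.numeric(habr_gain), seed = as.integer(seed),
              output_dir = output_dir,
              log_level = match.arg(log_level, c("quiet", "info")))
  for (f in c("inlet_pressure", "viscosity", "tolerance"))
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      hf_error("domain_error", paste0("config field '", f, "' must be > 0"))
  if (cfg$variability < 0 || cfg$variability > 0.5)
    hf_error("domain_error", "config variability must lie in [0, 0.5]")
  if (cfg$habr_gain < 0) hf_error("domain_error", "config habr_gain must be >= 0")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, j)
}

.log_kv <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  kv <- list(...)
  message(paste(names(kv), unlist(lapply(kv, format)), sep = "=", collapse = " "))
}

#' Run the full prediction workflow for one patient
#'
#' Stages: calibrate the outlet resistances to the baseline measurements;
#' solve baseline, GDA-clamp and CHA-clamp scenarios; attach
#' probe-variability prediction intervals and reversal flags; if post-clamp
#' measurements are available, score the predictions (relative error,
#' margin over the predicted minimum, range membership). Deterministic:
#' identical inputs and config give identical outputs.
#'
#' @param network an [arterial_network()] or path to a network JSON.
#' @param measurements measurement data.frame (see [read_measurements()])
#'   or path to a measurements CSV; baseline rows drive calibration,
#'   post-clamp rows are used only for validation.
#' @param config a [run_config()].
#' @param output_dir directory for prediction/flow CSVs, the calibration
#'   report (JSON) and a `run_log.txt`; defaults to `config$output_dir`
#'   (no files written when `NULL`).
#' @return list of class `pipeline_result`: `calibration` report,
#'   calibrated `network`, per-scenario `solutions`, `predictions`
#'   data.frame and (possibly empty) `validation` data.frame.
#' @export
run_pipeline <- function(network, measurements, config = run_config(),
                         output_dir = config$output_dir) {
  if (is.character(network)) network <- read_network(network)
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  meas <- .as_measurements(measurements)
  network$inlet$pressure <- config$inlet_pressure
  network$viscosity <- config$viscosity
  .log_kv(config, stage = "config", inlet_pressure = config$inlet_pressure,
          viscosity = config$viscosity, tolerance = config$tolerance,
          variability = config$variability, habr_gain = config$habr_gain,
          seed = config$seed, version = as.character(packageVersion("hepaflow")))

  cal <- calibrate_outlets(network, meas, tolerance = config$tolerance)
  if (!cal$report$converged)
    hf_error("calibration_failed",
             paste0("stage 'calibrate': no convergence within tolerance (max mismatch ",
                    format(max(cal$report$mismatch), digits = 3), ")"))
  .log_kv(config, stage = "calibrate", iterations = cal$report$iterations,
          max_mismatch = max(cal$report$mismatch))

  predictions <- predict_scenarios(cal$network, variability = config$variability,
                                   habr_gain = config$habr_gain)
  sols <- attr(predictions, "solutions")

  post <- meas[!is.null(meas$scenario) & meas$scenario %in% c("clamp_GDA", "clamp_CHA"), ,
               drop = FALSE]
  validation <- NULL
  if (nrow(post)) {
    rows <- lapply(seq_len(nrow(post)), function(i) {
      sc <- post$scenario[i]; br <- post$branch[i]
      p <- predictions[predictions$scenario == sc & predictions$branch == br, ]
      if (!nrow(p)) return(NULL)
      data.frame(scenario = sc, branch = br, real = post$flow[i],
                 predicted = p$predicted_flow,
                 interval_min = p$interval_min, interval_max = p$interval_max,
                 error_pct = relative_error(p$predicted_flow, post$flow[i]),
                 in_range = post$flow[i] >= p$interval_min & post$flow[i] <= p$interval_max,
                 stringsAsFactors = FALSE)
    })
    validation <- do.call(rbind, rows)
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(predictions, file.path(output_dir, "predictions.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      lapply(unclass(cal$report), function(x) if (is.numeric(x)) as.list(x) else x),
      file.path(output_dir, "calibration_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (sc in names(sols))
      write_flow_csv(sols[[sc]], file.path(output_dir, paste0("flows_", sc, ".csv")),
                     file.path(output_dir, paste0("pressures_", sc, ".csv")))
    if (!is.null(validation))
      write.csv(validation, file.path(output_dir, "validation.csv"),
                row.names = FALSE, quote = FALSE)
    log_lines <- c(
      paste0("package_version=", packageVersion("hepaflow")),
      paste0(names(unclass(config)), "=",
             vapply(unclass(config), function(x) paste(format(x), collapse = ","),
                    character(1))),
      paste0("calibration_iterations=", cal$report$iterations),
      paste0("calibration_max_mismatch=", format(max(cal$report$mismatch))))
    writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  }

  structure(list(calibration = cal$report, network = cal$network,
                 solutions = sols, predictions = predictions,
                 validation = validation, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$calibration)
  cat("  predictions:\n")
  print(x$predictions, row.names = FALSE, digits = 4)
  if (!is.null(x$validation)) {
    cat("  validation against measured post-clamp flows:\n")
    print(x$validation, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
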