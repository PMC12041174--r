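# JSON schema of the network interchange format. Field names carry their
# units; unknown fields are rejected so silently mislabelled inputs fail
# loudly.
.SCHEMA <- list(
  top      = c("variant", "viscosity_pa_s", "inlet", "segments", "outlets", "clamped"),
  required = c("variant", "viscosity_pa_s", "inlet", "segments", "outlets"),
  inlet    = c("node", "pressure_mmHg"),
  segment  = c("id", "name", "proximal", "distal", "radius_mm", "length_mm",
               "area_reduction", "stenosis_length_mm"),
  segment_required = c("id", "name", "proximal", "distal", "radius_mm", "length_mm"),
  outlet   = c("node", "resistance_mmHg_min_per_ml", "compliance_ml_per_mmHg",
               "reference_pressure_mmHg"))

.check_fields <- function(have, allowed, required, where) {
  unknown <- setdiff(have, allowed)
  if (length(unknown))
    hf_error("schema_error", paste0("unknown field '", where, ".", unknown[1], "'"))
  missing <- setdiff(required, have)
  if (length(missing))
    hf_error("schema_error", paste0("missing field '", where, ".", missing[1], "'"))
}

#' Read an arterial network from its JSON interchange format
#'
#' The schema is strict: unknown fields are rejected with a field-path
#' error, missing required fields likewise, and the assembled network must
#' pass [validate_network()]. [write_network()] followed by
#' `read_network()` round-trips all declared fields.
#'
#' @param path JSON file path.
#' @return an [arterial_network()].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) hf_error("io_error", paste0("no such file: ", path))
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  .check_fields(names(j), .SCHEMA$top, .SCHEMA$required, "network")
  .check_fields(names(j$inlet), .SCHEMA$inlet, .SCHEMA$inlet, "inlet")
  segs <- as.data.frame(j$segments, stringsAsFactors = FALSE)
  .check_fields(names(segs), .SCHEMA$segment, .SCHEMA$segment_required, "segments")
  outs <- as.data.frame(j$outlets, stringsAsFactors = FALSE)
  .check_fields(names(outs), .SCHEMA$outlet, .SCHEMA$outlet, "outlets")
  seg <- data.frame(id = segs$id, name = segs$name, proximal = segs$proximal,
                    distal = segs$distal, radius = as.numeric(segs$radius_mm),
                    length = as.numeric(segs$length_mm),
                    area_reduction = as.numeric(segs$area_reduction %||% 0),
                    stenosis_length = as.numeric(segs$stenosis_length_mm %||% 0),
                    stringsAsFactors = FALSE)
  out <- data.frame(node = outs$node,
                    resistance = as.numeric(outs$resistance_mmHg_min_per_ml),
                    compliance = as.numeric(outs$compliance_ml_per_mmHg),
                    reference_pressure = as.numeric(outs$reference_pressure_mmHg),
                    stringsAsFactors = FALSE)
  net <- arterial_network(seg, list(node = j$inlet$node,
                                    pressure = as.numeric(j$inlet$pressure_mmHg)),
                          out, variant = j$variant,
                          viscosity = as.numeric(j$viscosity_pa_s),
                          clamped = unlist(j$clamped) %||% character())
  diags <- validate_network(net)
  if (length(diags))
    hf_error("invalid_network", paste("network file fails validation:",
                                      paste(diags, collapse = "; ")))
  net
}

#' @rdname read_network
#' @param network an [arterial_network()] to serialise.
#' @export
write_network <- function(network, path) {
  seg <- network$segments
  out <- network$outlets
  obj <- list(
    variant = network$variant,
    viscosity_pa_s = network$viscosity,
    inlet = list(node = network$inlet$node, pressure_mmHg = network$inlet$pressure),
    segments = data.frame(id = seg$id, name = seg$name, proximal = seg$proximal,
                          distal = seg$distal, radius_mm = seg$radius,
                          length_mm = seg$length, area_reduction = seg$area_reduction,
                          stenosis_length_mm = seg$stenosis_length,
                          stringsAsFactors = FALSE),
    outlets = data.frame(node = out$node,
                         resistance_mmHg_min_per_ml = out$resistance,
                         compliance_ml_per_mmHg = out$compliance,
                         reference_pressure_mmHg = out$reference_pressure,
                         stringsAsFactors = FALSE),
    clamped = as.list(network$clamped))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.MEAS_COLS <- c("patient_id", "scenario", "branch", "flow_ml_min", "variability")

#' Read or write branch-flow measurements (CSV)
#'
#' CSV dialect: comma, dot decimal, UTF-8, header row with exactly the
#' columns `patient_id, scenario, branch, flow_ml_min, variability`.
#' Mislabelled columns (wrong units in the header) are rejected.
#'
#' @param path CSV path.
#' @return data.frame with columns `patient_id`, `scenario`, `branch`,
#'   `flow` (ml/min), `variability`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) hf_error("io_error", paste0("no such file: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), .MEAS_COLS))
    hf_error("unit_label_error", paste0(
      "measurement CSV must have columns ", paste(.MEAS_COLS, collapse = ", "),
      " (got: ", paste(names(df), collapse = ", "), ")"))
  names(df)[names(df) == "flow_ml_min"] <- "flow"
  .as_measurements(df)
}

#' @rdname read_measurements
#' @param measurements data.frame as returned by [generate_patient()]
#'   (`$measurements`) or [read_measurements()].
#' @export
write_measurements <- function(measurements, path) {
  m <- .as_measurements(measurements)
  out <- data.frame(patient_id = m$patient_id %||% NA_character_,
                    scenario = m$scenario %||% "baseline",
                    branch = m$branch, flow_ml_min = m$flow,
                    variability = m$variability %||% NA_real_)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise a flow solution to CSV
#'
#' Writes the per-segment signed flows (and optionally nodal pressures)
#' with the scenario name recorded in a leading comment line.
#'
#' @param solution a `flow_solution`.
#' @param path output CSV for flows (`segment_id, name, flow_ml_min`).
#' @param pressures_path optional CSV for pressures
#'   (`node_id, pressure_mmHg`).
#' @export
write_flow_csv <- function(solution, path, pressures_path = NULL) {
  con <- file(path, "w")
  writeLines(paste0("# scenario: ", solution$scenario), con)
  df <- data.frame(segment_id = names(solution$segment_flows),
                   name = unname(solution$names_by_id[names(solution$segment_flows)]),
                   flow_ml_min = unname(solution$segment_flows))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  close(con)
  if (!is.null(pressures_path)) {
    con <- file(pressures_path, "w")
    writeLines(paste0("# scenario: ", solution$scenario), con)
    write.csv(data.frame(node_id = names(solution$node_pressures),
                         pressure_mmHg = unname(solution$node_pressures)),
              con, row.names = FALSE, quote = FALSE)
    close(con)
  }
  invisible(path)
}
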