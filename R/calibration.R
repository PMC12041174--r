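#' Infer the baseline proper hepatic artery flow
#'
#' At the GDA bifurcation the common hepatic inflow splits into the proper
#' hepatic and gastroduodenal branches, so with antegrade (Michels type I)
#' baseline flow conservation gives `PHA0 = CHA - GDA`. A measured GDA flow
#' exceeding the CHA flow is nonphysical for antegrade anatomy and signals
#' celiac-trunk stenosis with reversed GDA flow; that case must go through
#' the stenosis pathway instead.
#'
#' @param cha_flow measured baseline common hepatic artery flow, ml/min.
#' @param gda_flow measured baseline gastroduodenal artery flow, ml/min
#'   (negative if reversed toward the liver).
#' @return inferred baseline PHA flow, ml/min.
#' @export
#' @examples
#' infer_pha0(331, 60) # 271
infer_pha0 <- function(cha_flow, gda_flow) {
  if (!is.finite(cha_flow) || !is.finite(gda_flow))
    hf_error("domain_error", "flows must be finite numbers (ml/min)")
  if (gda_flow > cha_flow)
    hf_error("nonphysical_baseline", paste0(
      "baseline GDA flow (", gda_flow, ") exceeds CHA flow (", cha_flow,
      "): nonphysical for antegrade Michels I anatomy; if the patient has a ",
      "celiac-trunk stenosis with reversed GDA flow, use the CELIAC_STENOSIS variant"))
  cha_flow - gda_flow
}

# coerce measurement inputs (data.frame with at least branch + flow, flow
# possibly labelled flow_ml_min as in the CSV interface)
.as_measurements <- function(measurements) {
  m <- as.data.frame(measurements, stringsAsFactors = FALSE)
  if (!is.null(m$flow_ml_min) && is.null(m$flow)) m$flow <- m$flow_ml_min
  if (is.null(m$branch) || is.null(m$flow))
    hf_error("schema_error", "measurements need 'branch' and 'flow' (ml/min) columns")
  if (!is.null(m$variability) &&
      any(is.finite(m$variability) & (m$variability < 0 | m$variability > 0.5)))
    hf_error("domain_error", "measurement variability must lie in [0, 0.5]")
  m
}

# Tuning targets, one per outlet-controllable branch. When CHA and GDA are
# both measured the PHA outlet is tuned to the inferred PHA0 = CHA - GDA
# (the measured PHA, if any, is kept for validation, not for tuning).
.calibration_targets <- function(meas) {
  f <- setNames(meas$flow, meas$branch)
  targets <- numeric()
  for (b in intersect(c("GDA", "SA", "SMA", "RHA"), names(f))) targets[b] <- f[[b]]
  if ("CHA" %in% names(f)) {
    if (!"GDA" %in% names(f))
      hf_error("insufficient_measurements",
               "a CHA target needs a GDA measurement to infer the PHA target")
    targets["PHA"] <- infer_pha0(f[["CHA"]], f[["GDA"]])
  } else if ("PHA" %in% names(f)) {
    targets["PHA"] <- f[["PHA"]]
  }
  targets
}

# outlet node controlling a named branch: the outlet at (or in an unbranched
# chain below) the branch segment's distal node
.outlet_node_for_branch <- function(network, branch) {
  seg <- network$segments
  i <- which(seg$name == branch)
  if (length(i) != 1L)
    hf_error("missing_branch", paste0("no segment named '", branch, "' in the network"))
  node <- seg$distal[i]
  repeat {
    if (node %in% network$outlets$node) return(node)
    ch <- which(seg$proximal == node)
    if (length(ch) != 1L)
      hf_error("uncontrollable_branch",
               paste0("branch '", branch, "' has no dedicated outlet to tune"))
    node <- seg$distal[ch]
  }
}

#' Calibrate outlet resistances to measured branch flows
#'
#' Iteratively rescales each measured branch's outlet resistance by the
#' damped multiplicative factor `(Q_sim / Q_target)^damping` until every
#' target branch's simulated flow is within `tolerance` of its measurement
#' (the 1% default is the calibration criterion used intraoperatively,
#' negligible against the 10-15% probe error), or `max_iterations` is
#' reached. Geometry is never altered: only outlet resistances move, and
#' only those behind measured branches; unmeasured beds (splenic, SMA) keep
#' their template values. Compliances are unidentifiable under steady flow
#' and are left untouched. Deterministic for fixed inputs.
#'
#' @param network a valid [arterial_network()].
#' @param measurements data.frame with columns `branch` and `flow` (ml/min;
#'   `flow_ml_min` also accepted); rows with a `scenario` column are
#'   filtered to `"baseline"`. At least two distinct branches are required.
#' @param tolerance maximum relative mismatch accepted per branch.
#' @param max_iterations iteration cap.
#' @param damping exponent of the multiplicative update, in (0, 1].
#' @return list with `network` (calibrated copy) and `report`, a
#'   `calibration_report` carrying `iterations`, `converged`, the final
#'   per-branch relative `mismatch` and the final outlet `resistances`.
#' @export
#' @examples
#' meas <- data.frame(branch = c("CHA", "GDA"), flow = c(331, 60))
#' cal <- calibrate_outlets(build_template("MICHELS_I"), meas)
#' branch_flow(solve_steady(cal$network), "PHA") # ~271
calibrate_outlets <- function(network, measurements, tolerance = 0.01,
                              max_iterations = 200, damping = 0.5) {
  meas <- .as_measurements(measurements)
  if (!is.null(meas$scenario)) meas <- meas[is.na(meas$scenario) | meas$scenario == "baseline", , drop = FALSE]
  if (anyDuplicated(meas$branch))
    hf_error("schema_error", "duplicate baseline measurement for a branch")
  if (length(unique(meas$branch)) < 2L)
    hf_error("insufficient_measurements", "calibration needs measurements on at least two branches")
  if (tolerance <= 0 || damping <= 0 || damping > 1)
    hf_error("domain_error", "tolerance must be > 0 and damping in (0, 1]")

  targets <- .calibration_targets(meas)
  if (!length(targets))
    hf_error("insufficient_measurements", "no outlet-controllable branch among the measurements")
  if (any(abs(targets) < 1e-9))
    hf_error("infeasible_targets", "a zero branch-flow target cannot be met by a finite outlet resistance")
  onodes <- vapply(names(targets), function(b) .outlet_node_for_branch(network, b), character(1))
  oidx <- match(onodes, network$outlets$node)

  # measured CHA participates in the convergence check even though the PHA
  # outlet is the tuned parameter
  check <- targets
  has_cha <- "CHA" %in% meas$branch
  if (has_cha) check["CHA"] <- meas$flow[match("CHA", meas$branch)]

  net <- network
  sim_of <- function(sol) vapply(names(check), function(b) branch_flow(sol, b), numeric(1))
  converged <- FALSE
  iterations <- 0L
  mism <- NULL
  for (it in 0:max_iterations) {
    sol <- solve_steady(net)
    sim <- sim_of(sol)
    mism <- abs(sim / check - 1)
    iterations <- it
    if (max(mism) <= tolerance) { converged <- TRUE; break }
    if (it == max_iterations) break
    ratio <- (sim / check)[names(targets)]
    # transient sign mismatch (e.g. a perturbed start reverses a collateral):
    # steer the outlet resistance toward the target's sign — more draw
    # (lower R) pushes the feeding branch positive, less draw negative
    bad <- !is.finite(ratio) | ratio <= 0
    ratio[bad] <- ifelse(targets[bad] > 0, 0.5, 2)
    net$outlets$resistance[oidx] <- net$outlets$resistance[oidx] * ratio^damping
    if (any(net$outlets$resistance[oidx] < 1e-9 | net$outlets$resistance[oidx] > 1e9))
      hf_error("infeasible_targets",
               "targets are jointly infeasible at this inlet pressure (outlet resistance left [1e-9, 1e9])")
  }
  report <- structure(
    list(iterations = iterations, converged = converged, tolerance = tolerance,
         mismatch = mism, targets = check,
         resistances = setNames(net$outlets$resistance, net$outlets$node)),
    class = "calibration_report")
  list(network = net, report = report)
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("<calibration_report>", if (x$converged) "converged" else "NOT converged",
      "after", x$iterations, "iterations (tolerance", x$tolerance, ")\n")
  cat("  per-branch relative mismatch:\n")
  print(round(x$mismatch, 6))
  invisible(x)
}
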