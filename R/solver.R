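#' Solve steady flows and pressures on an arterial network
#'
#' Nodal (Kirchhoff) analysis of the resistance network: at every node not
#' held at the inlet pressure, segment flows `(P_prox - P_dist)/R_seg` and
#' the outlet drain `(P_node - P_ref)/R_out` balance exactly. Windkessel
#' compliances are inert at steady state, so outlets act as resistors to
#' their reference (venous) pressure. Clamped segments are removed from the
#' system, which enforces an exact zero flow rather than a large-resistance
#' approximation. The linear system is solved by a direct dense method:
#' the solution is deterministic and bit-reproducible.
#'
#' @param network a valid [arterial_network()].
#' @param scenario label stored on the returned solution.
#' @return an object of class `flow_solution`: named `segment_flows`
#'   (ml/min, positive = proximal to distal), `node_pressures` (mmHg),
#'   `inlet_flow`, `scenario` and `residual` (max absolute nodal imbalance,
#'   ml/min). Nodes unreachable from the inlet (possible only after
#'   clamping) get `NA` pressure and zero flows.
#' @export
#' @examples
#' sol <- solve_steady(build_template("MICHELS_I"))
#' sol$segment_flows
solve_steady <- function(network, scenario = "baseline") {
  diags <- validate_network(network)
  if (length(diags))
    hf_error("invalid_network", paste("invalid network:", paste(diags, collapse = "; ")))
  seg <- network$segments
  out <- network$outlets
  inlet <- network$inlet
  active <- !(seg$id %in% network$clamped)
  res <- .segment_resistances(seg, network$viscosity)
  g <- ifelse(active, 1 / res, 0)

  nodes <- .all_nodes(network)
  # reachability from the inlet through unclamped segments only
  reach <- inlet$node
  repeat {
    nxt <- unique(c(seg$distal[active & seg$proximal %in% reach],
                    seg$proximal[active & seg$distal %in% reach]))
    nxt <- setdiff(nxt, reach)
    if (!length(nxt)) break
    reach <- c(reach, nxt)
  }
  if (!any(out$node %in% reach))
    hf_error("no_open_path", "no outlet is reachable from the inlet; the network is fully clamped")

  unknown <- setdiff(reach, inlet$node)
  m <- length(unknown)
  idx <- setNames(seq_len(m), unknown)
  A <- matrix(0, m, m, dimnames = list(unknown, unknown))
  b <- setNames(numeric(m), unknown)
  for (i in seq_len(nrow(seg))) {
    if (!active[i]) next
    p <- seg$proximal[i]; q <- seg$distal[i]; gi <- g[i]
    if (!(p %in% reach)) next
    for (end in list(c(p, q), c(q, p))) {
      a <- end[1]; o <- end[2]
      if (a %in% unknown) {
        A[idx[a], idx[a]] <- A[idx[a], idx[a]] + gi
        if (o %in% unknown) {
          A[idx[a], idx[o]] <- A[idx[a], idx[o]] - gi
        } else {
          b[idx[a]] <- b[idx[a]] + gi * inlet$pressure
        }
      }
    }
  }
  for (i in seq_len(nrow(out))) {
    nd <- out$node[i]
    if (!nd %in% unknown) next
    go <- 1 / out$resistance[i]
    A[idx[nd], idx[nd]] <- A[idx[nd], idx[nd]] + go
    b[idx[nd]] <- b[idx[nd]] + go * out$reference_pressure[i]
  }
  p_unknown <- if (m) drop(solve(A, b)) else numeric(0)

  pressures <- setNames(rep(NA_real_, length(nodes)), nodes)
  pressures[inlet$node] <- inlet$pressure
  pressures[unknown] <- p_unknown

  flows <- setNames(numeric(nrow(seg)), seg$id)
  live <- active & seg$proximal %in% reach
  flows[live] <- g[live] * (pressures[seg$proximal[live]] - pressures[seg$distal[live]])

  # residual: nodal imbalance including the outlet drain, over solved nodes
  imbalance <- setNames(numeric(m), unknown)
  for (i in seq_len(nrow(seg))) {
    p <- seg$proximal[i]; q <- seg$distal[i]
    if (p %in% unknown) imbalance[p] <- imbalance[p] - flows[seg$id[i]]
    if (q %in% unknown) imbalance[q] <- imbalance[q] + flows[seg$id[i]]
  }
  for (i in seq_len(nrow(out))) {
    nd <- out$node[i]
    if (nd %in% unknown)
      imbalance[nd] <- imbalance[nd] - (pressures[nd] - out$reference_pressure[i]) / out$resistance[i]
  }
  inlet_flow <- sum(flows[seg$id[seg$proximal == inlet$node]]) -
    sum(flows[seg$id[seg$distal == inlet$node]])

  structure(
    list(segment_flows = flows,
         node_pressures = pressures,
         inlet_flow = inlet_flow,
         scenario = scenario,
         residual = if (m) max(abs(imbalance)) else 0,
         names_by_id = setNames(seg$name, seg$id)),
    class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution> scenario:", x$scenario, "| residual:",
      format(x$residual, digits = 3), "ml/min\n")
  df <- data.frame(segment = names(x$segment_flows),
                   name = unname(x$names_by_id[names(x$segment_flows)]),
                   flow_ml_min = round(unname(x$segment_flows), 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Flow through a named branch
#'
#' Looks up the signed flow (ml/min) of the segment whose anatomical name
#' matches `branch` (falling back to segment id). Positive flow runs
#' proximal to distal along the segment's declared orientation; the GDA is
#' oriented bifurcation -> arcade, so reversed (hepatopetal) GDA flow is
#' negative.
#'
#' @param solution a `flow_solution`.
#' @param branch anatomical name (e.g. `"CHA"`, `"GDA"`, `"PHA"`) or id.
#' @return signed flow in ml/min.
#' @export
branch_flow <- function(solution, branch) {
  ids <- names(solution$names_by_id)[solution$names_by_id == branch]
  if (!length(ids) && branch %in% names(solution$segment_flows)) ids <- branch
  if (!length(ids))
    hf_error("missing_branch", paste0("no segment named '", branch, "' in this solution"))
  if (length(ids) > 1)
    hf_error("ambiguous_branch", paste0("branch name '", branch, "' matches several segments"))
  unname(solution$segment_flows[ids])
}

#' Clamp a vessel segment
#'
#' Returns a copy of the network with the segment added to the clamped set;
#' [solve_steady()] then removes it from the system, enforcing exactly zero
#' flow (the surgical bulldog-clamp idealisation). Clamping twice is
#' idempotent.
#'
#' @param network an [arterial_network()].
#' @param segment_id segment id or anatomical name.
#' @return the clamped network.
#' @export
clamp_segment <- function(network, segment_id) {
  seg <- network$segments
  id <- if (segment_id %in% seg$id) segment_id else seg$id[seg$name == segment_id]
  if (length(id) != 1L)
    hf_error("unknown_segment", paste0("no segment '", segment_id, "' to clamp"))
  network$clamped <- unique(c(network$clamped, id))
  network
}
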