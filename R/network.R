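# mmHg·min/ml per Pa·s/m^3: 1 mmHg = 133.322 Pa, 1 m^3/s = 6e7 ml/min
.PA_S_M3_TO_MMHG_MIN_ML <- 1 / (133.322 * 6e7)

#' Hagen-Poiseuille resistance of a cylindrical vessel segment
#'
#' Computes `R = 8 mu L / (pi r^4)` in SI units and converts the result to
#' the clinical unit system used throughout the package (mmHg·min/ml).
#' This is the segment-level replacement for a full 3D viscous solve:
#' laminar, fully developed, Newtonian flow in a straight rigid tube.
#'
#' @param radius lumen radius in mm; must be > 0.
#' @param length segment length in mm; must be > 0.
#' @param viscosity dynamic blood viscosity in Pa·s (default 0.0035, a
#'   standard whole-blood value; only flow ratios matter after calibration).
#' @return resistance in mmHg·min/ml (strictly positive).
#' @export
#' @examples
#' poiseuille_resistance(2, 30) # ~2.09e-3 mmHg·min/ml
poiseuille_resistance <- function(radius, length, viscosity = 0.0035) {
  if (any(!is.finite(radius)) || any(radius <= 0))
    hf_error("domain_error", "radius must be a positive finite number (mm)")
  if (any(!is.finite(length)) || any(length <= 0))
    hf_error("domain_error", "length must be a positive finite number (mm)")
  if (any(!is.finite(viscosity)) || any(viscosity <= 0))
    hf_error("domain_error", "viscosity must be a positive finite number (Pa·s)")
  r_m <- radius * 1e-3
  l_m <- length * 1e-3
  r_si <- 8 * viscosity * l_m / (pi * r_m^4)
  r_si * .PA_S_M3_TO_MMHG_MIN_ML
}

#' Resistance of a vessel segment, including a stenotic sub-length
#'
#' A stenosis is modelled as a series Poiseuille element over
#' `stenosis_length` with effective radius `r * sqrt(1 - area_reduction)`
#' (an area reduction `a` shrinks the radius by `sqrt(1 - a)`); the healthy
#' remainder keeps the nominal radius. With `area_reduction = 0` this equals
#' [poiseuille_resistance()] over the full length.
#'
#' @param segment a list or one-row data.frame with fields `radius`, `length`
#'   (mm) and optionally `area_reduction` (fraction in \[0,1)) and
#'   `stenosis_length` (mm, <= `length`).
#' @param viscosity dynamic viscosity in Pa·s.
#' @return resistance in mmHg·min/ml.
#' @export
segment_resistance <- function(segment, viscosity = 0.0035) {
  segment <- as.list(segment)
  ar <- segment$area_reduction %||% 0
  sl <- segment$stenosis_length %||% 0
  if (!is.finite(ar) || ar < 0 || ar >= 1)
    hf_error("domain_error", "area_reduction must lie in [0, 1)")
  if (!is.finite(sl) || sl < 0 || sl > segment$length)
    hf_error("domain_error", "stenosis_length must lie in [0, length]")
  if (ar == 0 || sl == 0)
    return(poiseuille_resistance(segment$radius, segment$length, viscosity))
  r_sten <- poiseuille_resistance(segment$radius * sqrt(1 - ar), sl, viscosity)
  if (sl >= segment$length) return(r_sten)
  r_sten + poiseuille_resistance(segment$radius, segment$length - sl, viscosity)
}

# vectorised over the rows of a segment data.frame
.segment_resistances <- function(segments, viscosity) {
  vapply(seq_len(nrow(segments)), function(i)
    segment_resistance(segments[i, , drop = FALSE], viscosity), numeric(1))
}

.VARIANTS <- c("MICHELS_I", "MICHELS_VIII_REPLACED_RHA", "CELIAC_STENOSIS", "CUSTOM")

#' Construct an arterial network
#'
#' Low-level constructor; most users will start from [build_template()] or
#' [read_network()]. The network is a directed graph of vessel segments
#' (oriented proximal -> distal) with a single fixed-pressure inlet and
#' resistive (steady two-parameter Windkessel) outlets.
#'
#' @param segments data.frame with columns `id`, `name`, `proximal`,
#'   `distal`, `radius` (mm), `length` (mm), `area_reduction`,
#'   `stenosis_length` (mm).
#' @param inlet list with `node` and `pressure` (mmHg).
#' @param outlets data.frame with columns `node`, `resistance`
#'   (mmHg·min/ml), `compliance` (ml/mmHg; inert under steady flow) and
#'   `reference_pressure` (mmHg, distal drainage pressure).
#' @param variant one of `r paste(.VARIANTS, collapse = ", ")`.
#' @param viscosity dynamic viscosity, Pa·s.
#' @param clamped character vector of clamped segment ids (zero-flow).
#' @return an object of class `arterial_network`.
#' @seealso [validate_network()], [solve_steady()]
#' @export
arterial_network <- function(segments, inlet, outlets, variant = "CUSTOM",
                             viscosity = 0.0035, clamped = character()) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  if (is.null(segments$area_reduction)) segments$area_reduction <- 0
  if (is.null(segments$stenosis_length)) segments$stenosis_length <- 0
  outlets <- as.data.frame(outlets, stringsAsFactors = FALSE)
  if (is.null(outlets$compliance)) outlets$compliance <- 0
  if (is.null(outlets$reference_pressure)) outlets$reference_pressure <- 0
  structure(
    list(segments = segments,
         inlet = list(node = inlet$node, pressure = inlet$pressure),
         outlets = outlets,
         variant = match.arg(variant, .VARIANTS),
         viscosity = viscosity,
         clamped = unique(as.character(clamped))),
    class = "arterial_network")
}

#' @export
print.arterial_network <- function(x, ...) {
  cat("<arterial_network> variant:", x$variant, "\n")
  cat("  segments:", nrow(x$segments),
      paste0("(", paste(x$segments$name, collapse = ", "), ")"), "\n")
  cat("  inlet:", x$inlet$node, "@", x$inlet$pressure, "mmHg |",
      nrow(x$outlets), "outlets | viscosity", x$viscosity, "Pa.s\n")
  if (length(x$clamped)) cat("  clamped:", paste(x$clamped, collapse = ", "), "\n")
  invisible(x)
}

.all_nodes <- function(network)
  unique(c(network$inlet$node, network$segments$proximal, network$segments$distal))

#' Validate an arterial network
#'
#' Checks the structural invariants of the network and returns diagnostics
#' instead of raising: an empty character vector means the network is valid.
#' Each violation yields one named entry, e.g. `"dangling_leaf:<node>"`.
#'
#' Checked invariants: positive geometry; no self-loop segments; stenosis
#' length within the segment; a single inlet that is not also an outlet;
#' outlets on existing nodes, at most one per node, with positive
#' resistance; a connected graph; every leaf node is the inlet or carries
#' exactly one outlet; clamped ids refer to existing segments.
#'
#' @param network an [arterial_network()].
#' @return character vector of diagnostics (empty when valid).
#' @export
validate_network <- function(network) {
  d <- character()
  seg <- network$segments
  out <- network$outlets
  if (length(network$inlet$node) != 1L) d <- c(d, "multiple_inlets")
  if (anyDuplicated(seg$id))
    d <- c(d, paste0("duplicate_segment_id:", unique(seg$id[duplicated(seg$id)])))
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    if (!is.finite(s$radius) || s$radius <= 0) d <- c(d, paste0("bad_segment:", s$id, ":radius"))
    if (!is.finite(s$length) || s$length <= 0) d <- c(d, paste0("bad_segment:", s$id, ":length"))
    if (identical(s$proximal, s$distal)) d <- c(d, paste0("bad_segment:", s$id, ":self_loop"))
    if (!is.finite(s$area_reduction) || s$area_reduction < 0 || s$area_reduction >= 1)
      d <- c(d, paste0("bad_segment:", s$id, ":area_reduction"))
    if (!is.finite(s$stenosis_length) || s$stenosis_length < 0 ||
        (is.finite(s$length) && s$stenosis_length > s$length))
      d <- c(d, paste0("bad_segment:", s$id, ":stenosis_length"))
  }
  nodes <- .all_nodes(network)
  if (anyDuplicated(out$node))
    d <- c(d, paste0("duplicate_outlet:", unique(out$node[duplicated(out$node)])))
  for (i in seq_len(nrow(out))) {
    o <- out[i, ]
    if (!o$node %in% nodes) d <- c(d, paste0("unknown_outlet_node:", o$node))
    if (!is.finite(o$resistance) || o$resistance <= 0) d <- c(d, paste0("bad_outlet:", o$node))
    if (!is.finite(o$compliance) || o$compliance < 0) d <- c(d, paste0("bad_outlet:", o$node))
  }
  if (any(network$inlet$node %in% out$node)) d <- c(d, "inlet_is_outlet")
  if (!all(is.finite(network$inlet$pressure)) || any(network$inlet$pressure <= 0))
    d <- c(d, "bad_inlet_pressure")
  # connectivity (undirected, ignoring clamps: clamping is a scenario, not topology)
  if (nrow(seg) > 0 && length(network$inlet$node) == 1L) {
    reach <- network$inlet$node
    repeat {
      nxt <- unique(c(seg$distal[seg$proximal %in% reach], seg$proximal[seg$distal %in% reach]))
      nxt <- setdiff(nxt, reach)
      if (!length(nxt)) break
      reach <- c(reach, nxt)
    }
    if (!setequal(reach, nodes)) d <- c(d, "disconnected")
    # leaves: degree-1 nodes of the undirected graph
    deg <- table(c(seg$proximal, seg$distal))
    leaves <- names(deg)[deg == 1L]
    for (lf in setdiff(leaves, network$inlet$node)) {
      if (sum(out$node == lf) != 1L) d <- c(d, paste0("dangling_leaf:", lf))
    }
  }
  bad_clamp <- setdiff(network$clamped, seg$id)
  if (length(bad_clamp)) d <- c(d, paste0("unknown_clamped:", bad_clamp))
  d
}

# default template geometry (mm). Per-patient geometry is unavailable from
# imaging here, so these are nominal supramesocolic calibres; calibration of
# the outlet resistances absorbs the residual geometric error.
.template_segments <- function() {
  data.frame(
    id       = c("CT", "SA", "CHA", "PHA", "GDA", "ARCADE", "SMA_T", "SMA"),
    name     = c("CT", "SA", "CHA", "PHA", "GDA", "ARCADE", "SMA_TRUNK", "SMA"),
    proximal = c("aorta", "celiac", "celiac", "bif", "bif", "gda_d", "aorta", "sma_j"),
    distal   = c("celiac", "sa_end", "bif", "pha_end", "gda_d", "sma_j", "sma_j", "sma_end"),
    radius   = c(3.2, 2.6, 2.2, 2.0, 1.8, 1.2, 3.5, 3.0),
    length   = c(25, 40, 35, 30, 25, 50, 40, 50),
    area_reduction  = 0,
    stenosis_length = 0,
    stringsAsFactors = FALSE)
}

# nominal beds sized for ~250/160/40/400/60 ml/min at 100 mmHg drive
.template_outlets <- function() {
  data.frame(
    node = c("sa_end", "pha_end", "gda_d", "sma_end"),
    resistance = c(0.40, 0.625, 2.5, 0.25),
    compliance = 0.5,
    reference_pressure = 0,
    stringsAsFactors = FALSE)
}

#' Build an anatomy template network
#'
#' Templates encode the simplified supramesocolic topology used throughout:
#' aorta -> celiac trunk -> \{splenic bed, common hepatic\}; the common
#' hepatic reaches the GDA bifurcation, which feeds the proper hepatic bed
#' and the GDA; the pancreaticoduodenal arcade is collapsed to a single
#' equivalent segment bridging the distal GDA (where the
#' pancreaticoduodenal/IPDA bed drains) to the SMA, closing the collateral
#' loop between the celiac and mesenteric systems.
#'
#' * `MICHELS_I`: normal anatomy, 4 outlets (splenic, PHA, IPDA bed, SMA).
#' * `MICHELS_VIII_REPLACED_RHA`: adds a replaced right hepatic artery from
#'   the SMA junction with its own outlet.
#' * `CELIAC_STENOSIS`: `MICHELS_I` with an area reduction over a sub-length
#'   of the celiac trunk.
#'
#' @param variant template name (see above).
#' @param geometry_overrides named list: `list(<segment id> = list(radius =,
#'   length =, area_reduction =, stenosis_length =))`; unknown ids error.
#' @param inlet_pressure aortic pressure, mmHg (default 100).
#' @param viscosity blood viscosity, Pa·s.
#' @param area_reduction,stenosis_length stenosis severity (fraction of
#'   lumen area lost) and extent (mm; default 70% of the celiac trunk) for
#'   `CELIAC_STENOSIS`.
#' @param outlet_resistances optional named numeric (node -> mmHg·min/ml)
#'   replacing template outlet resistances.
#' @return a valid [arterial_network()].
#' @export
#' @examples
#' net <- build_template("MICHELS_I")
#' validate_network(net)
build_template <- function(variant = "MICHELS_I", geometry_overrides = NULL,
                           inlet_pressure = 100, viscosity = 0.0035,
                           area_reduction = 0.85, stenosis_length = NULL,
                           outlet_resistances = NULL) {
  variant <- match.arg(variant, setdiff(.VARIANTS, "CUSTOM"))
  seg <- .template_segments()
  out <- .template_outlets()
  if (variant == "MICHELS_VIII_REPLACED_RHA") {
    seg <- rbind(seg, data.frame(
      id = "RHA", name = "RHA", proximal = "sma_j", distal = "rha_end",
      radius = 1.8, length = 35, area_reduction = 0, stenosis_length = 0,
      stringsAsFactors = FALSE))
    out <- rbind(out, data.frame(node = "rha_end", resistance = 1.67,
                                 compliance = 0.5, reference_pressure = 0,
                                 stringsAsFactors = FALSE))
  }
  if (variant == "CELIAC_STENOSIS") {
    i <- match("CT", seg$id)
    seg$area_reduction[i] <- area_reduction
    seg$stenosis_length[i] <- stenosis_length %||% (0.7 * seg$length[i])
  }
  for (id in names(geometry_overrides)) {
    i <- match(id, seg$id)
    if (is.na(i)) hf_error("unknown_segment", paste0("geometry override for absent segment '", id, "'"))
    ov <- geometry_overrides[[id]]
    for (f in names(ov)) {
      if (!f %in% c("radius", "length", "area_reduction", "stenosis_length"))
        hf_error("unknown_field", paste0("unknown geometry field '", f, "' for segment '", id, "'"))
      seg[[f]][i] <- ov[[f]]
    }
  }
  for (nd in names(outlet_resistances)) {
    i <- match(nd, out$node)
    if (is.na(i)) hf_error("unknown_outlet_node", paste0("no outlet at node '", nd, "'"))
    out$resistance[i] <- outlet_resistances[[nd]]
  }
  net <- arterial_network(seg, list(node = "aorta", pressure = inlet_pressure),
                          out, variant = variant, viscosity = viscosity)
  diags <- validate_network(net)
  if (length(diags))
    hf_error("invalid_network", paste("template failed validation:", paste(diags, collapse = "; ")))
  net
}
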