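# truncated multiplicative probe-noise factor: mean 1, sd v/1.96 (so ~95%
# of draws fall within the probe's stated margin v), truncated at +/- 3v
.noise_factor <- function(n, v) {
  if (v == 0) return(rep(1, n))
  vapply(seq_len(n), function(i) {
    repeat {
      x <- rnorm(1, 0, v / 1.96)
      if (abs(x) <= 3 * v) return(1 + x)
    }
  }, numeric(1))
}

#' Generate one synthetic patient
#'
#' Emulates the cohort's measurement protocol without any imaging or
#' intraoperative data: template geometry with seeded per-patient jitter
#' (radii x U(0.9, 1.1), lengths x U(0.85, 1.15)); baseline branch-flow
#' targets drawn inside the cohort's printed ranges (CHA in 150-330 ml/min,
#' GDA in 18-67 ml/min, PHA = CHA - GDA by conservation; RHA in 50-75
#' ml/min for the replaced-RHA variant); ground-truth outlet resistances
#' obtained by calibrating the jittered template tightly to those targets.
#' Unmeasured beds (splenic, SMA) keep template defaults in both the truth
#' and the model network.
#'
#' Post-clamp "real" flows are produced by re-solving the truth network
#' with a hepatic arterial buffer response applied
#' (`habr_gain_true`, drawn U(0.05, 0.35) unless given), so synthetic
#' measured post-clamp PHA flows systematically exceed the physics-only
#' prediction — the regularity observed clinically. Measurements carry
#' truncated multiplicative probe noise (see package vignette). For the
#' stenosis variant the drawn stenosis is applied to the celiac trunk
#' *after* bed calibration, representing a patient with normal peripheral
#' beds behind a stenosed trunk; severe stenosis reverses baseline GDA
#' flow.
#'
#' @param variant `"MICHELS_I"`, `"CELIAC_STENOSIS"` or
#'   `"MICHELS_VIII_REPLACED_RHA"`.
#' @param seed integer seed; the patient is fully reproducible from it.
#' @param noise_variability probe variability fraction in \[0, 0.2\]
#'   (default 0.12, mid probe margin).
#' @param habr_gain_true true biological HABR gain; `NULL` draws it.
#' @param patient_id identifier string.
#' @param area_reduction,stenosis_length celiac stenosis severity/extent
#'   for the stenosis variant (defaults 0.85 over 70% of the trunk).
#' @return an object of class `synthetic_patient`: `truth_network`
#'   (ground-truth resistances), `model_network` (same geometry, template
#'   default outlet resistances — the uncalibrated model a new patient
#'   presents), `truth_flows` (noise-free `flow_solution` per scenario),
#'   `measurements` (noisy data.frame: patient_id, scenario, branch, flow,
#'   variability), plus the seed and the drawn parameters.
#' @export
generate_patient <- function(variant = "MICHELS_I", seed = 1L,
                             noise_variability = 0.12, habr_gain_true = NULL,
                             patient_id = sprintf("SYN%05d", seed),
                             area_reduction = 0.85, stenosis_length = NULL) {
  variant <- match.arg(variant, setdiff(.VARIANTS, "CUSTOM"))
  if (!is.finite(noise_variability) || noise_variability < 0 || noise_variability > 0.2)
    hf_error("domain_error", "noise_variability must lie in [0, 0.2]")
  with_seed(seed, {
    if (is.null(habr_gain_true)) habr_gain_true <- runif(1, 0.05, 0.35)
    truth <- NULL
    targets <- NULL
    for (attempt in 1:5) {
      ids <- if (variant == "MICHELS_VIII_REPLACED_RHA")
        c(.template_segments()$id, "RHA") else .template_segments()$id
      jitter <- lapply(ids, function(id)
        list(radius = runif(1, 0.9, 1.1), length = runif(1, 0.85, 1.15)))
      names(jitter) <- ids
      # build the healthy (unstenosed) geometry and scale it
      net <- build_template(if (variant == "CELIAC_STENOSIS") "MICHELS_I" else variant)
      for (id in ids) {
        i <- match(id, net$segments$id)
        net$segments$radius[i] <- net$segments$radius[i] * jitter[[id]]$radius
        net$segments$length[i] <- net$segments$length[i] * jitter[[id]]$length
      }
      targets <- data.frame(
        branch = c("CHA", "GDA"),
        flow = c(runif(1, 150, 330), runif(1, 18, 67)),
        stringsAsFactors = FALSE)
      if (variant == "MICHELS_VIII_REPLACED_RHA")
        targets <- rbind(targets, data.frame(branch = "RHA", flow = runif(1, 50, 75)))
      truth <- tryCatch(
        calibrate_outlets(net, targets, tolerance = 1e-6, max_iterations = 500),
        hepaflow_error = function(e) NULL)
      if (!is.null(truth) && truth$report$converged) break
      truth <- NULL
    }
    if (is.null(truth))
      hf_error("generation_failed", paste("synthetic patient generation failed for seed", seed))
    truth_net <- truth$network
    if (variant == "CELIAC_STENOSIS") {
      i <- match("CT", truth_net$segments$id)
      truth_net$segments$area_reduction[i] <- area_reduction
      truth_net$segments$stenosis_length[i] <-
        stenosis_length %||% (0.7 * truth_net$segments$length[i])
      # chronic stenosis remodels the collateral route: hypertrophied
      # pancreaticoduodenal arcade and an enlarged GDA section, as seen on
      # imaging of stenosis patients
      truth_net$segments$radius[match("ARCADE", truth_net$segments$id)] <-
        truth_net$segments$radius[match("ARCADE", truth_net$segments$id)] * 1.5
      truth_net$segments$radius[match("GDA", truth_net$segments$id)] <-
        truth_net$segments$radius[match("GDA", truth_net$segments$id)] * 1.3
      truth_net$variant <- "CELIAC_STENOSIS"
    }
    truth_flows <- list(
      baseline  = run_scenario(truth_net, "baseline"),
      clamp_GDA = run_scenario(truth_net, "clamp_GDA", habr_gain = habr_gain_true),
      clamp_CHA = run_scenario(truth_net, "clamp_CHA", habr_gain = habr_gain_true))

    # the model a fresh patient presents: known geometry, template bed values
    model_net <- truth_net
    defaults <- if (variant == "MICHELS_VIII_REPLACED_RHA") {
      rbind(.template_outlets(),
            data.frame(node = "rha_end", resistance = 1.67, compliance = 0.5,
                       reference_pressure = 0, stringsAsFactors = FALSE))
    } else .template_outlets()
    model_net$outlets$resistance <-
      defaults$resistance[match(model_net$outlets$node, defaults$node)]

    protocol <- list(baseline = c("CHA", "GDA", "PHA"),
                     clamp_GDA = c("CHA", "PHA"),
                     clamp_CHA = c("GDA", "PHA"))
    if (variant == "MICHELS_VIII_REPLACED_RHA")
      protocol <- lapply(protocol, c, "RHA")
    meas <- do.call(rbind, lapply(names(protocol), function(sc) {
      br <- protocol[[sc]]
      q <- vapply(br, function(b) branch_flow(truth_flows[[sc]], b), numeric(1))
      data.frame(patient_id = patient_id, scenario = sc, branch = br,
                 flow = q * .noise_factor(length(q), noise_variability),
                 variability = noise_variability,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    structure(
      list(patient_id = patient_id, variant = variant, seed = as.integer(seed),
           noise_variability = noise_variability, habr_gain_true = habr_gain_true,
           truth_network = truth_net, model_network = model_net,
           truth_flows = truth_flows, measurements = meas,
           targets = setNames(targets$flow, targets$branch)),
      class = "synthetic_patient")
  })
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat("<synthetic_patient>", x$patient_id, "|", x$variant, "| seed", x$seed, "\n")
  cat("  habr_gain_true", round(x$habr_gain_true, 3),
      "| noise", x$noise_variability, "\n")
  cat("  truth baseline flows (ml/min):\n")
  q <- x$truth_flows$baseline
  for (b in intersect(c("CHA", "GDA", "PHA", "RHA"), x$truth_network$segments$name))
    cat("   ", b, round(branch_flow(q, b), 1), "\n")
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws `n` patients with per-patient seeds derived reproducibly from the
#' master seed and variants assigned by the mix probabilities.
#'
#' @param n cohort size (>= 1).
#' @param variant_mix named numeric of variant weights, e.g.
#'   `c(MICHELS_I = 0.85, CELIAC_STENOSIS = 0.1,
#'   MICHELS_VIII_REPLACED_RHA = 0.05)`.
#' @param seed master seed.
#' @param noise_variability passed to [generate_patient()].
#' @return list of `synthetic_patient` objects with ids `P001..`.
#' @export
generate_cohort <- function(n, variant_mix = c(MICHELS_I = 1), seed = 1L,
                            noise_variability = 0.12) {
  if (n < 1) hf_error("domain_error", "cohort size must be >= 1")
  bad <- setdiff(names(variant_mix), setdiff(.VARIANTS, "CUSTOM"))
  if (length(bad) || is.null(names(variant_mix)) || any(variant_mix < 0) ||
      sum(variant_mix) <= 0)
    hf_error("domain_error", "variant_mix must be named non-negative weights over known variants")
  with_seed(seed, {
    variants <- sample(names(variant_mix), n, replace = TRUE,
                       prob = variant_mix / sum(variant_mix))
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i)
      generate_patient(variants[i], seed = seeds[i],
                       noise_variability = noise_variability,
                       patient_id = sprintf("P%03d", i)))
  })
}
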