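test_that("a single segment behaves as an Ohmic series circuit", {
  seg <- data.frame(id = "s1", name = "s1", proximal = "n0", distal = "n1",
                    radius = 2, length = 30, area_reduction = 0, stenosis_length = 0,
                    stringsAsFactors = FALSE)
  out <- data.frame(node = "n1", resistance = 0.5, compliance = 0, reference_pressure = 0)
  net <- arterial_network(seg, list(node = "n0", pressure = 100), out)
  r_seg <- segment_resistance(as.list(seg[1, ]), net$viscosity)
  sol <- solve_steady(net)
  expect_equal(branch_flow(sol, "s1"), 100 / (r_seg + 0.5), tolerance = 1e-12)
  # with R_seg + R_out = 1 the flow is exactly 100 ml/min
  out2 <- out; out2$resistance <- 1 - r_seg
  sol2 <- solve_steady(arterial_network(seg, list(node = "n0", pressure = 100), out2))
  expect_equal(branch_flow(sol2, "s1"), 100, tolerance = 1e-12)
})

test_that("nodal solve matches the series-parallel oracle on random trees", {
  for (n_seg in 1:8) {
    for (s in 1:8) {
      net <- random_tree_network(n_seg, seed = 1000 * n_seg + s)
      sol <- solve_steady(net)
      oracle <- sp_oracle_flows(net)
      expect_equal(sol$segment_flows, oracle, tolerance = 1e-9)
      scale <- max(abs(sol$segment_flows), 1)
      expect_lt(sol$residual, 1e-9 * scale)
      expect_equal(sol$inlet_flow, total_outlet_flow(sol, net),
                   tolerance = 1e-9)
    }
  }
})

test_that("flow is conserved and the inlet pressure is honoured on templates", {
  for (v in c("MICHELS_I", "MICHELS_VIII_REPLACED_RHA", "CELIAC_STENOSIS")) {
    net <- build_template(v)
    sol <- solve_steady(net)
    expect_identical(unname(sol$node_pressures[net$inlet$node]), net$inlet$pressure)
    expect_equal(sol$inlet_flow, total_outlet_flow(sol, net), tolerance = 1e-9)
    expect_lt(sol$residual, 1e-9 * max(abs(sol$segment_flows), 1))
  }
})

test_that("clamping enforces an exact zero and redistributes as expected", {
  net <- build_template("MICHELS_I")
  base <- solve_steady(net)
  gcl <- solve_steady(clamp_segment(net, "GDA"))
  expect_identical(branch_flow(gcl, "GDA"), 0)
  expect_gt(branch_flow(gcl, "PHA"), branch_flow(base, "PHA"))
  expect_lt(branch_flow(gcl, "CHA"), branch_flow(base, "CHA"))
  ccl <- solve_steady(clamp_segment(net, "CHA"))
  expect_identical(branch_flow(ccl, "CHA"), 0)
  expect_lt(branch_flow(ccl, "GDA"), 0)           # reversed toward the liver
  expect_equal(branch_flow(ccl, "PHA"), -branch_flow(ccl, "GDA"),
               tolerance = 1e-9)
  # idempotent
  expect_identical(clamp_segment(clamp_segment(net, "GDA"), "GDA")$clamped,
                   clamp_segment(net, "GDA")$clamped)
  expect_error(clamp_segment(net, "XX"), class = "unknown_segment")
})

test_that("a fully clamped network reports no open path", {
  net <- clamp_segment(clamp_segment(build_template("MICHELS_I"), "CT"), "SMA_T")
  expect_error(solve_steady(net), class = "no_open_path")
})

test_that("clamping never raises inlet flow and never starves the sibling branch", {
  pts <- generate_cohort(50, seed = 314, noise_variability = 0)
  for (p in pts) {
    net <- p$truth_network
    base <- solve_steady(net)
    for (target in c("GDA", "SA")) {
      cl <- solve_steady(clamp_segment(net, target))
      expect_lte(cl$inlet_flow, base$inlet_flow + 1e-9)
      sib <- if (target == "GDA") "PHA" else "CHA"
      expect_gte(branch_flow(cl, sib), branch_flow(base, sib) - 1e-9)
    }
  }
})

test_that("increasing celiac stenosis reverses the GDA at some severity", {
  pts <- generate_cohort(20, seed = 99, noise_variability = 0)
  for (p in pts) {
    flows <- cha <- numeric()
    for (a in seq(0, 0.95, by = 0.05)) {
      net <- p$truth_network
      i <- match("CT", net$segments$id)
      net$segments$area_reduction[i] <- a
      net$segments$stenosis_length[i] <- 0.7 * net$segments$length[i]
      s <- solve_steady(net)
      flows <- c(flows, branch_flow(s, "GDA"))
      cha <- c(cha, branch_flow(s, "CHA"))
    }
    expect_gt(flows[1], 0)
    expect_lt(min(flows), 0)                      # sign change occurs
    expect_true(all(diff(cha) < 1e-9))            # CHA decreases monotonically
  }
})

test_that("the Windkessel waveform degenerates correctly and matches an ODE oracle", {
  outlet <- list(resistance = 0.6, compliance = 0, reference_pressure = 5)
  wf <- windkessel_waveform(outlet, amplitude = 300, period = 1, n_cycles = 3)
  expect_equal(wf$pressure_mmHg, 5 + wf$inflow_ml_min * 0.6, tolerance = 1e-12)

  # constant inflow limit: relax to P_ref + Q R with time constant RC
  outlet <- list(resistance = 0.6, compliance = 0.5, reference_pressure = 0)
  wf <- windkessel_waveform(outlet, amplitude = 200, period = 60,
                            n_cycles = 60, systolic_fraction = 1,
                            samples_per_cycle = 50)
  # half-sine over a long period is slowly varying; instead check directly
  # against the quasi-static bound: pressure never exceeds A*R + ref
  expect_lte(max(wf$pressure_mmHg), 200 * 0.6 + 1e-9)

  # ODE oracle: RC = 1 s, period 1 s half-sine pulses
  library(deSolve)
  outlet <- list(resistance = 0.5, compliance = 1 / (0.5 * 60),  # RC = 1 s
                 reference_pressure = 10)
  A <- 300; Ts <- 0.5 / 60  # minutes
  wf <- windkessel_waveform(outlet, amplitude = A, period = 1, n_cycles = 8,
                            samples_per_cycle = 100)
  qin <- function(t_min) {
    s <- t_min %% (1 / 60)
    if (s < Ts) A * sin(pi * s / Ts) else 0
  }
  deriv <- function(t, y, parms)
    list((qin(t) - (y - 10) / 0.5) / outlet$compliance)
  ode_out <- ode(y = c(P = 10), times = wf$time_s / 60, func = deriv,
                 parms = NULL, rtol = 1e-11, atol = 1e-11, method = "lsoda")
  last <- wf$time_s >= 7  # final cycle, periodic steady state
  expect_equal(wf$pressure_mmHg[last], unname(ode_out[last, "P"]), tolerance = 1e-5)
  ratio_analytic <- max(wf$pressure_mmHg[last]) / min(wf$pressure_mmHg[last])
  ratio_ode <- max(ode_out[last, "P"]) / min(ode_out[last, "P"])
  expect_equal(ratio_analytic, ratio_ode, tolerance = 1e-4)
  expect_error(windkessel_waveform(outlet, amplitude = -1, period = 1),
               class = "domain_error")
  expect_error(windkessel_waveform(outlet, amplitude = 1, period = 0),
               class = "domain_error")
})
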