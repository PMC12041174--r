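test_that("Poiseuille resistance agrees with an independent SI hand conversion", {
  # independent chain: SI value, then Pa -> mmHg, m^3 -> ml, s -> min
  r_si <- 8 * 0.0035 * 0.03 / (pi * 0.002^4)
  expected <- r_si / 133.322 * 1e-6 / 60
  expect_equal(poiseuille_resistance(2, 30, 0.0035), expected, tolerance = 1e-12)
  expect_equal(expected, 2.089e-3, tolerance = 1e-3)
})

test_that("Poiseuille resistance scales linearly in length and as r^-4", {
  base <- poiseuille_resistance(1.7, 22, 0.0035)
  expect_equal(poiseuille_resistance(1.7, 44, 0.0035), 2 * base, tolerance = 1e-12)
  expect_equal(poiseuille_resistance(0.85, 22, 0.0035), 16 * base, tolerance = 1e-12)
  expect_gt(base, 0)
})

test_that("non-positive geometry raises a domain error naming the field", {
  expect_error(poiseuille_resistance(0, 10), "radius", class = "domain_error")
  expect_error(poiseuille_resistance(2, -1), "length", class = "domain_error")
  expect_error(poiseuille_resistance(2, 10, 0), "viscosity", class = "domain_error")
})

test_that("segment resistance composes the stenotic and healthy portions in series", {
  seg <- list(radius = 2, length = 30, area_reduction = 0, stenosis_length = 0)
  healthy <- poiseuille_resistance(2, 30)
  expect_identical(segment_resistance(seg), healthy)
  # 75% area loss halves the radius: x16 over the full length
  seg$area_reduction <- 0.75; seg$stenosis_length <- 30
  expect_equal(segment_resistance(seg), 16 * healthy, tolerance = 1e-12)
  # half-length stenosis: series sum of two half-length resistances
  seg$stenosis_length <- 15
  expect_equal(segment_resistance(seg), (1 + 16) / 2 * healthy, tolerance = 1e-12)
  seg$area_reduction <- 1
  expect_error(segment_resistance(seg), class = "domain_error")
})

test_that("segment resistance is monotone in severity and extent", {
  prev <- -Inf
  for (ar in seq(0, 0.95, by = 0.05)) {
    r <- segment_resistance(list(radius = 2, length = 30, area_reduction = ar,
                                 stenosis_length = 20))
    expect_gte(r, prev)
    prev <- r
  }
  prev <- -Inf
  for (sl in seq(0, 30, by = 5)) {
    r <- segment_resistance(list(radius = 2, length = 30, area_reduction = 0.6,
                                 stenosis_length = sl))
    expect_gte(r, prev)
    prev <- r
  }
})

test_that("anatomy templates are valid and have the expected outlets", {
  m1 <- build_template("MICHELS_I")
  expect_length(validate_network(m1), 0)
  expect_equal(nrow(m1$outlets), 4)
  m8 <- build_template("MICHELS_VIII_REPLACED_RHA")
  expect_length(validate_network(m8), 0)
  expect_equal(nrow(m8$outlets), 5)
  expect_true("RHA" %in% m8$segments$name)
  st <- build_template("CELIAC_STENOSIS", area_reduction = 0.8)
  expect_length(validate_network(st), 0)
  rct_sten <- segment_resistance(st$segments[st$segments$id == "CT", ], st$viscosity)
  rct <- segment_resistance(m1$segments[m1$segments$id == "CT", ], m1$viscosity)
  expect_gt(rct_sten / rct, 5)
})

test_that("templates remain valid under seeded geometry jitter", {
  set.seed(101)
  for (i in 1:20) {
    ids <- c("CT", "SA", "CHA", "PHA", "GDA", "ARCADE", "SMA_T", "SMA")
    ov <- lapply(ids, function(id) list(radius = runif(1, 0.9, 1.1) * 2,
                                        length = runif(1, 20, 60)))
    names(ov) <- ids
    net <- build_template("MICHELS_I", geometry_overrides = ov)
    expect_length(validate_network(net), 0)
  }
  expect_error(build_template("MICHELS_I", geometry_overrides = list(XX = list(radius = 2))),
               class = "unknown_segment")
})

test_that("validate_network reports named diagnostics instead of raising", {
  net <- build_template("MICHELS_I")
  expect_identical(validate_network(net), character(0))

  dangling <- net
  dangling$outlets <- dangling$outlets[dangling$outlets$node != "sa_end", ]
  expect_true("dangling_leaf:sa_end" %in% validate_network(dangling))

  two_inlets <- net
  two_inlets$inlet$node <- c("aorta", "celiac")
  expect_true("multiple_inlets" %in% validate_network(two_inlets))

  inout <- net
  inout$outlets$node[1] <- "aorta"
  expect_true("inlet_is_outlet" %in% validate_network(inout))

  clamped <- net
  clamped$clamped <- "NOPE"
  expect_true("unknown_clamped:NOPE" %in% validate_network(clamped))

  badseg <- net
  badseg$segments$radius[2] <- -1
  expect_true(any(grepl("bad_segment:SA:radius", validate_network(badseg))))
})
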