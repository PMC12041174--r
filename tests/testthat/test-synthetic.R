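test_that("patients are fully reproducible from their seed and leave RNG state alone", {
  set.seed(777); before <- rnorm(1)
  set.seed(777)
  a <- generate_patient("MICHELS_I", seed = 42)
  after <- rnorm(1)
  b <- generate_patient("MICHELS_I", seed = 42)
  expect_identical(before, after)          # no global RNG side effects
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$truth_network$outlets, b$truth_network$outlets)
})

test_that("noise-free measurements equal truth flows and satisfy conservation", {
  p <- generate_patient("MICHELS_I", seed = 5, noise_variability = 0)
  m <- p$measurements
  for (i in seq_len(nrow(m)))
    expect_identical(m$flow[i], branch_flow(p$truth_flows[[m$scenario[i]]], m$branch[i]))
  b <- m[m$scenario == "baseline", ]
  expect_equal(b$flow[b$branch == "CHA"] - b$flow[b$branch == "GDA"],
               b$flow[b$branch == "PHA"], tolerance = 1e-9)
  # drawn targets hit the cohort ranges
  sol <- p$truth_flows$baseline
  expect_true(branch_flow(sol, "CHA") >= 140 && branch_flow(sol, "CHA") <= 340)
  expect_true(branch_flow(sol, "GDA") >= 15 && branch_flow(sol, "GDA") <= 70)
})

test_that("probe noise stays within the truncation band around truth", {
  for (s in 1:10) {
    p <- generate_patient("MICHELS_I", seed = s, noise_variability = 0.12)
    m <- p$measurements
    truth <- vapply(seq_len(nrow(m)), function(i)
      branch_flow(p$truth_flows[[m$scenario[i]]], m$branch[i]), numeric(1))
    ratio <- m$flow / truth
    expect_true(all(ratio >= 1 - 3 * 0.12 & ratio <= 1 + 3 * 0.12))
  }
  expect_error(generate_patient("MICHELS_I", seed = 1, noise_variability = 0.5),
               class = "domain_error")
})

test_that("severe celiac stenosis reverses baseline GDA flow in every seed", {
  for (s in 1:10) {
    p <- generate_patient("CELIAC_STENOSIS", seed = s, noise_variability = 0,
                          area_reduction = 0.8)
    expect_lt(branch_flow(p$truth_flows$baseline, "GDA"), 0)
  }
})

test_that("a replaced right hepatic artery decouples RHA flow from GDA clamping", {
  for (s in c(2, 8, 21)) {
    p <- generate_patient("MICHELS_VIII_REPLACED_RHA", seed = s,
                          noise_variability = 0, habr_gain_true = 0)
    rha0 <- branch_flow(p$truth_flows$baseline, "RHA")
    rha1 <- branch_flow(p$truth_flows$clamp_GDA, "RHA")
    expect_lt(abs(rha1 / rha0 - 1), 0.10)
    expect_gt(branch_flow(p$truth_flows$clamp_GDA, "PHA"),
              branch_flow(p$truth_flows$baseline, "PHA"))
    expect_true(rha0 >= 45 && rha0 <= 80)
  }
})

test_that("cohorts are deterministic with unique patient ids", {
  a <- generate_cohort(20, seed = 7)
  b <- generate_cohort(20, seed = 7)
  expect_identical(lapply(a, `[[`, "measurements"), lapply(b, `[[`, "measurements"))
  expect_length(unique(vapply(a, `[[`, character(1), "patient_id")), 20)
  mix <- c(MICHELS_I = 0.85, CELIAC_STENOSIS = 0.1, MICHELS_VIII_REPLACED_RHA = 0.05)
  cc <- generate_cohort(12, variant_mix = mix, seed = 3)
  expect_length(cc, 12)
  expect_error(generate_cohort(5, variant_mix = c(BAD = 1), seed = 1),
               class = "domain_error")
})

test_that("with no noise and no HABR the pipeline recovers truth post-clamp flows", {
  for (s in c(1, 9, 17, 25, 33, 41, 49, 57, 65, 73)) {
    p <- generate_patient("MICHELS_I", seed = s, noise_variability = 0,
                          habr_gain_true = 0)
    cal <- calibrate_outlets(p$model_network, p$measurements)
    expect_true(cal$report$converged)
    for (sc in c("clamp_GDA", "clamp_CHA")) {
      pred <- branch_flow(run_scenario(cal$network, sc), "PHA")
      truth <- branch_flow(p$truth_flows[[sc]], "PHA")
      expect_lt(abs(pred / truth - 1), 0.01)
    }
  }
})

test_that("synthetic real post-clamp PHA exceeds the physics-only lower bound", {
  pts <- generate_cohort(50, seed = 1234, noise_variability = 0.12)
  ok <- vapply(pts, function(p) {
    cal <- calibrate_outlets(p$model_network, p$measurements)
    pred <- branch_flow(run_scenario(cal$network, "clamp_GDA", habr_gain = 0), "PHA")
    lo <- predict_interval(pred, 0.15)[["interval_min"]]
    m <- p$measurements
    real <- m$flow[m$scenario == "clamp_GDA" & m$branch == "PHA"]
    real >= lo
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
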