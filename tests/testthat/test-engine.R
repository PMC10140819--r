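test_that("Lint80 release is lagged, linear and capped", {
  expect_equal(lint80_release_fraction(30, 300, 60), 0)
  expect_equal(lint80_release_fraction(60 + 300, 300, 60), 0.80)
  expect_equal(lint80_release_fraction(60 + 150, 300, 60), 0.40)
  # linear continuation past 80 %, capped at 1
  expect_equal(lint80_release_fraction(60 + 375, 300, 60), 1)
  expect_equal(lint80_release_fraction(1e5, 300, 60), 1)
  expect_equal(lint80_release_fraction(1e5, 300, 60, cap = 0.8), 0.8)
  t <- seq(0, 600, 5)
  expect_true(all(diff(lint80_release_fraction(t, 300, 60)) >= 0))
})

test_that("a zero-clearance IV dose is conserved over 1000 h", {
  p <- ref_adult()
  sys <- build_ode_system(p, inert_drug(),
                          regimen = iv_regimen(155, times = seq(0, 1000, 5),
                                               inf_min = 1))
  prof <- simulate_profile(sys)
  expect_lt(mass_balance_error(prof, after = 0.1), 1e-4)  # 0.01 %
})

test_that("oral dosing balances body + eliminated + lumen against the dose", {
  p <- ref_adult()
  sys <- build_ode_system(p, hcq_drug(), regimen = oral_regimen(155))
  prof <- simulate_profile(sys)
  expect_lt(mass_balance_error(prof), 1e-3)  # 0.1 %
  states <- attr(prof, "states")
  # release leaves the solid state monotonically and transit loss only grows
  expect_true(all(diff(states[, "lumen_solid"]) <= 1e-9))
  expect_true(all(diff(states[, "lumen_transit_lost"]) >= -1e-9))
})

test_that("tissue:plasma ratios equilibrate to Kp when clearance is zero", {
  p <- ref_adult()
  parts <- compute_partition_set(neutral_drug(1.5), p)  # moderate Kp, fast eq
  sys <- build_ode_system(p, neutral_drug(1.5), partitions = parts,
                          clearances = manual_clearances(0, 0),
                          regimen = iv_regimen(100, times = seq(0, 1500, 10),
                                               inf_min = 1))
  prof <- simulate_profile(sys)
  states <- attr(prof, "states")
  last <- states[nrow(states), ]
  c_blood <- last[["venous_blood"]] / p$organ_volumes[["venous_blood"]]
  c_plasma <- c_blood / parts$bp_ratio
  for (org in names(parts$Kp)) {
    c_tis <- last[[org]] / p$organ_volumes[[org]]
    expect_equal(c_tis / c_plasma, unname(parts$Kp[org]), tolerance = 0.01,
                 info = org)
  }
})

test_that("AUC is dose-proportional for the linear system", {
  p <- ref_adult()
  drug <- hcq_drug()
  auc <- vapply(c(155, 310), function(dose) {
    sys <- build_ode_system(p, drug, regimen = iv_regimen(dose))
    run_nca(simulate_profile(sys), dose)$AUC0_t
  }, numeric(1))
  expect_equal(auc[2] / auc[1], 2, tolerance = 1e-3)  # 0.1 %
})

test_that("the lumped one-compartment reduction matches the closed form", {
  p <- ref_adult()
  cl <- 0.25  # L/h, gentle elimination so perfusion mixing is much faster
  sys <- build_ode_system(p, inert_drug(), partitions = flat_partitions(),
                          clearances = manual_clearances(0, cl),
                          regimen = iv_regimen(100, times = seq(0, 400, 2),
                                               inf_min = 1))
  prof <- simulate_profile(sys)
  v_tot <- sum(p$organ_volumes)
  keep <- prof$time_h >= 24
  pred <- (100 / v_tot) * exp(-cl * prof$time_h[keep] / v_tot) * 1000
  expect_equal(prof$conc_ng_per_ml[keep], pred, tolerance = 5e-3)  # 0.5 %
})

test_that("halving solver tolerances leaves AUC0-t unchanged to 0.01 %", {
  p <- ref_adult()
  sys <- build_ode_system(p, hcq_drug(), regimen = iv_regimen(155))
  a1 <- run_nca(simulate_profile(sys, rtol = 1e-8, atol = 1e-10), 155)$AUC0_t
  a2 <- run_nca(simulate_profile(sys, rtol = 5e-9, atol = 5e-11), 155)$AUC0_t
  expect_equal(a1, a2, tolerance = 1e-4)
})

test_that("oral bioavailability never exceeds IV exposure at equal dose", {
  drug <- hcq_drug()
  pop <- sample_population(population_spec(n = 5, seed = 31))
  for (p in pop) {
    auc_iv <- run_nca(simulate_profile(
      build_ode_system(p, drug, regimen = iv_regimen(155))), 155)$AUC0_t
    auc_po <- run_nca(simulate_profile(
      build_ode_system(p, drug, regimen = oral_regimen(155))), 155)$AUC0_t
    expect_lt(auc_po, auc_iv)
  }
})

test_that("truncating Lint80 release at 80 % reduces oral exposure", {
  p <- ref_adult()
  drug <- hcq_drug()
  auc_full <- run_nca(simulate_profile(
    build_ode_system(p, drug, regimen = oral_regimen(155, cap = 1))), 155)$AUC0_t
  auc_cap <- run_nca(simulate_profile(
    build_ode_system(p, drug, regimen = oral_regimen(155, cap = 0.8))), 155)$AUC0_t
  expect_lt(auc_cap, auc_full)
  expect_gt(auc_cap, 0.75 * auc_full)
})

test_that("mismatched organ sets between physiology and partitions error", {
  p <- ref_adult()
  parts <- compute_partition_set(hcq_drug(), p)
  parts$Kb <- parts$Kb[setdiff(names(parts$Kb), "spleen")]
  expect_error(build_ode_system(p, hcq_drug(), partitions = parts,
                                regimen = iv_regimen(155)),
               "spleen")
})

test_that("simulation output contract: grid, matrix label, plasma conversion", {
  p <- ref_adult()
  sys <- build_ode_system(p, hcq_drug(),
                          regimen = iv_regimen(155, times = seq(0, 24, 0.5)))
  b <- simulate_profile(sys)
  expect_true(all(diff(b$time_h) > 0))
  expect_true(all(b$conc_ng_per_ml >= 0))
  expect_equal(unique(b$matrix), "blood")
  pl <- simulate_profile(sys, matrix = "plasma")
  expect_equal(pl$conc_ng_per_ml * sys$partitions$bp_ratio, b$conc_ng_per_ml,
               tolerance = 1e-12)
})
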