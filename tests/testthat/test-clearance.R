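test_that("intrinsic-clearance back-calculation matches hand arithmetic", {
  expect_equal(back_calculate_clint(90, 1.5, 0.0667), 30.0, tolerance = 5e-3)
  expect_equal(back_calculate_clint(90, 0, 0.0667), 0)
  expect_equal(back_calculate_clint(90, 0, 0.0667, "standard_well_stirred"), 0)
  expect_error(back_calculate_clint(90, 7, 0.0667),
               "exceeds unbound hepatic flow capacity")
})

test_that("well-stirred forward model approaches the flow-limited ceiling", {
  expect_equal(hepatic_clearance_term(0, 90, 0.5), 0)
  expect_equal(hepatic_clearance_term(1e9, 90, 0.5), 90, tolerance = 1e-3)
  expect_lt(hepatic_clearance_term(1e12, 90, 1), 90)
})

test_that("forward then standard-form inversion recovers CLint to 1e-9", {
  set.seed(11)
  for (i in 1:200) {
    qh <- runif(1, 30, 150)
    fub <- runif(1, 0.01, 1)
    clint <- runif(1, 0.1, 500)
    clh <- hepatic_clearance_term(clint, qh, fub)
    back <- back_calculate_clint(qh, clh, fub, "standard_well_stirred")
    expect_equal(back, clint, tolerance = 1e-9)
  }
  # the printed form is the low-extraction approximation of the standard one
  expect_equal(back_calculate_clint(90, 0.09, 0.5, "as_printed"),
               back_calculate_clint(90, 0.09, 0.5, "standard_well_stirred"),
               tolerance = 1e-2)
})

test_that("CYP apportionment conserves whole-liver CLint", {
  set.seed(22)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    contrib <- as.numeric(rmultinom(1, 1000, runif(k))) / 1000
    names(contrib) <- paste0("E", seq_len(k))
    abund <- setNames(runif(k, 1e5, 1e7), names(contrib))
    clint <- runif(1, 1, 400)
    vals <- apportion_to_enzymes(clint, contrib, abund)
    expect_equal(aggregate_enzyme_clint(vals, abund), clint, tolerance = 1e-9)
  }
})

test_that("apportionment handles degenerate and proportional splits", {
  v <- apportion_to_enzymes(60, c(CYP3A4 = 1), c(CYP3A4 = 2e6))
  expect_equal(unname(v), 60 * 1e6 / 60 / 2e6)
  v3 <- apportion_to_enzymes(60, c(a = 0.5, b = 0.3, c = 0.2),
                             c(a = 1e6, b = 1e6, c = 1e6))
  expect_equal(unname(v3 / v3[["c"]]), c(2.5, 1.5, 1), tolerance = 1e-12)
  expect_error(apportion_to_enzymes(60, c(a = 1), c(b = 1e6)), "missing")
  expect_error(apportion_to_enzymes(60, c(a = 0.5, b = 0.4), c(a = 1, b = 1)),
               "sum to 1")
})

test_that("renal clearance scales proportionally with GFR", {
  expect_equal(renal_clearance_scaled(12.7, 90, 90), 12.7)
  expect_equal(renal_clearance_scaled(12.7, 45, 90), 6.35)
  expect_equal(signif(renal_clearance_scaled(12.7, 20, 90), 4), 2.822)
  expect_error(renal_clearance_scaled(12.7, 0, 90), "GFR")
})

test_that("lowering the binding-protein scalar raises fu and hepatic clearance", {
  p <- ref_adult()
  drug <- hcq_drug()
  scalars <- c(1, 0.8, 0.6)
  fus <- clhs <- numeric(3)
  cs <- build_clearance_set(drug, p)
  for (i in seq_along(scalars)) {
    q <- p; q$binding_protein_scalar <- scalars[i]
    ps <- compute_partition_set(drug, q)
    fus[i] <- ps$fu
    clhs[i] <- hepatic_clearance_term(cs$CLint_total, q$hepatic_blood_flow_QH,
                                      ps$fu_blood)
  }
  expect_true(all(diff(fus) > 0))
  expect_true(all(diff(clhs) > 0))
})

test_that("clearance set is anchored at the reference hepatic flow", {
  drug <- hcq_drug()
  small <- ref_adult("F", 25, 45)
  big <- ref_adult("M", 25, 100)
  expect_equal(build_clearance_set(drug, small)$CLint_total,
               build_clearance_set(drug, big)$CLint_total)
  expect_output(clearance_explain(drug), "CLint \\[as_printed\\]")
})
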