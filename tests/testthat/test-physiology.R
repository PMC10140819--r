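test_that("reference adult satisfies the physiology invariants", {
  p <- ref_adult("F", 22.6, 63.5)
  expect_s3_class(p, "individual_physiology")
  expect_true(all(p$organ_volumes > 0))
  expect_true(all(p$organ_blood_flows > 0))
  expect_gt(p$hematocrit, 0); expect_lt(p$hematocrit, 1)
  expect_equal(sum(p$organ_blood_flows), p$cardiac_output,
               tolerance = 1e-9)
  expect_equal(p$hepatic_blood_flow_QH,
               unname(p$organ_blood_flows["liver"] + p$organ_blood_flows["gut"] +
                        p$organ_blood_flows["spleen"]))
  # deterministic: no hidden randomness
  expect_identical(ref_adult("F", 22.6, 63.5), p)
})

test_that("body-size scaling of volumes and flows is linear in weight", {
  a <- ref_adult("F", 22.6, 50)
  b <- ref_adult("F", 22.6, 100)
  expect_equal(b$organ_volumes, 2 * a$organ_volumes, tolerance = 1e-12)
  expect_equal(b$organ_blood_flows, 2 * a$organ_blood_flows, tolerance = 1e-12)
  expect_equal(b$cardiac_output, 2 * a$cardiac_output)
})

test_that("demographic preconditions are enforced with named fields", {
  expect_error(build_reference_adult("F", 10, 60), "age")
  expect_error(build_reference_adult("F", 30, 150), "weight")
  expect_error(build_reference_adult("X", 30, 60))
})

test_that("population sampling honors counts, sex split and the seed", {
  spec <- population_spec(n = 100, female_fraction = 0.60, seed = 1)
  pop <- sample_population(spec)
  expect_length(pop, 100)
  expect_equal(sum(vapply(pop, `[[`, character(1), "sex") == "F"), 60)
  pop2 <- sample_population(population_spec(n = 100, female_fraction = 0.60,
                                            seed = 1))
  expect_identical(pop, pop2)
  pop3 <- sample_population(population_spec(n = 100, female_fraction = 0.60,
                                            seed = 2))
  expect_false(identical(pop, pop3))
  expect_error(population_spec(n = 0), "n")
})

test_that("zero variability collapses every individual onto the reference", {
  cv0 <- list(body_weight = 0, organ_volumes = 0, organ_blood_flows = 0,
              hematocrit = 0, GFR = 0)
  pop <- sample_population(population_spec(n = 6, female_fraction = 0.5,
                                           weight_range = c(55, 68),
                                           variability_cv = cv0, seed = 9))
  for (p in pop) {
    ref <- build_reference_adult(p$sex, p$age, mean(c(55, 68)))
    expect_equal(p$organ_volumes, ref$organ_volumes)
    expect_equal(p$organ_blood_flows, ref$organ_blood_flows)
    expect_equal(p$hematocrit, ref$hematocrit)
    expect_equal(p$GFR, ref$GFR)
    expect_equal(p$body_weight, ref$body_weight)
  }
})

test_that("sampled weight variability reproduces the requested CV", {
  pop <- sample_population(population_spec(
    n = 1000, female_fraction = 0.5, seed = 7,
    variability_cv = list(body_weight = 0.2, organ_volumes = 0,
                          organ_blood_flows = 0, hematocrit = 0, GFR = 0)))
  w <- vapply(pop, `[[`, numeric(1), "body_weight")
  cv <- sd(w) / mean(w)
  expect_gt(cv, 0.2 * 0.85)
  expect_lt(cv, 0.2 * 1.15)
})

test_that("disease scaling preserves flow balance and hits the GFR stages", {
  p <- ref_adult()
  for (stage in c("CP-A", "CP-B", "CP-C", "CKD-moderate", "CKD-severe")) {
    d <- apply_disease(p, stage)
    expect_equal(sum(d$organ_blood_flows), d$cardiac_output, tolerance = 1e-9,
                 info = stage)
    expect_equal(d$disease_stage, stage)
  }
  expect_equal(apply_disease(p, "CKD-moderate")$GFR, 45)
  expect_equal(apply_disease(p, "CKD-severe")$GFR, 20)
  # healthy stage is the identity
  expect_equal(apply_disease(p, "healthy"), p)
  # the input object is untouched
  apply_disease(p, "CP-C")
  expect_equal(p$GFR, 90)
  expect_error(disease_spec("CP-D"), "stage")
})

test_that("shipped scaler tables are monotone in severity", {
  p <- ref_adult()
  cp <- lapply(c("CP-A", "CP-B", "CP-C"), function(s) apply_disease(p, s))
  qh <- vapply(cp, `[[`, numeric(1), "hepatic_blood_flow_QH")
  lv <- vapply(cp, function(x) unname(x$organ_volumes["liver"]), numeric(1))
  bp <- vapply(cp, `[[`, numeric(1), "binding_protein_scalar")
  expect_true(all(diff(qh) <= 0))
  expect_true(all(diff(lv) <= 0))
  expect_true(all(diff(bp) <= 0))
  expect_true(qh[1] < p$hepatic_blood_flow_QH)
  ckd <- vapply(c("CKD-moderate", "CKD-severe"),
                function(s) apply_disease(p, s)$GFR, numeric(1))
  expect_true(all(diff(c(p$GFR, ckd)) < 0))
})

test_that("population export is one row per individual", {
  pop <- sample_population(population_spec(n = 5, seed = 1))
  df <- population_to_df(pop)
  expect_equal(nrow(df), 5)
  expect_true(all(c("vol_liver", "flow_kidney", "GFR") %in% names(df)))
})
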