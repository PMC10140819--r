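test_that("NCA reproduces closed forms on known profiles", {
  # rectangle
  flat <- data.frame(time_h = 0:10, conc_ng_per_ml = rep(100, 11))
  expect_equal(run_nca(flat, 155)$AUC0_t, 1000)
  # mono-exponential, densely sampled
  t <- seq(0, 120, 0.1)
  mono <- data.frame(time_h = t, conc_ng_per_ml = 1000 * exp(-0.1 * t))
  res <- run_nca(mono, dose_base = 155)
  expect_equal(res$AUC0_inf, 10000, tolerance = 5e-3)
  expect_equal(res$terminal_rate, 0.1, tolerance = 1e-3)
  expect_equal(res$CL, 1000 * 155 / res$AUC0_inf)
  expect_equal(res$Cmax, 1000)
  expect_equal(res$Tmax, 0)
  expect_false(res$flagged)
  expect_true(res$AUC0_inf >= res$AUC0_t)
  expect_true(res$extrapolated_fraction >= 0 && res$extrapolated_fraction < 1)
})

test_that("NCA flags profiles without a terminal decline", {
  rising <- data.frame(time_h = 0:5, conc_ng_per_ml = c(1, 2, 4, 8, 16, 32))
  res <- run_nca(rising, 155)
  expect_true(res$flagged)
  expect_true(is.na(res$AUC0_inf) && is.na(res$CL))
  expect_error(run_nca(data.frame(time_h = c(0, 1, 1),
                                  conc_ng_per_ml = c(1, 2, 3)), 155),
               "increasing")
})

test_that("observed/predicted ratio and fold rule follow the definitions", {
  expect_equal(round_half_up(obs_pred_ratio(12607.25, 11122.39), 2), 1.13)
  expect_equal(round_half_up(obs_pred_ratio(16.9, 20.6), 2), 0.82)
  expect_equal(obs_pred_ratio(3, 3), 1)
  expect_error(obs_pred_ratio(1, 0), "predicted")
  expect_true(within_fold(1.94))
  expect_true(within_fold(0.5))   # inclusive boundary
  expect_true(within_fold(2.0))
  expect_false(within_fold(2.01))
  expect_false(within_fold(0.49))
  expect_error(within_fold(1, fold = 1), "fold")
})

test_that("round_half_up uses commercial rounding at 2 d.p.", {
  expect_equal(round_half_up(0.005, 2), 0.01)
  expect_equal(round_half_up(1.135, 2), 1.14)
  expect_equal(round_half_up(-0.005, 2), -0.01)
})

test_that("VPC envelope matches the linear-interpolation percentile rule", {
  mk <- function(v) data.frame(time_h = 1, conc_ng_per_ml = v)
  profs <- lapply(1:100, mk)
  env <- vpc_envelope(profs)
  expect_equal(env$p5, 5.95)
  expect_equal(env$p95, 95.05)
  expect_equal(env$mean, 50.5)
  expect_equal(env$min, 1); expect_equal(env$max, 100)
  # duplicated single profile: all five curves coincide
  p <- data.frame(time_h = c(1, 2), conc_ng_per_ml = c(10, 5))
  env2 <- vpc_envelope(list(p, p, p))
  for (col in c("mean", "min", "p5", "p95", "max")) {
    expect_equal(env2[[col]], p$conc_ng_per_ml)
  }
  # order statistics stay ordered for random inputs
  set.seed(5)
  profs3 <- lapply(1:40, function(i)
    data.frame(time_h = 1:4, conc_ng_per_ml = runif(4, 0, 100)))
  env3 <- vpc_envelope(profs3)
  expect_true(all(env3$min <= env3$p5 & env3$p5 <= env3$mean &
                    env3$mean <= env3$p95 & env3$p95 <= env3$max))
  bad <- data.frame(time_h = 1:3, conc_ng_per_ml = 1:3)
  expect_error(vpc_envelope(list(p, bad)), "mismatched")
})

test_that("population AUC summary is seeded and collapses on ties", {
  mk <- function(auc) structure(list(AUC0_t = auc), class = "nca_result")
  same <- lapply(rep(5000, 12), mk)
  s <- summarize_population_auc(same, seed = 4)
  expect_equal(s$median_AUC0_t, 5000)
  expect_equal(s$ci95_low, 5000); expect_equal(s$ci95_high, 5000)
  set.seed(99); vals <- lapply(rlnorm(50, log(5000), 0.2), mk)
  s1 <- summarize_population_auc(vals, seed = 7)
  s2 <- summarize_population_auc(vals, seed = 7)
  expect_identical(s1, s2)
  expect_true(s1$ci95_low <= s1$median_AUC0_t &&
                s1$median_AUC0_t <= s1$ci95_high)
  expect_error(summarize_population_auc(vals[1:5]), "at least 10")
})

test_that("bootstrap CI of the median attains nominal-ish coverage", {
  mk <- function(auc) list(AUC0_t = auc)
  n_rep <- 200
  set.seed(1234)
  covered <- vapply(seq_len(n_rep), function(i) {
    x <- rnorm(10000, mean = 100, sd = 10)
    s <- summarize_population_auc(lapply(x, mk), n_boot = 400, seed = i)
    s$ci95_low <= 100 && 100 <= s$ci95_high
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("percent change reproduces the reported disease arithmetic", {
  expect_lt(abs(percent_change(5317, 9204) - 73.10), 0.01)
  expect_equal(percent_change(42, 42), 0)
  expect_equal(round_half_up(percent_change(4989, 4890), 2), -1.98)
  expect_error(percent_change(0, 5), "healthy")
})
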