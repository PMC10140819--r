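# Non-compartmental analysis and model-qualification machinery:
# observed/predicted ratios, 2-fold checks, VPC envelopes, population AUC
# summaries, percent change versus healthy.

#' Round half-up to a number of decimals
#'
#' Commercial rounding (0.005 -> 0.01), the convention used for the
#' reported ratio tables; base `round()` rounds half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Non-compartmental analysis of a concentration-time profile
#'
#' Computes Cmax/Tmax, AUC0-t by the linear trapezoid on the sampled grid,
#' the terminal log-linear elimination rate from the last `n_terminal`
#' positive samples, AUC0-inf = AUC0-t + Clast/lambda_z, and clearance
#' CL = Dose / AUC0-inf (mg and ng.h/mL convert to L/h as
#' `1000 * dose / AUC`).  A non-positive terminal slope flags the result:
#' AUC0-inf and CL are set `NA`.
#'
#' @param profile A `concentration_profile` (or data frame with `time_h`,
#'   `conc_ng_per_ml`).
#' @param dose_base Dose in mg (base).
#' @param n_terminal Number of terminal points for the log-linear fit
#'   (>= 3).
#' @return Object of class `nca_result`: `Cmax` (ng/mL), `Tmax` (h),
#'   `AUC0_t`, `AUC0_inf` (ng.h/mL), `terminal_rate` (1/h), `CL` (L/h),
#'   `extrapolated_fraction`.
#' @examples
#' prof <- data.frame(time_h = 0:10, conc_ng_per_ml = 1000 * exp(-0.1 * 0:10))
#' run_nca(prof, dose_base = 155)$AUC0_t
#' @export
run_nca <- function(profile, dose_base, n_terminal = 3) {
  t <- profile$time_h
  c <- profile$conc_ng_per_ml
  if (length(t) < 3) stop("NCA needs at least 3 time points", call. = FALSE)
  if (any(diff(t) <= 0)) stop_field("time_h", "must be strictly increasing")
  if (n_terminal < 3) stop_field("n_terminal", "must be >= 3")

  cmax <- max(c)
  tmax <- t[which.max(c)]
  auc0t <- sum(diff(t) * (head(c, -1) + tail(c, -1)) / 2)
  if (auc0t <= 0) stop("non-positive AUC0-t", call. = FALSE)

  pos <- which(c > 0)
  lambda <- NA_real_
  if (length(pos) >= n_terminal) {
    idx <- tail(pos, n_terminal)
    fit <- lm(log(c[idx]) ~ t[idx])
    slope <- unname(coef(fit)[2])
    if (is.finite(slope) && slope < 0) lambda <- -slope
  }
  c_last <- c[tail(pos, 1)]
  if (!is.na(lambda)) {
    auc_inf <- auc0t + c_last / lambda
    cl <- 1000 * dose_base / auc_inf
    extrap <- (c_last / lambda) / auc_inf
  } else {
    auc_inf <- NA_real_
    cl <- NA_real_
    extrap <- NA_real_
  }
  structure(list(Cmax = cmax, Tmax = tmax, AUC0_t = auc0t,
                 AUC0_inf = auc_inf, terminal_rate = lambda, CL = cl,
                 extrapolated_fraction = extrap,
                 dose_base = dose_base,
                 flagged = is.na(lambda)),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> Cmax %.4g ng/mL @ %.2g h | AUC0-t %.5g | AUC0-inf %.5g ng.h/mL | CL %.4g L/h%s\n",
              x$Cmax, x$Tmax, x$AUC0_t, x$AUC0_inf, x$CL,
              if (x$flagged) " [flagged: no terminal slope]" else ""))
  invisible(x)
}

#' Observed-to-predicted ratio
#'
#' @param observed,predicted PK parameter values; `predicted` > 0.
#' @return `observed / predicted` at full precision (display rounding is
#'   the caller's job, see [round_half_up()]).
#' @examples
#' obs_pred_ratio(12607.25, 11122.39)  # 1.13 at 2 d.p.
#' @export
obs_pred_ratio <- function(observed, predicted) {
  if (any(predicted <= 0)) stop_field("predicted", "must be > 0")
  observed / predicted
}

#' Fold-range qualification check
#'
#' `TRUE` iff `1/fold <= ratio <= fold` (boundaries included); the standard
#' PBPK 2-fold acceptance rule at `fold = 2`.
#'
#' @param ratio Observed/predicted ratio, > 0.
#' @param fold Fold limit, > 1.
#' @return Logical vector.
#' @export
within_fold <- function(ratio, fold = 2) {
  if (fold <= 1) stop_field("fold", "must be > 1")
  if (any(ratio <= 0)) stop_field("ratio", "must be > 0")
  ratio >= 1 / fold & ratio <= fold
}

#' Visual-predictive-check envelope
#'
#' Pointwise arithmetic mean, minimum, maximum, and 5th/95th percentiles
#' (linear-interpolation percentiles, `stats::quantile` type 7) over
#' profiles sharing a common time grid.
#'
#' @param profiles List of `concentration_profile`s (>= 2) on identical
#'   grids; re-sampling mismatched grids is the caller's job.
#' @return Data frame `time_h`, `mean`, `min`, `p5`, `p95`, `max`.
#' @export
vpc_envelope <- function(profiles) {
  if (length(profiles) < 2) stop("need at least 2 profiles", call. = FALSE)
  t0 <- profiles[[1]]$time_h
  same <- vapply(profiles, function(p) {
    length(p$time_h) == length(t0) && all(p$time_h == t0)
  }, logical(1))
  if (!all(same)) stop("profiles are on mismatched time grids", call. = FALSE)
  cmat <- matrix(vapply(profiles, `[[`, numeric(length(t0)), "conc_ng_per_ml"),
                 nrow = length(t0))
  data.frame(
    time_h = t0,
    mean = rowMeans(cmat),
    min = apply(cmat, 1, min),
    p5 = apply(cmat, 1, quantile, probs = 0.05, type = 7, names = FALSE),
    p95 = apply(cmat, 1, quantile, probs = 0.95, type = 7, names = FALSE),
    max = apply(cmat, 1, max)
  )
}

#' Population AUC0-t summary
#'
#' Median AUC0-t with a seeded percentile-bootstrap 95 % confidence
#' interval of the median (1000 resamples by default).
#'
#' @param nca_results List of `nca_result`s (>= 10).
#' @param stage,route Labels carried into the summary.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `population_summary`: `stage`, `route`, `n`,
#'   `median_AUC0_t`, `ci95_low`, `ci95_high`, `p5`, `p95`.
#' @export
summarize_population_auc <- function(nca_results, stage = "healthy",
                                     route = "iv", n_boot = 1000, seed = 1L) {
  aucs <- vapply(nca_results, `[[`, numeric(1), "AUC0_t")
  if (length(aucs) < 10) stop("need at least 10 NCA results", call. = FALSE)
  med <- median(aucs)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      median(sample(aucs, replace = TRUE))
    }, numeric(1))
  })
  ci <- quantile(boots, c(0.025, 0.975), type = 7, names = FALSE)
  structure(list(stage = stage, route = route, n = length(aucs),
                 median_AUC0_t = med,
                 ci95_low = ci[1], ci95_high = ci[2],
                 p5 = quantile(aucs, 0.05, type = 7, names = FALSE),
                 p95 = quantile(aucs, 0.95, type = 7, names = FALSE)),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> %s/%s (n=%d): median AUC0-t %.0f (95%% CI %.0f-%.0f) ng.h/mL\n",
              x$stage, x$route, x$n, x$median_AUC0_t, x$ci95_low, x$ci95_high))
  invisible(x)
}

#' Percent change of a disease median versus healthy
#'
#' `100 * (disease - healthy) / healthy`; positive = increase.
#'
#' @param healthy_median Healthy-population median, > 0.
#' @param disease_median Disease-population median.
#' @return Percent change.
#' @examples
#' percent_change(5317, 9204)  # +73.1 %
#' @export
percent_change <- function(healthy_median, disease_median) {
  if (any(healthy_median <= 0)) stop_field("healthy_median", "must be > 0")
  100 * (disease_median - healthy_median) / healthy_median
}

#' Load the packaged healthy-adult evaluation table
#'
#' The observed and predicted Cmax (ng/mL), AUC0-t (ng.h/mL) and CL (L/h)
#' for the 12 healthy study profiles (4 IV, 8 oral), with the ratio each
#' source table printed.
#'
#' @param path Optional alternative CSV.
#' @return Data frame with `study_id`, `route`, `parameter`, `observed`,
#'   `predicted`, `printed_ratio`.
#' @export
load_healthy_evaluation_table <- function(path = hcq_extdata("healthy_evaluation_table.csv")) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute evaluation records from an observed/predicted table
#'
#' Adds the recomputed observed/predicted ratio (full precision and
#' half-up 2 d.p. display) and the 2-fold verdict to each row.
#'
#' @param tab Data frame as from [load_healthy_evaluation_table()].
#' @param fold Fold-acceptance limit.
#' @return The table with `ratio`, `ratio_2dp`, `within_2fold` columns.
#' @export
evaluate_ratio_table <- function(tab = load_healthy_evaluation_table(), fold = 2) {
  tab$ratio <- obs_pred_ratio(tab$observed, tab$predicted)
  tab$ratio_2dp <- round_half_up(tab$ratio, 2)
  tab$within_2fold <- within_fold(tab$ratio, fold)
  tab
}

#' Load the reported disease-population AUC0-t medians
#'
#' Median AUC0-t (ng.h/mL, 155 mg dose) with 95 % CI per disease stage and
#' route, as reported for the source model's virtual populations; used as
#' the printed input surface for percent-change arithmetic.
#'
#' @param path Optional alternative CSV.
#' @return Data frame `stage`, `route`, `median_auc0_t`, `ci95_low`,
#'   `ci95_high`.
#' @export
load_reported_disease_medians <- function(path = hcq_extdata("reported_disease_medians.csv")) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Percent changes of reported disease medians versus healthy
#'
#' Applies [percent_change()] to the reported median table, per route and
#' stage.
#'
#' @param medians Table from [load_reported_disease_medians()].
#' @return Data frame `stage`, `route`, `percent_change`.
#' @export
reported_percent_changes <- function(medians = load_reported_disease_medians()) {
  out <- do.call(rbind, lapply(split(medians, medians$route), function(d) {
    healthy <- d$median_auc0_t[d$stage == "healthy"]
    dd <- d[d$stage != "healthy", ]
    data.frame(stage = dd$stage, route = dd$route,
               percent_change = percent_change(healthy, dd$median_auc0_t),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
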