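# Whole-body perfusion-limited ODE system: assembly and integration.
#
# Amount states (mg): one per perfused organ, arterial and venous blood,
# cumulative hepatic and renal elimination, and the oral lumen chain
# (undissolved solid, dissolved drug, transit loss).  All mass balances are
# linear, so the system is a constant matrix plus piecewise-constant input
# (infusion / formulation release) and is integrated segment-by-segment
# with a stiff solver.

.STATE_NAMES <- c(.PERFUSED_ORGANS, "arterial_blood", "venous_blood",
                  "elim_hepatic", "elim_renal",
                  "lumen_solid", "lumen_dissolved", "lumen_transit_lost")

#' Lint80 formulation release fraction
#'
#' Linear-release profile: zero up to the lag time, then linear with slope
#' `0.80 / dissolution_time`, so 80 % of the dose is released
#' `dissolution_time` minutes after the lag.  Release continues at the same
#' rate past 80 % up to `cap` (default 1; set `cap = 0.8` to truncate the
#' profile at 80 % released).
#'
#' @param t Time since dosing, min (vectorised).
#' @param dissolution_time Time to release 80 % after the lag, min, > 0.
#' @param lag_time Lag before release starts, min, >= 0.
#' @param cap Maximum released fraction, in (0, 1].
#' @return Released fraction in `[0, cap]`, non-decreasing in `t`.
#' @examples
#' lint80_release_fraction(c(30, 360, 210), 300, 60)  # 0, 0.8, 0.4
#' @export
lint80_release_fraction <- function(t, dissolution_time, lag_time, cap = 1) {
  if (dissolution_time <= 0) stop_field("dissolution_time", "must be > 0")
  if (lag_time < 0) stop_field("lag_time", "must be >= 0")
  if (cap <= 0 || cap > 1) stop_field("cap", "must lie in (0, 1]")
  if (any(t < 0)) stop_field("t", "must be >= 0")
  pmin(pmax(t - lag_time, 0) * 0.80 / dissolution_time, cap)
}

#' Define a dosing regimen
#'
#' @param route `"iv_infusion"` or `"oral"`.
#' @param dose_base Base (not salt) dose, mg, > 0.
#' @param infusion_duration Infusion duration, min (IV only), > 0.
#' @param dissolution_time,lag_time Lint80 formulation parameters, min
#'   (oral only).
#' @param release_cap Maximum released fraction (oral), in (0, 1].
#' @param times Output sampling grid, h, strictly increasing from 0.
#' @return Object of class `dosing_regimen`.
#' @examples
#' iv155 <- dosing_regimen("iv_infusion", 155, infusion_duration = 30)
#' oral155 <- dosing_regimen("oral", salt_to_base_dose(200))
#' @export
dosing_regimen <- function(route = c("iv_infusion", "oral"), dose_base,
                           infusion_duration = 30,
                           dissolution_time = 300, lag_time = 60,
                           release_cap = 1,
                           times = seq(0, 72, by = 0.1)) {
  route <- match.arg(route)
  if (dose_base <= 0) stop_field("dose_base", "must be > 0")
  if (route == "iv_infusion" && infusion_duration <= 0) {
    stop_field("infusion_duration", "must be > 0 for IV infusion")
  }
  if (route == "oral") {
    if (dissolution_time <= 0) stop_field("dissolution_time", "must be > 0")
    if (lag_time < 0) stop_field("lag_time", "must be >= 0")
  }
  if (any(diff(times) <= 0) || times[1] < 0) {
    stop_field("times", "must be non-negative and strictly increasing")
  }
  structure(list(route = route, dose_base = dose_base,
                 infusion_duration = infusion_duration,
                 release_model = "lint80",
                 dissolution_time = dissolution_time, lag_time = lag_time,
                 release_cap = release_cap, times = times),
            class = "dosing_regimen")
}

#' Assemble the whole-body ODE system for one individual
#'
#' Builds the linear perfusion-limited mass-balance system: arterial blood
#' feeds every systemic organ; gut and spleen drain into the liver through
#' the portal vein; the liver drains (hepatic artery + portal flow) into
#' venous blood; venous blood passes through the lung back to arterial.
#' Hepatic elimination follows the well-stirred sink
#' `fuB * CLint * C_liver_outflow`, renal elimination removes
#' `CLR_blood * C_arterial` within the kidney balance.  IV dosing is a
#' zero-order infusion into venous blood; oral dosing releases solid drug
#' into a single absorbing small-intestinal compartment (Lint80 profile,
#' delayed additionally by gastric emptying), from which dissolved drug is
#' absorbed into the portal inflow (first pass) at
#' `ka = Peff * (surface/volume)` or lost by intestinal transit at
#' `1 / SITT`.
#'
#' @param individual An `individual_physiology`.
#' @param drug A `drug_parameters` record.
#' @param partitions A `partition_set` for this individual (default:
#'   computed from `drug` and `individual`).
#' @param clearances A `clearance_set` (default: built from `drug` and
#'   `individual`).
#' @param regimen A [dosing_regimen()].
#' @return Object of class `pbpk_system`: state matrix `A` (1/h), initial
#'   state, piecewise-constant forcing segments, and the inputs.
#' @export
build_ode_system <- function(individual, drug, partitions = NULL,
                             clearances = NULL, regimen) {
  validate_physiology(individual)
  stopifnot(inherits(regimen, "dosing_regimen"))
  if (is.null(partitions)) partitions <- compute_partition_set(drug, individual)
  if (is.null(clearances)) clearances <- build_clearance_set(drug, individual)

  missing_kb <- setdiff(.PERFUSED_ORGANS, names(partitions$Kb))
  if (length(missing_kb)) {
    stop("partition set lacks organs: ", paste(missing_kb, collapse = ", "),
         call. = FALSE)
  }

  V <- individual$organ_volumes
  Q <- individual$organ_blood_flows
  CO <- individual$cardiac_output
  QH <- individual$hepatic_blood_flow_QH
  Kb <- partitions$Kb
  fuB <- partitions$fu_blood
  CLint <- clearances$CLint_total * individual$cyp_activity_scalar
  CLR_b <- clearances$renal_plasma_clearance / partitions$bp_ratio
  if (CLR_b >= Q["kidney"]) {
    stop("renal blood clearance exceeds renal blood flow", call. = FALSE)
  }

  ns <- length(.STATE_NAMES)
  A <- matrix(0, ns, ns, dimnames = list(.STATE_NAMES, .STATE_NAMES))
  # outflow concentration coefficient per organ: C_out = amount / (V * Kb)
  oc <- function(org) 1 / (V[[org]] * Kb[[org]])
  ca <- 1 / V[["arterial_blood"]]
  cv <- 1 / V[["venous_blood"]]

  # lung in series with the heart
  A["lung", "venous_blood"] <- CO * cv
  A["lung", "lung"] <- -CO * oc("lung")
  A["arterial_blood", "lung"] <- CO * oc("lung")
  A["arterial_blood", "arterial_blood"] <- -CO * ca

  venous_returns <- setdiff(.SYSTEMIC_ORGANS, c("liver", "gut", "spleen"))
  for (org in venous_returns) {
    A[org, "arterial_blood"] <- A[org, "arterial_blood"] + Q[[org]] * ca
    A[org, org] <- A[org, org] - Q[[org]] * oc(org)
    A["venous_blood", org] <- Q[[org]] * oc(org)
  }
  # renal elimination from the kidney inflow
  A["kidney", "arterial_blood"] <- A["kidney", "arterial_blood"] - CLR_b * ca
  A["elim_renal", "arterial_blood"] <- CLR_b * ca

  # portal organs drain into the liver
  for (org in c("gut", "spleen")) {
    A[org, "arterial_blood"] <- A[org, "arterial_blood"] + Q[[org]] * ca
    A[org, org] <- A[org, org] - Q[[org]] * oc(org)
    A["liver", org] <- Q[[org]] * oc(org)
  }
  A["liver", "arterial_blood"] <- A["liver", "arterial_blood"] + Q[["liver"]] * ca
  A["liver", "liver"] <- -(QH + fuB * CLint) * oc("liver")
  A["venous_blood", "liver"] <- QH * oc("liver")
  A["venous_blood", "venous_blood"] <- -CO * cv
  A["elim_hepatic", "liver"] <- fuB * CLint * oc("liver")

  # oral lumen chain
  ka <- drug$intestinal_permeability_cm_min * 60 *
    (drug$absorption$surface_to_volume_per_cm %||% 1600)
  kt <- 60 / individual$small_intestinal_transit_time
  A["lumen_dissolved", "lumen_dissolved"] <- -(ka + kt)
  A["liver", "lumen_dissolved"] <- ka
  A["lumen_transit_lost", "lumen_dissolved"] <- kt

  # dosing: piecewise-constant forcing segments over the simulated horizon
  horizon <- max(regimen$times)
  y0 <- setNames(numeric(ns), .STATE_NAMES)
  zero <- y0
  dose <- regimen$dose_base
  if (regimen$route == "iv_infusion") {
    t_inf <- regimen$infusion_duration / 60
    b_inf <- zero
    b_inf["venous_blood"] <- dose / t_inf
    segments <- list(list(t0 = 0, t1 = min(t_inf, horizon), b = b_inf))
    if (horizon > t_inf) {
      segments <- c(segments, list(list(t0 = t_inf, t1 = horizon, b = zero)))
    }
  } else {
    y0["lumen_solid"] <- dose
    lag_h <- (regimen$lag_time + individual$gastric_emptying_time) / 60
    td_h <- regimen$dissolution_time / 60
    t_end <- lag_h + td_h * regimen$release_cap / 0.80
    rate <- dose * 0.80 / td_h
    b_rel <- zero
    b_rel["lumen_solid"] <- -rate
    b_rel["lumen_dissolved"] <- rate
    segments <- list()
    if (lag_h > 0) segments <- list(list(t0 = 0, t1 = min(lag_h, horizon), b = zero))
    if (horizon > lag_h) {
      segments <- c(segments, list(list(t0 = lag_h, t1 = min(t_end, horizon),
                                        b = b_rel)))
    }
    if (horizon > t_end) {
      segments <- c(segments, list(list(t0 = t_end, t1 = horizon, b = zero)))
    }
  }

  structure(list(A = A, y0 = y0, segments = segments,
                 individual = individual, drug = drug,
                 partitions = partitions, clearances = clearances,
                 regimen = regimen, dose = dose),
            class = "pbpk_system")
}

#' Integrate a PBPK system
#'
#' Runs the stiff solver (`deSolve::lsoda` with the analytic constant
#' Jacobian) segment-by-segment across the piecewise-constant dosing
#' forcing and returns the whole-blood (venous) concentration-time profile.
#'
#' @param system A `pbpk_system` from [build_ode_system()].
#' @param times Output grid, h; defaults to the regimen's grid.  Must span
#'   `[0, horizon]` of the system.
#' @param matrix Report concentrations in `"blood"` (default) or `"plasma"`
#'   (blood divided by the individual blood:plasma ratio).
#' @param rtol,atol Solver tolerances.
#' @return A `concentration_profile` data frame with columns `time_h`,
#'   `conc_ng_per_ml`, `matrix`, `subject_id`; the full amount-state matrix
#'   is attached as attribute `"states"`.
#' @examples
#' ref <- build_reference_adult("F", 25, 60)
#' hcq <- load_drug_parameters()
#' sys <- build_ode_system(ref, hcq,
#'                         regimen = dosing_regimen("iv_infusion", 155,
#'                                                  times = seq(0, 24, 0.5)))
#' prof <- simulate_profile(sys)
#' max(prof$conc_ng_per_ml)
#' @export
simulate_profile <- function(system, times = NULL,
                             matrix = c("blood", "plasma"),
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(system, "pbpk_system"))
  matrix <- match.arg(matrix)
  times <- times %||% system$regimen$times
  if (any(diff(times) <= 0)) stop_field("times", "must be strictly increasing")
  horizon <- max(vapply(system$segments, `[[`, numeric(1), "t1"))
  if (max(times) > horizon + 1e-9) {
    stop_field("times", "extend beyond the assembled dosing horizon")
  }

  A <- system$A
  y <- system$y0
  out <- matrix(NA_real_, nrow = length(times), ncol = length(y),
                dimnames = list(NULL, names(y)))
  if (times[1] == 0) out[1, ] <- y

  for (seg in system$segments) {
    b <- seg$b
    inside <- times[times > seg$t0 + 1e-12 & times <= seg$t1 + 1e-12]
    seg_times <- sort(unique(c(seg$t0, inside, seg$t1)))
    sol <- deSolve::ode(
      y = y, times = seg_times,
      func = function(t, y, p) list(A %*% y + b),
      parms = NULL,
      jacfunc = function(t, y, p) A,
      jactype = "fullusr",
      method = "lsoda", rtol = rtol, atol = atol
    )
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE integration failed in segment [", seg$t0, ", ", seg$t1,
           "] h; solver istate = ", attr(sol, "istate")[1], call. = FALSE)
    }
    y <- sol[nrow(sol), -1]
    if (length(inside)) {
      rows <- match(round(inside, 12), round(sol[, 1], 12))
      out[match(inside, times), ] <- sol[rows, -1, drop = FALSE]
    }
  }

  conc_blood <- out[, "venous_blood"] / system$individual$organ_volumes[["venous_blood"]]
  conc <- if (matrix == "blood") conc_blood else conc_blood / system$partitions$bp_ratio
  prof <- data.frame(time_h = times,
                     conc_ng_per_ml = conc * 1000,  # mg/L -> ng/mL
                     matrix = matrix,
                     subject_id = system$individual$subject_id,
                     stringsAsFactors = FALSE)
  class(prof) <- c("concentration_profile", "data.frame")
  attr(prof, "states") <- out
  attr(prof, "dose") <- system$dose
  attr(prof, "route") <- system$regimen$route
  prof
}

#' Mass-balance error of a simulated profile
#'
#' Total drug (body + eliminated + lumen states) must equal the dose at
#' every time after the dosing input has completed.
#'
#' @param profile A `concentration_profile` from [simulate_profile()].
#' @param after Only check times >= `after` (h); defaults to 0 for oral
#'   (the solid lumen state carries the dose from t = 0) and should cover
#'   the infusion end for IV.
#' @return Maximum relative deviation `|total - dose| / dose`.
#' @export
mass_balance_error <- function(profile, after = NULL) {
  states <- attr(profile, "states")
  dose <- attr(profile, "dose")
  if (is.null(after)) {
    after <- if (attr(profile, "route") == "iv_infusion") 1 else 0
  }
  keep <- profile$time_h >= after
  total <- rowSums(states[keep, , drop = FALSE])
  max(abs(total - dose) / dose)
}
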