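# Seeded synthetic "pseudo-observed" study data: sparse whole-blood
# concentration-time profiles with the structure of the published
# single-dose studies, so the full evaluation pipeline is testable without
# any external data.

.IV_GRID <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 24, 36, 48, 72)
.ORAL_GRID <- c(0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 12, 16, 24, 36, 48, 72, 96, 120)

#' Registry of study fixtures
#'
#' Eight single-dose healthy-adult study descriptors (3 IV-infusion, 5
#' oral) mirroring the published hydroxychloroquine studies: dose level
#' (155/310 mg base or 200 mg sulfate salt), 30-min infusions for every IV
#' entry, cohort size, female fraction and demographic summaries, plus a
#' default sparse sampling grid (dense over the first 2 h, sparse to 72 h
#' IV / 120 h oral).
#'
#' @return List of `study_fixture` objects.
#' @examples
#' reg <- make_fixture_registry()
#' length(reg)  # 8
#' @export
make_fixture_registry <- function() {
  fx <- function(study_id, route, dose_mg, dose_form, n_subjects,
                 female_fraction, age, weight, infusion_duration = NA_real_) {
    dose_base <- if (dose_form == "salt") salt_to_base_dose(dose_mg) else dose_mg
    structure(list(
      study_id = study_id, route = route,
      dose_mg = dose_mg, dose_form = dose_form, dose_base = dose_base,
      infusion_duration = infusion_duration,
      n_subjects = n_subjects, female_fraction = female_fraction,
      mean_age = age, mean_weight = weight,
      sampling_grid = if (route == "iv_infusion") .IV_GRID else .ORAL_GRID
    ), class = "study_fixture")
  }
  list(
    fx("iv_tett_1988", "iv_infusion", 310, "base", 5, 0.60, 22.6, 63.5, 30),
    fx("iv_tett_1989", "iv_infusion", 155, "base", 5, 0.60, 22.6, 63.5, 30),
    fx("iv_tett_1992", "iv_infusion", 155, "base", 9, 0.66, 24.4, 71.4, 30),
    fx("oral_williams_1988", "oral", 310, "base", 2, 0.50, 35, 86),
    fx("oral_tett_1989", "oral", 155, "base", 5, 0.60, 22.6, 63.5),
    fx("oral_tett_1992", "oral", 155, "base", 9, 0.66, 24.4, 71.4),
    fx("oral_ducharme_1995", "oral", 200, "salt", 24, 0.00, 28, 80),
    fx("oral_liu_2012", "oral", 200, "salt", 27, 0.00, 25, 63)
  )
}

#' Residual/parameter noise model for pseudo-observed data
#'
#' @param proportional_cv Proportional residual CV on the concentration
#'   scale (mean-unbiased multiplicative normal error).
#' @param additive_sd Additive residual SD, ng/mL.
#' @param parameter_perturbation_cv Log-normal CV applied to the
#'   generating drug parameters (hepatic and renal clearance, intestinal
#'   permeability).
#' @param seed Integer seed.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(proportional_cv = 0.15, additive_sd = 0,
                        parameter_perturbation_cv = 0.2, seed = 1L) {
  if (proportional_cv < 0 || additive_sd < 0 || parameter_perturbation_cv < 0) {
    stop_field("noise_model", "all components must be >= 0")
  }
  structure(list(proportional_cv = proportional_cv, additive_sd = additive_sd,
                 parameter_perturbation_cv = parameter_perturbation_cv,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate one pseudo-observed dataset
#'
#' Simulates the fixture's regimen for a representative individual with the
#' generating drug parameters perturbed log-normally
#' (`parameter_perturbation_cv`; the perturbed hepatic blood clearance is
#' clamped below the individual's unbound hepatic flow capacity so the
#' well-stirred back-calculation stays admissible), samples the clean
#' profile at the fixture grid, and applies mean-unbiased proportional plus
#' additive residual noise (floored at zero).  Returns both the noisy
#' profile and the ground truth (perturbed parameters, clean profile and
#' its NCA) for recovery tests.  Fully seeded: identical inputs give
#' identical datasets.
#'
#' @param fixture A `study_fixture`.
#' @param truth_drug Generating `drug_parameters` record.
#' @param noise A [noise_model()].
#' @return List with `observed` (`concentration_profile`), `truth` (list:
#'   `drug`, `profile`, `nca`), and `fixture`.
#' @export
generate_pseudo_observed <- function(fixture, truth_drug = load_drug_parameters(),
                                     noise = noise_model()) {
  stopifnot(inherits(fixture, "study_fixture"))
  sex <- if (fixture$female_fraction >= 0.5) "F" else "M"
  phys <- build_reference_adult(sex, fixture$mean_age, fixture$mean_weight,
                                subject_id = fixture$study_id)
  with_seed(noise$seed, {
    drug <- truth_drug
    pcv <- noise$parameter_perturbation_cv
    drug$hepatic_blood_clearance_L_h <-
      drug$hepatic_blood_clearance_L_h * lnorm_mult(1, pcv)
    drug$renal_plasma_clearance_L_h <-
      drug$renal_plasma_clearance_L_h * lnorm_mult(1, pcv)
    drug$intestinal_permeability_cm_min <-
      drug$intestinal_permeability_cm_min * lnorm_mult(1, pcv)
    fuB <- fu_blood(drug$fu_plasma, drug$blood_to_plasma_ratio)
    cap <- 0.90 * fuB * reference_QH()
    drug$hepatic_blood_clearance_L_h <- min(drug$hepatic_blood_clearance_L_h, cap)

    grid <- fixture$sampling_grid
    regimen <- if (fixture$route == "iv_infusion") {
      dosing_regimen("iv_infusion", fixture$dose_base,
                     infusion_duration = fixture$infusion_duration,
                     times = c(0, grid))
    } else {
      dosing_regimen("oral", fixture$dose_base,
                     dissolution_time = drug$formulation$dissolution_time_min,
                     lag_time = drug$formulation$lag_time_min,
                     release_cap = drug$formulation$release_cap,
                     times = c(0, grid))
    }
    sys <- build_ode_system(phys, drug, regimen = regimen)
    clean <- simulate_profile(sys)
    clean_obs <- clean[clean$time_h > 0, , drop = FALSE]

    eps <- rnorm(nrow(clean_obs), 0, noise$proportional_cv)
    add <- if (noise$additive_sd > 0) rnorm(nrow(clean_obs), 0, noise$additive_sd) else 0
    observed <- clean_obs
    observed$conc_ng_per_ml <- pmax(clean_obs$conc_ng_per_ml * (1 + eps) + add, 0)
    class(observed) <- c("concentration_profile", "data.frame")

    list(observed = observed,
         truth = list(drug = drug, profile = clean_obs,
                      nca = run_nca(clean_obs, fixture$dose_base)),
         fixture = fixture)
  })
}

#' Development / verification split of the fixture registry
#'
#' Deterministic split by registry order: the development third takes the
#' first IV and the first two oral fixtures; the remaining two IV and
#' three oral fixtures form the verification set.  All eight are used in
#' final evaluation.
#'
#' @param fixtures Registry from [make_fixture_registry()].
#' @return List with `development` and `verification` fixture lists.
#' @export
split_development_verification <- function(fixtures = make_fixture_registry()) {
  routes <- vapply(fixtures, `[[`, character(1), "route")
  iv_idx <- which(routes == "iv_infusion")
  oral_idx <- which(routes == "oral")
  dev <- sort(c(iv_idx[1], oral_idx[1:2]))
  list(development = fixtures[dev],
       verification = fixtures[setdiff(seq_along(fixtures), dev)])
}
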