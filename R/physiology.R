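# Reference adult physiology, virtual-population sampling and disease
# (cirrhosis / CKD) scaling.

#' Load the packaged reference physiology table
#'
#' Reads the ICRP-style reference adult table shipped with the package:
#' per-sex reference body weight, cardiac output, hematocrit and GFR, plus
#' organ volume fractions (of body weight) and blood-flow fractions (of
#' cardiac output).
#'
#' @param path Optional path to an alternative YAML table with the same
#'   structure.
#' @return A list with elements `reference`, `organ_volume_fractions`,
#'   `organ_flow_fractions`, `gastric_emptying_time_min`,
#'   `small_intestinal_transit_time_min`.
#' @export
load_reference_physiology <- function(path = hcq_extdata("reference_physiology.yaml")) {
  ref <- cached_yaml(path)
  stopifnot(all(c("reference", "organ_volume_fractions",
                  "organ_flow_fractions") %in% names(ref)))
  ref
}

#' Build a reference adult physiology
#'
#' Constructs one virtual adult by linearly rescaling the packaged reference
#' organ volumes and blood flows to the requested body weight
#' (allometric exponent 1 by default).  The construction is deterministic:
#' identical inputs give identical physiologies.
#'
#' @param sex `"F"` or `"M"`.
#' @param age Age in years, within `[18, 65]`.
#' @param weight Body weight in kg, within `[40, 120]`.
#' @param scaling_exponent Allometric exponent on the weight ratio applied
#'   to volumes and flows (default 1, i.e. linear).
#' @param reference Reference table from [load_reference_physiology()].
#' @param subject_id Identifier stored on the physiology.
#' @return An object of class `individual_physiology`: a list with organ
#'   volumes (L), organ blood flows (L/h), cardiac output, hepatic blood
#'   flow `QH` (hepatic artery + portal gut/spleen inflow), hematocrit,
#'   GFR (mL/min/1.73 m2), binding-protein and CYP-activity scalars and
#'   gastrointestinal transit times (min).
#' @examples
#' adult <- build_reference_adult("F", age = 22.6, weight = 63.5)
#' adult$hepatic_blood_flow_QH
#' @export
build_reference_adult <- function(sex, age, weight,
                                  scaling_exponent = 1,
                                  reference = load_reference_physiology(),
                                  subject_id = "ref") {
  sex <- match.arg(sex, c("F", "M"))
  if (!is.numeric(age) || length(age) != 1L || age < 18 || age > 65) {
    stop_field("age", "must be a single value in [18, 65] years")
  }
  if (!is.numeric(weight) || length(weight) != 1L || weight < 40 || weight > 120) {
    stop_field("weight", "must be a single value in [40, 120] kg")
  }
  sexref <- reference$reference[[sex]]
  wr <- (weight / sexref$body_weight_kg)^scaling_exponent

  vfrac <- unlist(reference$organ_volume_fractions)
  missing_v <- setdiff(c(.PERFUSED_ORGANS, .BLOOD_COMPARTMENTS), names(vfrac))
  if (length(missing_v)) {
    stop("reference table lacks volume fractions for: ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  }
  # fractions are quoted at the reference body weight; linear-in-weight by
  # construction, other exponents rescale the reference organ sizes
  volumes <- vfrac[c(.PERFUSED_ORGANS, .BLOOD_COMPARTMENTS)] *
    sexref$body_weight_kg * wr

  ffrac <- unlist(reference$organ_flow_fractions)
  missing_f <- setdiff(.SYSTEMIC_ORGANS, names(ffrac))
  if (length(missing_f)) {
    stop("reference table lacks flow fractions for: ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(ffrac) - 1) > 1e-9) {
    stop("reference flow fractions must sum to 1", call. = FALSE)
  }
  co <- sexref$cardiac_output_L_h * wr
  flows <- ffrac[.SYSTEMIC_ORGANS] * co

  phys <- structure(list(
    subject_id = subject_id,
    sex = sex,
    age = age,
    body_weight = weight,
    hematocrit = sexref$hematocrit,
    organ_volumes = volumes,
    organ_blood_flows = flows,
    cardiac_output = sum(flows),
    hepatic_blood_flow_QH = unname(flows["liver"] + flows["gut"] + flows["spleen"]),
    GFR = sexref$GFR_ml_min_1.73m2,
    binding_protein_scalar = 1.0,
    cyp_activity_scalar = 1.0,
    gastric_emptying_time = reference$gastric_emptying_time_min,
    small_intestinal_transit_time = reference$small_intestinal_transit_time_min,
    disease_stage = "healthy"
  ), class = "individual_physiology")
  validate_physiology(phys)
}

#' Validate an individual physiology
#'
#' Checks positivity of all volumes and flows, hematocrit in (0,1),
#' flow balance (organ outflows sum to cardiac output within 1e-6
#' relative) and the hepatic-inflow identity
#' `QH = hepatic artery + gut + spleen`.
#'
#' @param phys An `individual_physiology`.
#' @return `phys`, invisibly unchanged, or an error.
#' @export
validate_physiology <- function(phys) {
  if (!inherits(phys, "individual_physiology")) {
    stop("not an individual_physiology object", call. = FALSE)
  }
  v <- phys$organ_volumes
  f <- phys$organ_blood_flows
  if (any(!is.finite(v)) || any(v <= 0)) stop_field("organ_volumes", "must all be positive")
  if (any(!is.finite(f)) || any(f <= 0)) stop_field("organ_blood_flows", "must all be positive")
  if (phys$hematocrit <= 0 || phys$hematocrit >= 1) {
    stop_field("hematocrit", "must lie in (0, 1)")
  }
  if (phys$GFR <= 0) stop_field("GFR", "must be positive")
  if (phys$binding_protein_scalar <= 0) {
    stop_field("binding_protein_scalar", "must be positive")
  }
  if (abs(sum(f) - phys$cardiac_output) > 1e-6 * phys$cardiac_output) {
    stop_field("cardiac_output", "organ outflows do not balance cardiac output")
  }
  qh <- unname(f["liver"] + f["gut"] + f["spleen"])
  if (abs(qh - phys$hepatic_blood_flow_QH) > 1e-6 * qh) {
    stop_field("hepatic_blood_flow_QH",
               "must equal hepatic artery + portal (gut + spleen) inflow")
  }
  invisible(phys)
}

#' @export
print.individual_physiology <- function(x, ...) {
  cat(sprintf("<individual_physiology> %s: %s, %.1f y, %.1f kg [%s]\n",
              x$subject_id, x$sex, x$age, x$body_weight, x$disease_stage))
  cat(sprintf("  cardiac output %.1f L/h, QH %.1f L/h, Hct %.2f, GFR %.0f mL/min/1.73m2\n",
              x$cardiac_output, x$hepatic_blood_flow_QH, x$hematocrit, x$GFR))
  invisible(x)
}

#' Specify a virtual population
#'
#' @param n Number of individuals (>= 1).
#' @param female_fraction Fraction of females in `[0, 1]`; the female count
#'   is `round(n * female_fraction)`.
#' @param age_range Two-element range in years.
#' @param weight_range Two-element range in kg; the sampling centre is its
#'   midpoint.
#' @param variability_cv Named list/vector of log-normal coefficients of
#'   variation.  Recognised names: `body_weight`, `organ_volumes`,
#'   `organ_blood_flows`, `hematocrit`, `GFR`.  Unnamed parameters fall
#'   back to the defaults (0.1 weight, 0.2 volumes/flows, 0.05 hematocrit,
#'   0.2 GFR).
#' @param seed Integer seed; identical specs give bit-identical populations.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n = 100, female_fraction = 0.6,
                            age_range = c(19, 27), weight_range = c(55, 68),
                            variability_cv = list(), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop_field("n", "must be an integer >= 1")
  }
  if (female_fraction < 0 || female_fraction > 1) {
    stop_field("female_fraction", "must lie in [0, 1]")
  }
  cv <- list(body_weight = 0.10, organ_volumes = 0.20, organ_blood_flows = 0.20,
             hematocrit = 0.05, GFR = 0.20)
  for (nm in names(variability_cv)) {
    if (!nm %in% names(cv)) stop_field("variability_cv", paste("unknown parameter", nm))
    if (variability_cv[[nm]] < 0) stop_field("variability_cv", "CVs must be >= 0")
    cv[[nm]] <- variability_cv[[nm]]
  }
  structure(list(n = as.integer(n), female_fraction = female_fraction,
                 age_range = sort(age_range), weight_range = sort(weight_range),
                 variability_cv = cv, seed = as.integer(seed)),
            class = "population_spec")
}

# mean-1 log-normal multipliers for a given CV
lnorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Sample a virtual population
#'
#' Draws `n` individuals around the sex-specific reference physiology.
#' Ages are uniform over `age_range`; body weight is the midpoint of
#' `weight_range` times a mean-one log-normal multiplier; organ volumes,
#' blood flows, hematocrit and GFR receive independent mean-one log-normal
#' multipliers with the spec's CVs, after which flows are re-balanced so
#' cardiac output equals the sum of organ outflows.
#'
#' @param spec A [population_spec()].
#' @param reference Reference table from [load_reference_physiology()].
#' @return List of `individual_physiology` objects of length `spec$n`.
#' @examples
#' pop <- sample_population(population_spec(n = 5, seed = 42))
#' sapply(pop, function(p) p$body_weight)
#' @export
sample_population <- function(spec, reference = load_reference_physiology()) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n
  n_f <- round(n * spec$female_fraction)
  sexes <- c(rep("F", n_f), rep("M", n - n_f))
  cv <- spec$variability_cv
  with_seed(spec$seed, {
    ages <- runif(n, spec$age_range[1], spec$age_range[2])
    w_mid <- mean(spec$weight_range)
    weights <- w_mid * lnorm_mult(n, cv$body_weight)
    weights <- pmin(pmax(weights, 40), 120)
    lapply(seq_len(n), function(i) {
      phys <- build_reference_adult(sexes[i], ages[i], weights[i],
                                    reference = reference,
                                    subject_id = sprintf("S%03d", i))
      nv <- length(phys$organ_volumes)
      nf <- length(phys$organ_blood_flows)
      phys$organ_volumes <- phys$organ_volumes * lnorm_mult(nv, cv$organ_volumes)
      phys$organ_blood_flows <- phys$organ_blood_flows *
        lnorm_mult(nf, cv$organ_blood_flows)
      phys$cardiac_output <- sum(phys$organ_blood_flows)
      phys$hepatic_blood_flow_QH <- unname(phys$organ_blood_flows["liver"] +
                                             phys$organ_blood_flows["gut"] +
                                             phys$organ_blood_flows["spleen"])
      phys$hematocrit <- min(max(phys$hematocrit * lnorm_mult(1, cv$hematocrit),
                                 0.15), 0.60)
      phys$GFR <- phys$GFR * lnorm_mult(1, cv$GFR)
      validate_physiology(phys)
    })
  })
}

#' Load the packaged disease-stage scaler tables
#'
#' @param path Optional alternative YAML file with the same structure.
#' @return Named list of per-stage `multipliers` / `overrides` blocks.
#' @export
load_disease_scalers <- function(path = hcq_extdata("disease_scalers.yaml")) {
  cached_yaml(path)
}

#' Specify a disease stage
#'
#' @param stage One of `"healthy"`, `"CP-A"`, `"CP-B"`, `"CP-C"`,
#'   `"CKD-moderate"`, `"CKD-severe"`.
#' @param scalers Scaler table from [load_disease_scalers()].
#' @return Object of class `disease_spec` with `stage`, `multipliers`,
#'   `overrides`.
#' @export
disease_spec <- function(stage, scalers = load_disease_scalers()) {
  if (!stage %in% .DISEASE_STAGES) {
    stop_field("stage", paste("unknown disease stage:", stage))
  }
  if (!stage %in% names(scalers)) {
    stop_field("stage", paste("no scaler entry for stage:", stage))
  }
  entry <- scalers[[stage]]
  mult <- entry$multipliers %||% list()
  if (length(mult) && any(unlist(mult) <= 0)) {
    stop_field("scalers", "all multipliers must be positive")
  }
  structure(list(stage = stage, multipliers = mult,
                 overrides = entry$overrides %||% list()),
            class = "disease_spec")
}

#' Apply disease-stage scaling to a physiology
#'
#' Returns a new physiology with the stage's multipliers and overrides
#' applied: functional liver volume, hepatic CYP activity, splanchnic
#' (hepatic artery + gut + spleen) and renal blood flow, GFR, hematocrit,
#' binding-protein (alpha-1 acid glycoprotein) scalar and gastrointestinal
#' transit times.  Cardiac output and hepatic inflow are re-balanced from
#' the scaled organ flows and all invariants re-validated.  The input
#' object is not modified.
#'
#' @param phys An `individual_physiology`.
#' @param disease A [disease_spec()] (or a stage name, resolved against the
#'   packaged default scalers).
#' @return A new validated `individual_physiology`.
#' @examples
#' ref <- build_reference_adult("F", 25, 60)
#' ckd <- apply_disease(ref, "CKD-severe")
#' ckd$GFR
#' @export
apply_disease <- function(phys, disease) {
  validate_physiology(phys)
  if (is.character(disease)) disease <- disease_spec(disease)
  stopifnot(inherits(disease, "disease_spec"))
  out <- phys
  m <- disease$multipliers
  ov <- disease$overrides

  if (!is.null(m$liver_volume)) {
    out$organ_volumes["liver"] <- out$organ_volumes["liver"] * m$liver_volume
    # shrinking functional liver shrinks whole-liver metabolic capacity too
    out$cyp_activity_scalar <- out$cyp_activity_scalar * m$liver_volume
  }
  if (!is.null(m$splanchnic_flow)) {
    for (org in c("liver", "gut", "spleen")) {
      out$organ_blood_flows[org] <- out$organ_blood_flows[org] * m$splanchnic_flow
    }
  }
  if (!is.null(m$renal_flow)) {
    out$organ_blood_flows["kidney"] <- out$organ_blood_flows["kidney"] * m$renal_flow
  }
  if (!is.null(m$hematocrit)) out$hematocrit <- out$hematocrit * m$hematocrit
  if (!is.null(m$GFR)) out$GFR <- out$GFR * m$GFR
  if (!is.null(m$binding_protein)) {
    out$binding_protein_scalar <- out$binding_protein_scalar * m$binding_protein
  }
  if (!is.null(m$cyp_activity)) {
    out$cyp_activity_scalar <- out$cyp_activity_scalar * m$cyp_activity
  }
  if (!is.null(m$gastric_emptying_time)) {
    out$gastric_emptying_time <- out$gastric_emptying_time * m$gastric_emptying_time
  }
  if (!is.null(m$small_intestinal_transit_time)) {
    out$small_intestinal_transit_time <-
      out$small_intestinal_transit_time * m$small_intestinal_transit_time
  }
  if (!is.null(ov$GFR)) out$GFR <- ov$GFR

  out$cardiac_output <- sum(out$organ_blood_flows)
  out$hepatic_blood_flow_QH <- unname(out$organ_blood_flows["liver"] +
                                        out$organ_blood_flows["gut"] +
                                        out$organ_blood_flows["spleen"])
  out$disease_stage <- disease$stage
  validate_physiology(out)
}

#' Flatten a population to a data frame
#'
#' One row per individual; organ volumes and flows become `vol_*` / `flow_*`
#' columns.  Suitable for CSV/JSON export.
#'
#' @param population List of `individual_physiology` objects.
#' @return A `data.frame`.
#' @export
population_to_df <- function(population) {
  rows <- lapply(population, function(p) {
    base <- data.frame(
      subject_id = p$subject_id, sex = p$sex, age = p$age,
      body_weight = p$body_weight, hematocrit = p$hematocrit,
      cardiac_output = p$cardiac_output,
      hepatic_blood_flow_QH = p$hepatic_blood_flow_QH,
      GFR = p$GFR, binding_protein_scalar = p$binding_protein_scalar,
      cyp_activity_scalar = p$cyp_activity_scalar,
      gastric_emptying_time = p$gastric_emptying_time,
      small_intestinal_transit_time = p$small_intestinal_transit_time,
      disease_stage = p$disease_stage,
      stringsAsFactors = FALSE
    )
    vols <- as.data.frame(as.list(setNames(p$organ_volumes,
                                           paste0("vol_", names(p$organ_volumes)))))
    flows <- as.data.frame(as.list(setNames(p$organ_blood_flows,
                                            paste0("flow_", names(p$organ_blood_flows)))))
    cbind(base, vols, flows)
  })
  do.call(rbind, rows)
}
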