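# Drug parameter record, blood/plasma conversions, dose bookkeeping and
# tissue partition coefficients (Rodgers-Rowland tissue-composition scheme).

#' Load a drug parameter file
#'
#' Reads a YAML drug record (the packaged hydroxychloroquine file by
#' default): physicochemical properties (MW, logP, pKa), plasma binding,
#' blood-to-plasma ratio, solubility, intestinal permeability, renal and
#' hepatic clearance inputs, CYP apportionment defaults and formulation
#' (Lint80) parameters.
#'
#' @param path YAML file path; defaults to the packaged hydroxychloroquine
#'   record.
#' @return Object of class `drug_parameters` (named list).
#' @examples
#' hcq <- load_drug_parameters()
#' hcq$blood_to_plasma_ratio
#' @export
load_drug_parameters <- function(path = hcq_extdata("hydroxychloroquine.yaml")) {
  drug <- cached_yaml(path)
  class(drug) <- "drug_parameters"
  validate_drug_parameters(drug)
}

#' Validate a drug parameter record
#'
#' @param drug A `drug_parameters` object.
#' @return `drug`, invisibly, or an error naming the offending field.
#' @export
validate_drug_parameters <- function(drug) {
  if (drug$molecular_weight_g_mol <= 0) stop_field("molecular_weight_g_mol", "must be > 0")
  if (drug$fu_plasma <= 0 || drug$fu_plasma > 1) stop_field("fu_plasma", "must lie in (0, 1]")
  if (drug$blood_to_plasma_ratio <= 0) stop_field("blood_to_plasma_ratio", "must be > 0")
  if (drug$renal_plasma_clearance_L_h < 0) stop_field("renal_plasma_clearance_L_h", "must be >= 0")
  if (!is.null(drug$hepatic_blood_clearance_L_h) &&
      drug$hepatic_blood_clearance_L_h < 0) {
    stop_field("hepatic_blood_clearance_L_h", "must be >= 0")
  }
  invisible(drug)
}

#' Write a drug parameter record back to YAML
#'
#' Round-trips with [load_drug_parameters()].
#'
#' @param drug A `drug_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_drug_parameters <- function(drug, path) {
  yaml::write_yaml(unclass(drug), path)
  invisible(path)
}

#' Unbound fraction in whole blood
#'
#' `fuB = fu_plasma / (blood:plasma ratio)`, capped at 1.  This is the
#' binding term of the well-stirred liver model when clearances are
#' referenced to whole-blood concentrations.
#'
#' @param fu_plasma Unbound fraction in plasma, in (0, 1].
#' @param bp_ratio Whole-blood to plasma concentration ratio, > 0.
#' @return Unbound fraction in blood, in (0, 1].
#' @examples
#' fu_blood(0.48, 7.2)  # 0.0667
#' @export
fu_blood <- function(fu_plasma, bp_ratio) {
  if (!is.numeric(bp_ratio) || bp_ratio <= 0) {
    stop_field("bp_ratio", "must be > 0")
  }
  if (fu_plasma <= 0 || fu_plasma > 1) stop_field("fu_plasma", "must lie in (0, 1]")
  min(fu_plasma / bp_ratio, 1)
}

#' Convert a sulfate-salt dose to the free-base dose
#'
#' The sulfate salt carries 77.5 % of its mass as free base
#' (200 mg salt = 155 mg base).
#'
#' @param dose_salt Salt dose in mg, >= 0.
#' @return Base dose in mg.
#' @examples
#' salt_to_base_dose(200)  # 155
#' @export
salt_to_base_dose <- function(dose_salt) {
  if (any(dose_salt < 0)) stop_field("dose_salt", "must be >= 0")
  dose_salt * 0.775
}

#' Load the packaged tissue-composition table
#'
#' @param path Optional alternative YAML file.
#' @return List with `pH`, `tissues`, `blood_cells` blocks.
#' @export
load_tissue_composition <- function(path = hcq_extdata("tissue_composition.yaml")) {
  cached_yaml(path)
}

# ionisation term of the Henderson-Hasselbalch equilibrium for a (di)protic
# base: sum over protonation states of 10^(sum(pKa_i) - k*pH)
ionization_X <- function(pKa, pH) {
  if (is.null(pKa) || length(pKa) == 0) return(0)
  pKa <- sort(as.numeric(pKa), decreasing = TRUE)
  x <- 10^(pKa[1] - pH)
  if (length(pKa) >= 2) x <- x + 10^(pKa[1] + pKa[2] - 2 * pH)
  x
}

#' Tissue-to-plasma partition coefficients (Rodgers-Rowland scheme)
#'
#' Computes unbound tissue:plasma partition coefficients for a
#' (di)protic base from tissue composition (extra/intracellular water,
#' neutral lipid, neutral phospholipid, acidic phospholipid), lipophilicity
#' and ionisation, then converts to total Kp with the individual's plasma
#' unbound fraction.  The acidic-phospholipid association constant is
#' calibrated from the drug's measured blood-to-plasma ratio at the
#' reference hematocrit, so the scheme reproduces the observed erythrocyte
#' partitioning by construction; the individual's blood:plasma ratio and
#' whole-blood unbound fraction are then re-derived from the individual's
#' hematocrit and binding-protein scalar.
#'
#' The computation is deterministic; identical inputs give identical output.
#'
#' @param drug A `drug_parameters` record.
#' @param physiology An `individual_physiology` (hematocrit and
#'   binding-protein scalar are used).
#' @param composition Tissue-composition table from
#'   [load_tissue_composition()].
#' @param reference_hematocrit Hematocrit at which the drug's quoted
#'   blood:plasma ratio was measured.
#' @return Object of class `partition_set`: `Kp` (tissue:plasma), `Kpu`
#'   (tissue:plasma-unbound), `Kb` (tissue:blood), `fu` (individual plasma
#'   unbound fraction), `fu_blood`, `bp_ratio` (individual whole-blood to
#'   plasma ratio) and `KaAP`.
#' @examples
#' hcq <- load_drug_parameters()
#' ref <- build_reference_adult("F", 25, 60)
#' ps <- compute_partition_set(hcq, ref)
#' ps$Kp["muscle"] > ps$Kp["adipose"]  # strong base: lean tissue binding
#' @export
compute_partition_set <- function(drug, physiology,
                                  composition = load_tissue_composition(),
                                  reference_hematocrit = 0.45) {
  validate_drug_parameters(drug)
  validate_physiology(physiology)

  pH_p <- composition$pH$plasma
  pH_iw <- composition$pH$intracellular
  pH_bc <- composition$pH$blood_cells
  P <- 10^drug$logP
  X_p <- ionization_X(drug$pKa, pH_p)
  X_iw <- ionization_X(drug$pKa, pH_iw)
  X_bc <- ionization_X(drug$pKa, pH_bc)

  # individual plasma unbound fraction: binding protein reduced in disease
  fu_ref <- drug$fu_plasma
  fu <- min(fu_ref / physiology$binding_protein_scalar, 1)

  bc <- composition$blood_cells
  nl_term_bc <- (P * bc$f_nl + (0.3 * P + 0.7) * bc$f_np) / (1 + X_p)
  w_term_bc <- bc$f_w * (1 + X_bc) / (1 + X_p)

  # calibrate the acidic-phospholipid association constant from the quoted
  # blood:plasma ratio (at reference hematocrit and reference fu)
  KaAP <- 0
  if (X_bc > 1e-12 && !is.null(drug$blood_to_plasma_ratio)) {
    kp_bc_ref <- (drug$blood_to_plasma_ratio - (1 - reference_hematocrit)) /
      reference_hematocrit
    if (kp_bc_ref <= 0) {
      stop("blood:plasma ratio inconsistent with reference hematocrit",
           call. = FALSE)
    }
    kpu_bc_ref <- kp_bc_ref / fu_ref
    KaAP <- max(0, (kpu_bc_ref - w_term_bc - nl_term_bc) *
                  (1 + X_p) / (bc$ap_mg_g * X_bc))
  }

  organs <- .PERFUSED_ORGANS
  kpu <- vapply(organs, function(org) {
    tc <- composition$tissues[[org]]
    if (is.null(tc)) {
      stop("tissue-composition table has no entry for organ: ", org,
           call. = FALSE)
    }
    tc$f_ew +
      tc$f_iw * (1 + X_iw) / (1 + X_p) +
      KaAP * tc$ap_mg_g * X_iw / (1 + X_p) +
      (P * tc$f_nl + (0.3 * P + 0.7) * tc$f_np) / (1 + X_p)
  }, numeric(1))

  # erythrocyte partitioning and individual blood:plasma ratio
  kpu_bc <- w_term_bc + KaAP * bc$ap_mg_g * X_bc / (1 + X_p) + nl_term_bc
  hct <- physiology$hematocrit
  bp_ind <- (1 - hct) + hct * kpu_bc * fu
  Kp <- kpu * fu

  structure(list(
    Kp = Kp,
    Kpu = kpu,
    Kb = Kp / bp_ind,
    fu = fu,
    fu_blood = min(fu / bp_ind, 1),
    bp_ratio = bp_ind,
    KaAP = KaAP,
    Kpu_blood_cells = kpu_bc
  ), class = "partition_set")
}

#' @export
print.partition_set <- function(x, ...) {
  cat("<partition_set> fu =", signif(x$fu, 3),
      " fuB =", signif(x$fu_blood, 3),
      " B:P =", signif(x$bp_ratio, 3), "\n")
  print(round(x$Kp, 2))
  invisible(x)
}
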