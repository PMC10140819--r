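# Hepatic intrinsic-clearance back-calculation (well-stirred liver model),
# CYP apportionment and clearance terms for the ODE engine.

# L/h -> uL/min
.L_H_TO_UL_MIN <- 1e6 / 60

#' Reference hepatic blood flow
#'
#' QH of the reference female adult (hepatic artery + portal inflow), used
#' as the anchor for the drug-level intrinsic-clearance back-calculation.
#'
#' @param reference Table from [load_reference_physiology()].
#' @return Hepatic blood flow, L/h.
#' @export
reference_QH <- function(reference = load_reference_physiology()) {
  f <- reference$organ_flow_fractions
  reference$reference$F$cardiac_output_L_h * (f$liver + f$gut + f$spleen)
}

#' Back-calculate hepatic intrinsic clearance
#'
#' Inverts the well-stirred liver model to recover whole-liver intrinsic
#' clearance from hepatic blood flow `QH`, hepatic blood clearance `CLH`
#' and the unbound fraction in blood `fuB`.  Two algebraic forms are
#' provided:
#' \describe{
#'   \item{`as_printed`}{`CLint = QH * CLH / (fuB * QH - CLH)` — the form
#'     with the binding term applied to hepatic flow only.  Default.}
#'   \item{`standard_well_stirred`}{`CLint = QH * CLH / (fuB * (QH - CLH))`
#'     — the exact inverse of [hepatic_clearance_term()].}
#' }
#' Both forms agree in the low-extraction limit `CLH << QH`; they are both
#' reported by [clearance_explain()].
#'
#' @param QH Hepatic blood flow, L/h.
#' @param CLH Hepatic blood clearance, L/h, with `0 <= CLH < QH`.
#' @param fuB Unbound fraction in whole blood, in (0, 1].
#' @param form `"as_printed"` (default) or `"standard_well_stirred"`.
#' @return Intrinsic clearance, L/h (whole-blood referenced).
#' @examples
#' back_calculate_clint(90, 1.5, 0.0667)  # 30.0 L/h
#' @export
back_calculate_clint <- function(QH, CLH, fuB,
                                 form = c("as_printed", "standard_well_stirred")) {
  form <- match.arg(form)
  if (QH <= 0) stop_field("QH", "must be > 0")
  if (CLH < 0) stop_field("CLH", "must be >= 0")
  if (fuB <= 0 || fuB > 1) stop_field("fuB", "must lie in (0, 1]")
  if (CLH == 0) return(0)
  den <- switch(form,
                as_printed = fuB * QH - CLH,
                standard_well_stirred = fuB * (QH - CLH))
  if (den <= 0) {
    stop("hepatic clearance exceeds unbound hepatic flow capacity",
         call. = FALSE)
  }
  QH * CLH / den
}

#' Forward well-stirred hepatic clearance
#'
#' `CLH = QH * fuB * CLint / (QH + fuB * CLint)`; bounded above by the
#' hepatic blood flow (flow-limited ceiling).
#'
#' @param CLint Intrinsic clearance, L/h, >= 0.
#' @param QH Hepatic blood flow, L/h, > 0.
#' @param fuB Unbound fraction in whole blood, in (0, 1].
#' @return Hepatic blood clearance, L/h, strictly < `QH`.
#' @export
hepatic_clearance_term <- function(CLint, QH, fuB) {
  if (QH <= 0) stop_field("QH", "must be > 0")
  if (CLint < 0) stop_field("CLint", "must be >= 0")
  if (fuB <= 0 || fuB > 1) stop_field("fuB", "must lie in (0, 1]")
  QH * fuB * CLint / (QH + fuB * CLint)
}

#' Apportion whole-liver intrinsic clearance to CYP enzymes
#'
#' Splits total intrinsic clearance by fractional enzyme contribution and
#' divides by whole-liver enzyme abundance, giving per-enzyme in vitro
#' clearances in uL/min/pmol (1 L/h = 1e6/60 uL/min).  Re-aggregating
#' `sum(value_e * abundance_e)` reconstructs the total.
#'
#' @param CLint_total Whole-liver intrinsic clearance, L/h.
#' @param contributions Named fractions summing to 1.
#' @param abundances Named whole-liver abundances, pmol, > 0; must cover
#'   the same enzymes.
#' @return Named numeric vector, uL/min/pmol.
#' @export
apportion_to_enzymes <- function(CLint_total, contributions, abundances) {
  contributions <- unlist(contributions)
  abundances <- unlist(abundances)
  missing <- union(setdiff(names(contributions), names(abundances)),
                   setdiff(names(abundances), names(contributions)))
  if (length(missing)) {
    stop("enzyme missing from contributions or abundances: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(contributions) - 1) > 1e-9) {
    stop_field("contributions", "must sum to 1")
  }
  if (any(abundances <= 0)) stop_field("abundances", "must all be > 0")
  if (CLint_total < 0) stop_field("CLint_total", "must be >= 0")
  clint_ul_min <- CLint_total * .L_H_TO_UL_MIN
  (clint_ul_min * contributions / abundances[names(contributions)])
}

#' Re-aggregate per-enzyme in vitro clearances to whole-liver CLint
#'
#' Inverse of [apportion_to_enzymes()].
#'
#' @param per_enzyme Named uL/min/pmol values.
#' @param abundances Named whole-liver abundances, pmol.
#' @return Whole-liver intrinsic clearance, L/h.
#' @export
aggregate_enzyme_clint <- function(per_enzyme, abundances) {
  per_enzyme <- unlist(per_enzyme)
  abundances <- unlist(abundances)
  sum(per_enzyme * abundances[names(per_enzyme)]) / .L_H_TO_UL_MIN
}

#' GFR-proportional renal clearance
#'
#' Scales the healthy renal plasma clearance by the patient-to-reference
#' GFR ratio.
#'
#' @param CLR_plasma_healthy Healthy renal plasma clearance, L/h.
#' @param GFR_patient,GFR_reference GFR, mL/min/1.73 m2, > 0.
#' @return Renal plasma clearance, L/h.
#' @examples
#' renal_clearance_scaled(12.7, 45, 90)  # 6.35
#' @export
renal_clearance_scaled <- function(CLR_plasma_healthy, GFR_patient,
                                   GFR_reference = 90) {
  if (GFR_patient <= 0 || GFR_reference <= 0) {
    stop_field("GFR", "must be > 0")
  }
  CLR_plasma_healthy * GFR_patient / GFR_reference
}

#' Assemble the clearance set for one individual
#'
#' Back-calculates whole-liver intrinsic clearance from the drug record's
#' healthy hepatic blood clearance using the individual's hepatic blood
#' flow and reference whole-blood unbound fraction, apportions it to the
#' configured CYP enzymes, and scales renal plasma clearance with the
#' individual's GFR.  Disease stages act later through the physiology's
#' CYP-activity scalar and the partition set's individual `fuB`.
#'
#' The back-calculation is anchored at the reference-adult hepatic blood
#' flow (one drug-level CLint), not at each sampled individual's perturbed
#' flow: intrinsic clearance is a property of the drug-enzyme system, and
#' per-individual hepatic clearance then emerges from the well-stirred sink
#' inside the ODE model.
#'
#' @param drug A `drug_parameters` record.
#' @param physiology An `individual_physiology`.
#' @param GFR_reference Healthy reference GFR (mL/min/1.73 m2).
#' @param form Equation form passed to [back_calculate_clint()]; defaults
#'   to the drug file's `clearance$eq_form`.
#' @param QH_reference Hepatic blood flow used in the back-calculation;
#'   defaults to the reference female adult's QH.
#' @return Object of class `clearance_set` with `CLint_total` (L/h, healthy
#'   whole liver), `per_enzyme_invitro` (uL/min/pmol), `renal_plasma_clearance`
#'   (L/h, GFR-scaled), `fuB_reference` and the inputs used.
#' @export
build_clearance_set <- function(drug, physiology, GFR_reference = 90,
                                form = NULL, QH_reference = NULL) {
  validate_drug_parameters(drug)
  validate_physiology(physiology)
  form <- form %||% (drug$clearance$eq_form %||% "as_printed")
  fuB_ref <- fu_blood(drug$fu_plasma, drug$blood_to_plasma_ratio)
  QH <- QH_reference %||% reference_QH()
  CLH <- drug$hepatic_blood_clearance_L_h
  clint <- back_calculate_clint(QH, CLH, fuB_ref, form = form)
  per_enz <- apportion_to_enzymes(clint,
                                  drug$clearance$enzyme_contributions,
                                  drug$clearance$enzyme_abundance_pmol)
  structure(list(
    CLint_total = clint,
    per_enzyme_invitro = per_enz,
    renal_plasma_clearance = renal_clearance_scaled(
      drug$renal_plasma_clearance_L_h, physiology$GFR, GFR_reference),
    fuB_reference = fuB_ref,
    QH = QH, CLH = CLH, form = form,
    GFR_reference = GFR_reference
  ), class = "clearance_set")
}

#' Print the full clearance back-calculation chain
#'
#' Walks through the computation with units: unbound blood fraction, both
#' algebraic forms of the intrinsic-clearance back-calculation, the CYP
#' apportionment and the GFR-scaled renal clearance.
#'
#' @param drug A `drug_parameters` record.
#' @param physiology An `individual_physiology`; defaults to the reference
#'   female adult.
#' @return The `clearance_set`, invisibly.
#' @export
clearance_explain <- function(drug = load_drug_parameters(),
                              physiology = build_reference_adult("F", 25, 60)) {
  fuB <- fu_blood(drug$fu_plasma, drug$blood_to_plasma_ratio)
  QH <- reference_QH()
  CLH <- drug$hepatic_blood_clearance_L_h
  cat(sprintf("fuB = fu/BP = %.3g / %.3g = %.4g\n",
              drug$fu_plasma, drug$blood_to_plasma_ratio, fuB))
  cat(sprintf("QH  = %.4g L/h (reference hepatic artery + portal inflow)\n", QH))
  cat(sprintf("CLH = %.4g L/h (whole-blood hepatic clearance)\n", CLH))
  cl_p <- back_calculate_clint(QH, CLH, fuB, "as_printed")
  cl_s <- back_calculate_clint(QH, CLH, fuB, "standard_well_stirred")
  cat(sprintf("CLint [as_printed]            = QH*CLH/(fuB*QH - CLH)   = %.4g L/h\n", cl_p))
  cat(sprintf("CLint [standard_well_stirred] = QH*CLH/(fuB*(QH - CLH)) = %.4g L/h\n", cl_s))
  cs <- build_clearance_set(drug, physiology)
  cat(sprintf("using form '%s': CLint = %.4g L/h = %.4g uL/min\n",
              cs$form, cs$CLint_total, cs$CLint_total * .L_H_TO_UL_MIN))
  for (e in names(cs$per_enzyme_invitro)) {
    cat(sprintf("  %s: %.3g x CLint / %.3g pmol = %.4g uL/min/pmol\n", e,
                drug$clearance$enzyme_contributions[[e]],
                drug$clearance$enzyme_abundance_pmol[[e]],
                cs$per_enzyme_invitro[[e]]))
  }
  cat(sprintf("renal plasma CL = %.4g x GFR(%.3g)/GFR_ref(%.3g) = %.4g L/h\n",
              drug$renal_plasma_clearance_L_h, physiology$GFR,
              cs$GFR_reference, cs$renal_plasma_clearance))
  cat(sprintf("renal blood CL  = %.4g / B:P = %.4g L/h\n",
              cs$renal_plasma_clearance,
              cs$renal_plasma_clearance / drug$blood_to_plasma_ratio))
  invisible(cs)
}
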