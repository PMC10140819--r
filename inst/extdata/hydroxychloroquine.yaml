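# Hydroxychloroquine drug parameter file.  Physicochemical and ADME inputs
# are the literature values used throughout the package; clearance and
# formulation blocks configure the well-stirred back-calculation and the
# Lint80 release model.
name: hydroxychloroquine
molecular_weight_g_mol: 335.87
logP: 2.4                       # octanol-water, optimized literature value
pKa: [8.27, 9.67]               # diprotic base
pka_type: diprotic_base
fu_plasma: 0.48
blood_to_plasma_ratio: 7.2      # at reference hematocrit 0.45
binding_partner: AGP            # alpha-1 acid glycoprotein
solubility_mg_ml: 5.0           # sulfate salt, phosphate buffer
solubility_pH: 7.2
intestinal_permeability_cm_min: 1.06e-05
renal_plasma_clearance_L_h: 12.7
# Healthy whole-blood hepatic clearance used to back-calculate intrinsic
# clearance: reported total blood clearance ~5.76 L/h (96 mL/min) minus
# renal blood clearance 12.7/7.2 = 1.76 L/h.
hepatic_blood_clearance_L_h: 4.0
clearance:
  eq_form: as_printed           # or standard_well_stirred
  # percentage contributions of the metabolising CYPs and whole-liver
  # abundances (pmol; per-mg-microsomal-protein abundances 137/24/8
  # pmol/mg for 3A4/2C8/2D6 x 40 mg MSP/g liver x 1800 g liver).
  # Editable defaults; contributions chosen consistent with the relative
  # per-pmol in vitro clearances reported for this drug.
  enzyme_contributions: {CYP3A4: 0.41, CYP2C8: 0.28, CYP2D6: 0.31}
  enzyme_abundance_pmol: {CYP3A4: 9864000, CYP2C8: 1728000, CYP2D6: 576000}
formulation:
  release_model: lint80
  dissolution_time_min: 300
  lag_time_min: 60
  release_cap: 1.0              # set 0.8 to truncate release at 80 %
absorption:
  # First-order absorption of dissolved lumen drug into the portal vein:
  # ka = Peff * (surface/volume).  The effective surface-to-volume ratio
  # of the absorbing small intestine (villous + microvillous folding on a
  # ~1.25 cm radius tube) gives ka ~ 1/h for the fitted Peff.
  surface_to_volume_per_cm: 1600
partition_method: rodgers_rowland
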