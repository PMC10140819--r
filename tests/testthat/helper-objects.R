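# Shared fixtures, built in code.

ref_adult <- function(sex = "F", age = 22.6, weight = 63.5) {
  build_reference_adult(sex, age, weight)
}

hcq_drug <- function() load_drug_parameters()

# drug with clearance switched off (distribution-only simulations)
inert_drug <- function() {
  d <- hcq_drug()
  d$hepatic_blood_clearance_L_h <- 0
  d$renal_plasma_clearance_L_h <- 0
  d
}

# a neutral, water-like mock compound
neutral_drug <- function(logP = 0) {
  d <- hcq_drug()
  d$logP <- logP
  d$pKa <- NULL
  d$fu_plasma <- 1
  d$blood_to_plasma_ratio <- 1
  d
}

# hand-built partition/clearance sets for engine reduction tests
flat_partitions <- function(kp = 1, fu = 1, bp = 1) {
  organs <- c("lung", "liver", "kidney", "gut", "muscle", "adipose", "skin",
              "bone", "brain", "heart", "spleen", "rest")
  Kp <- setNames(rep(kp, length(organs)), organs)
  structure(list(Kp = Kp, Kpu = Kp / fu, Kb = Kp / bp, fu = fu,
                 fu_blood = min(fu / bp, 1), bp_ratio = bp, KaAP = 0),
            class = "partition_set")
}

manual_clearances <- function(clint = 0, clr_plasma = 0) {
  structure(list(CLint_total = clint,
                 per_enzyme_invitro = c(CYP3A4 = 0),
                 renal_plasma_clearance = clr_plasma,
                 fuB_reference = 1, QH = 80, CLH = 0,
                 form = "standard_well_stirred", GFR_reference = 90),
            class = "clearance_set")
}

iv_regimen <- function(dose = 155, times = seq(0, 72, 0.25), inf_min = 30) {
  dosing_regimen("iv_infusion", dose, infusion_duration = inf_min, times = times)
}

oral_regimen <- function(dose = 155, times = seq(0, 72, 0.25), cap = 1) {
  dosing_regimen("oral", dose, release_cap = cap, times = times)
}
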