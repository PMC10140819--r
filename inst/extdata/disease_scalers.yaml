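# Disease-stage physiology scalers applied on top of a healthy virtual
# individual.  Multipliers act on the healthy value; overrides replace it.
#
# Liver cirrhosis (Child-Pugh A/B/C): functional liver volume, hepatic
# CYP activity, splanchnic (hepatic arterial + portal) and renal blood
# flow, GFR, hematocrit and plasma-binding-protein (alpha-1 acid
# glycoprotein) reductions follow the severity-graded impairment
# physiologies of Johnson et al. (2010, Clin Pharmacokinet 49:189-206)
# and Edginton & Willmann (2008, Clin Pharmacokinet 47:743-752),
# rounded to two digits.
#
# CKD (moderate/severe): GFR is overridden with the stage values
# 45 and 20 mL/min/1.73 m^2; gastric emptying and small-intestinal
# transit slow and hematocrit falls with severity, per the renal-failure
# physiology summaries of Rowland Yeo et al. (2011) and Malik et al.
# (2020).  Alpha-1 acid glycoprotein is left unchanged: no quantitative
# change is reported for this binding partner in renal failure.
healthy:
  multipliers: {}
  overrides: {}
CP-A:
  multipliers:
    liver_volume: 0.69
    cyp_activity: 0.64
    splanchnic_flow: 0.75
    renal_flow: 0.88
    GFR: 0.88
    hematocrit: 0.92
    binding_protein: 0.88
  overrides: {}
CP-B:
  multipliers:
    liver_volume: 0.55
    cyp_activity: 0.40
    splanchnic_flow: 0.60
    renal_flow: 0.70
    GFR: 0.70
    hematocrit: 0.85
    binding_protein: 0.75
  overrides: {}
CP-C:
  multipliers:
    liver_volume: 0.28
    cyp_activity: 0.24
    splanchnic_flow: 0.45
    renal_flow: 0.55
    GFR: 0.36
    hematocrit: 0.78
    binding_protein: 0.60
  overrides: {}
CKD-moderate:
  multipliers:
    hematocrit: 0.90
    gastric_emptying_time: 1.30
    small_intestinal_transit_time: 1.20
  overrides:
    GFR: 45
CKD-severe:
  multipliers:
    hematocrit: 0.80
    gastric_emptying_time: 1.80
    small_intestinal_transit_time: 1.40
  overrides:
    GFR: 20
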