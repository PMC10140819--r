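# Reference adult physiology (ICRP-89-style reference male/female).
# Organ volumes are expressed as fractions of body weight (density ~1 kg/L),
# organ blood flows as fractions of cardiac output.  Values are rounded
# composites of the ICRP Publication 89 reference anatomical data and the
# regional blood-flow tables of Williams & Leggett (1989); they are the
# package's single documented reference table, linearly rescaled to the
# requested body weight (allometric exponent 1 by default).
# "rest" lumps the remaining perfused soft tissue; non-perfused mass
# (mineral bone, GI contents) carries the residual body weight.
reference:
  F:
    body_weight_kg: 60
    cardiac_output_L_h: 330
    hematocrit: 0.40
    GFR_ml_min_1.73m2: 90
  M:
    body_weight_kg: 73
    cardiac_output_L_h: 360
    hematocrit: 0.45
    GFR_ml_min_1.73m2: 90
# fraction of body weight
organ_volume_fractions:
  lung: 0.0076
  liver: 0.024
  kidney: 0.0044
  gut: 0.017
  muscle: 0.30
  adipose: 0.25
  skin: 0.045
  bone: 0.080
  brain: 0.020
  heart: 0.005
  spleen: 0.0026
  rest: 0.10
  arterial_blood: 0.023
  venous_blood: 0.046
# fraction of cardiac output; liver is the hepatic-arterial fraction only,
# portal inflow arrives through gut + spleen.  Fractions sum to 1.
organ_flow_fractions:
  liver: 0.065
  kidney: 0.190
  gut: 0.150
  muscle: 0.170
  adipose: 0.050
  skin: 0.050
  bone: 0.050
  brain: 0.120
  heart: 0.040
  spleen: 0.020
  rest: 0.095
gastric_emptying_time_min: 30
small_intestinal_transit_time_min: 199
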