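# Tissue-composition table for the Rodgers-Rowland partition-coefficient
# scheme (moderate-to-strong bases): fractional extracellular water (f_ew),
# intracellular water (f_iw), neutral lipid (f_nl), neutral phospholipid
# (f_np), and acidic phospholipid concentration AP (mg/g tissue).
# Values follow the published human/rat composite tables of
# Rodgers, Leahy & Rowland (2005) and Rodgers & Rowland (2006); "rest"
# reuses the muscle entry.  Intracellular pH 7.0 for tissue cells and 7.22
# for erythrocytes; plasma pH 7.4.
pH:
  plasma: 7.4
  intracellular: 7.0
  blood_cells: 7.22
tissues:
  adipose:  {f_ew: 0.135, f_iw: 0.017, f_nl: 0.853,  f_np: 0.0016, ap_mg_g: 0.40}
  bone:     {f_ew: 0.100, f_iw: 0.346, f_nl: 0.017,  f_np: 0.0017, ap_mg_g: 0.67}
  brain:    {f_ew: 0.162, f_iw: 0.620, f_nl: 0.039,  f_np: 0.0015, ap_mg_g: 0.40}
  gut:      {f_ew: 0.282, f_iw: 0.475, f_nl: 0.038,  f_np: 0.0125, ap_mg_g: 2.41}
  heart:    {f_ew: 0.320, f_iw: 0.456, f_nl: 0.014,  f_np: 0.0111, ap_mg_g: 2.25}
  kidney:   {f_ew: 0.273, f_iw: 0.483, f_nl: 0.012,  f_np: 0.0240, ap_mg_g: 5.03}
  liver:    {f_ew: 0.161, f_iw: 0.573, f_nl: 0.014,  f_np: 0.0240, ap_mg_g: 4.56}
  lung:     {f_ew: 0.336, f_iw: 0.446, f_nl: 0.022,  f_np: 0.0128, ap_mg_g: 3.91}
  muscle:   {f_ew: 0.118, f_iw: 0.630, f_nl: 0.010,  f_np: 0.0072, ap_mg_g: 1.53}
  skin:     {f_ew: 0.382, f_iw: 0.291, f_nl: 0.060,  f_np: 0.0044, ap_mg_g: 1.32}
  spleen:   {f_ew: 0.207, f_iw: 0.579, f_nl: 0.0077, f_np: 0.0113, ap_mg_g: 3.18}
  rest:     {f_ew: 0.118, f_iw: 0.630, f_nl: 0.010,  f_np: 0.0072, ap_mg_g: 1.53}
blood_cells: {f_w: 0.603, f_nl: 0.0017, f_np: 0.0029, ap_mg_g: 0.50}
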