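Package: hcqpbpk
Title: Whole-Body PBPK Modelling of Hydroxychloroquine in Healthy and
    Impaired Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A whole-body, perfusion-limited physiologically based
    pharmacokinetic (PBPK) model of hydroxychloroquine after intravenous
    infusion and oral dosing.  The package builds reference adult
    physiologies, samples virtual populations with log-normal parameter
    variability, derives tissue-to-plasma partition coefficients with the
    Rodgers-Rowland tissue-composition scheme, back-calculates hepatic
    intrinsic clearance from a well-stirred liver model and apportions it
    to CYP3A4/2C8/2D6, and integrates the resulting organ mass balances
    with a stiff ODE solver.  Healthy-adult predictions are evaluated by
    non-compartmental analysis (Cmax, AUC, CL), observed-to-predicted
    ratios with a 2-fold acceptance rule, and visual-predictive-check
    envelopes; the healthy model is extrapolated to liver cirrhosis
    (Child-Pugh A/B/C) and chronic kidney disease stages via
    physiology-scaling tables.  A seeded synthetic-data generator emulates
    sparse whole-blood concentration-time studies for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
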