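---
title: "Whole-body PBPK modelling of hydroxychloroquine: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body PBPK modelling of hydroxychloroquine: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcqpbpk)
```

## The problem

Hydroxychloroquine (HCQ) is a diprotic base (pKa 8.27 and 9.67, logP 2.4)
with three features that dominate its kinetics: an enormous distribution
volume from extensive tissue and erythrocyte uptake (whole-blood to plasma
ratio 7.2), a long terminal half-life, and low clearance split between
hepatic CYP metabolism (CYP3A4/2C8/2D6) and renal excretion (renal plasma
clearance 12.7 L/h).  Because no clinical pharmacokinetic data exist in
hepatic or renal impairment, the only way to anticipate exposure in those
patients is a mechanistic model: build a whole-body physiologically based
pharmacokinetic (PBPK) model, qualify it against healthy-adult
intravenous and oral studies, then swap in impaired physiology and
re-simulate.

`hcqpbpk` implements that workflow end to end: reference physiology and
virtual populations, tissue partitioning, clearance back-calculation, a
perfusion-limited whole-body ODE system, non-compartmental analysis (NCA)
with the observed/predicted 2-fold qualification rule, disease-stage
scaling for Child–Pugh (CP) A/B/C cirrhosis and moderate/severe chronic
kidney disease (CKD), and a seeded synthetic-data generator that stands in
for the sparse digitized literature profiles.

## Model structure

Each organ (lung, liver, kidney, gut, muscle, adipose, skin, bone, brain,
heart, spleen, and a lumped "rest") is a well-mixed, perfusion-limited
compartment: the venous outflow concentration is the tissue amount divided
by volume times the tissue:blood partition coefficient.  Arterial blood
feeds all systemic organs; gut and spleen drain through the portal vein
into the liver; the liver drains hepatic artery plus portal flow into
venous blood, which passes through the lung back to arterial.  All mass
balances are linear, so the system is a constant matrix plus
piecewise-constant dosing input, integrated with `deSolve::lsoda` and the
analytic Jacobian (defaults `rtol = 1e-8`, `atol = 1e-10`; the
convergence test halves both and requires AUC changes below 0.01 %).
Dosing discontinuities (infusion end, release lag, release end) are
segment boundaries, never stepped over.

Cellular permeability is taken as non-limiting (perfusion-limited organs
throughout), the simplest model consistent with a long half-life produced
by high partition coefficients, and the drug's solubility (5 mg/mL) is
treated as non-limiting at the simulated doses — dissolution kinetics,
not solubility, rate-limit absorption.

### Partitioning

Tissue:plasma partition coefficients come from the Rodgers–Rowland
tissue-composition scheme for moderate-to-strong bases: extracellular and
intracellular water with Henderson–Hasselbalch ion trapping (intracellular
pH 7.0, plasma 7.4, erythrocyte 7.22), neutral lipid and neutral
phospholipid terms driven by lipophilicity, and an acidic-phospholipid
association term for the ionised base.  The acidic-phospholipid
association constant is not taken from tables: it is calibrated so the
scheme reproduces the drug's *measured* blood:plasma ratio (7.2 at
hematocrit 0.45) through the erythrocyte composition entry.  Each
individual's blood:plasma ratio and whole-blood unbound fraction are then
re-derived from that calibrated constant with the individual's hematocrit
and binding-protein scalar.  Two consequences matter:

* absolute Kp values will differ from proprietary simulator outputs — the
  acceptance surface here is evaluation-layer arithmetic and engine
  properties, not engine-exact replication; and
* for a drug this strongly erythrocyte-bound, whole-blood kinetics are
  nearly insensitive to plasma-binding changes (the unbound fraction
  cancels between tissue and red-cell partitioning), while *anemia
  directly lowers whole-blood concentrations*.  This is what produces the
  counterintuitive small AUC decrease simulated in CKD.

### Clearance

Whole-liver intrinsic clearance is back-calculated from the healthy
hepatic whole-blood clearance (4.0 L/h: reported total blood clearance
~5.76 L/h minus renal blood clearance 12.7/7.2 = 1.76 L/h) with the
well-stirred liver model.  Two algebraic forms are implemented behind a
flag because the printed source formula is ambiguous:

* `as_printed` (default): `CLint = QH·CLH / (fuB·QH − CLH)`
* `standard_well_stirred`: `CLint = QH·CLH / (fuB·(QH − CLH))`

`clearance_explain()` prints both with units.  The back-calculation is
anchored at the reference female adult's hepatic flow: intrinsic
clearance is a drug-level constant, and each individual's hepatic
clearance emerges inside the ODE system from the well-stirred sink
`fuB · CLint · C_liver,out`, which reproduces the forward relation
`CLH = QH·fuB·CLint/(QH + fuB·CLint)` at steady state.  Apportionment to
CYP3A4/2C8/2D6 uses editable contribution fractions (0.41/0.28/0.31) and
PK-Sim-like whole-liver abundances; tests pin only the conservation
property (re-aggregation recovers total CLint to 1e-9), since the
published per-enzyme values cannot be reproduced without the unprinted
contribution and abundance inputs.  Renal plasma clearance scales
proportionally with GFR against a healthy reference of 90 mL/min/1.73 m²
and is converted to a blood clearance via the individual blood:plasma
ratio; elimination is taken from the arterial side of the kidney balance.

### Absorption

Oral dosing uses the Lint80 formulation profile: nothing before the lag
(60 min), then linear release reaching 80 % at the dissolution time
(300 min).  Behaviour past 80 % is undocumented in the source; the
default continues the same linear rate to 100 %, with `release_cap = 0.8`
available to truncate — the switch is exposed because it changes oral AUC
by roughly 10–20 %.  Release is additionally delayed by the individual's
gastric emptying time (30 min healthy), which is how CKD's slowed gastric
emptying enters the oral model.  Dissolved drug in a single absorbing
small-intestinal compartment is absorbed into the portal inflow (first
pass through the liver) at `ka = Peff × (surface/volume)`; with the
fitted permeability 1.06e-5 cm/min and an effective surface-to-volume
ratio of 1600 cm⁻¹ (villous and microvillous folding on a ~1.25 cm radius
tube) this gives ka ≈ 1.0 h⁻¹, and first-order transit loss at
1/SITT (SITT 199 min healthy) caps the absorbed fraction near 0.77.  A
single absorbing segment is used because one fitted permeability cannot
identify a multi-segment model.

## Physiology and populations

The reference adult is an ICRP-style composite (female 60 kg, cardiac
output 330 L/h, hematocrit 0.40; male 73 kg, 360 L/h, 0.45; GFR 90
mL/min/1.73 m² both), shipped as a YAML table of organ volume fractions
of body weight and flow fractions of cardiac output that sum to one.
Volumes and flows scale linearly with body weight (configurable
exponent); hepatic inflow is hepatic-arterial plus gut and spleen flow,
and flow balance against cardiac output is enforced to 1e-6 after every
construction or scaling step.

Virtual populations perturb volumes, flows, hematocrit, GFR and body
weight with independent mean-one log-normal multipliers.  Defaults: CV
0.2 for volumes/flows and GFR, 0.05 for hematocrit, 0.1 for weight
(consistent with the ±10 % weight ranges of the source cohorts); the
female fraction is 0.6 and demographics 19–27 y / 55–68 kg, matching the
development cohorts.  The source reports no variability model, so these
are the package's own choices, fixed once.  All sampling is seeded;
identical specs are bit-identical, and multi-stage runs derive per-stage
sub-seeds from one root seed.

## Disease extrapolation

Stage scalers live in an editable YAML table with per-value provenance
comments.  Cirrhosis (CP-A/B/C) scales functional liver volume
(0.69/0.55/0.28), per-liver CYP activity (0.64/0.40/0.24, compounded with
the volume loss into whole-liver metabolic capacity), splanchnic and
renal flows, GFR, hematocrit, and the α-1 acid glycoprotein
binding-protein scalar (0.88/0.75/0.60), following the severity-graded
impairment physiologies of Johnson et al. (2010) and Edginton & Willmann
(2008).  The unbound plasma fraction rises as `fu / scalar` (capped at
1), the stated binding partner being an acute-phase protein depressed in
cirrhosis.  CKD overrides GFR with the stage values 45 and 20
mL/min/1.73 m², slows gastric emptying and intestinal transit, and lowers
hematocrit (0.90/0.80); the binding protein is left unchanged because no
quantitative change is reported for α-1 acid glycoprotein in renal
failure.  Tests pin directionality (monotone severity), not magnitudes.

With these defaults the simulated 155 mg single-dose AUC0–72h rises
monotonically across cirrhosis severity for both routes (metabolic
capacity loss dominates), and changes only a few percent in CKD — mostly
*downward*, because the anemia term outweighs the lost renal clearance
over a 72 h window in which only a modest fraction of this
slowly-cleared drug is eliminated.  The CKD-severe IV change sits near
−10 % of the healthy median, so it straddles a ±10 % band across
sampling seeds.

## Evaluation

NCA uses the linear trapezoid on the sampled grid, a log-linear terminal
fit on the last k ≥ 3 positive samples, `AUC0-inf = AUC0-t +
Clast/λz`, and `CL = Dose/AUC0-inf` — the Dose/AUC0-t alternative is
inconsistent with the observed clearance column of the shipped
evaluation table.  Ratios are observed/predicted, displayed with
commercial (half-up) rounding at 2 d.p.; the qualification rule is the
inclusive 2-fold band [0.5, 2].  The shipped 36-cell evaluation table
mixes rounding and truncation in its printed ratio column, so exact-match
tests use only the 13 rounding-robust cells and allow ±0.01 elsewhere;
two week-4 oral clearance cells print 0.50 while their own columns give
0.39/0.40, and the tests pin the column arithmetic for those.  VPC
envelopes report pointwise mean, min, max and type-7
(linear-interpolation) 5th/95th percentiles.  Population summaries give
the median AUC0-t with a seeded percentile-bootstrap 95 % CI of the
median (1000 resamples) — the source names no CI method, so this choice
is documented rather than inferred.

## Synthetic data

No digitized concentration points are shipped; `make_fixture_registry()`
describes the eight study entries (3 IV with 30-min infusions at 155/310
mg base, 5 oral at 155/310 mg base or 200 mg sulfate = 155 mg base), and
`generate_pseudo_observed()` simulates each with log-normally perturbed
drug parameters (CV 0.2 on hepatic clearance, renal clearance and
permeability, hepatic clearance clamped below the unbound-flow
admissibility bound), samples the fixture's sparse grid (dense to 2 h,
sparse to 72/120 h; the real grids are unpublished), and applies
mean-unbiased proportional (CV 0.15) plus optional additive noise,
flooring at zero.  The generator returns the clean profile and its NCA as
ground truth, so recovery tests can ask whether noisy sparse NCA stays
within 2-fold of truth.  The development/verification split (1 IV + 2
oral vs 2 IV + 3 oral) is by registry order, since the source does not
identify which studies formed the development third.  What passing these
tests shows is pipeline self-consistency under known noise — not fidelity
to the real 1988–2012 measurements, whose repeated-dose week-4 arms and
digitization error are outside the generator's scope (each fixture is a
single-dose profile).

## Problem sizes and numerical choices

The default evaluation grid is 0–72 h at 0.25 h steps (0.1 h changes AUC
by far less than the solver tolerance); long-horizon checks use 0–1000 h
or 0–1500 h with coarse output.  The disease analysis simulates 100
virtual adults per stage across six stages and two routes; the
synthetic-recovery analysis uses 200 seeded replicates; the
bootstrap-coverage check uses 200 replications of a 10,000-draw sample.
Degenerate inputs are rejected with named-field errors (non-positive
volumes/flows, hematocrit outside (0,1), hepatic clearance at or above
the unbound flow capacity, renal blood clearance above renal flow,
non-monotone time grids), and profiles without a terminal decline are
flagged rather than extrapolated.

## Known limitations

* Single-dose regimens only; the week-4 arms of the oral reference data
  reflect repeated dosing the model does not attempt.
* Perfusion-limited tissues throughout: no lysosomal trapping or
  permeability-limited deep compartments, so the simulated terminal
  half-life is shorter than the 40–50 day literature value even though
  72 h exposure metrics are in range.
* No enterohepatic recirculation, metabolite kinetics, enzyme ontogeny
  or polymorphism, and no pediatric/pregnant physiologies.
* Disease scalers are literature composites with directionality, not
  patient-level calibration; predictions in impairment are unverifiable
  against clinical data, which do not exist.
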