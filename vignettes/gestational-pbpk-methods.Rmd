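---
title: "Methods: a minimal gestational PBPK model for sertraline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a minimal gestational PBPK model for sertraline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sertpbpk)
```

## The problem

Pregnancy changes nearly everything that determines a drug's plasma
concentration: body weight and fat mass rise, plasma volume expands, cardiac
output increases, serum albumin falls (loosening protein binding), and the
activity of several hepatic CYP enzymes is induced. For a drug such as
sertraline — an SSRI commonly continued through pregnancy, ~98.5% protein
bound, cleared essentially entirely by hepatic CYP metabolism, with
negligible renal clearance and linear kinetics — these changes compound into
a substantial loss of exposure at an unchanged dose. This package implements
a minimal physiologically based pharmacokinetic (PBPK) model that predicts
maternal sertraline plasma concentration-time profiles as a function of
gestational age (GA, weeks), quantifies population variability around them,
and solves for the dose that restores nonpregnant steady-state exposure.

## Model structure

The structural model has five perfusion-limited tissue compartments —
plasma, gut, liver, and the rest of the body lumped into richly and slowly
perfused tissues — plus a gut lumen (oral depot) and a gallbladder/bile
compartment. Each tissue `i` with volume `V_i`, blood flow `Q_i` and
tissue:plasma partition coefficient `Kp_i` exchanges drug with plasma at the
perfusion-limited rate `Q_i (C_plasma - C_i/Kp_i)`. The liver receives the
gut venous outflow plus its own arterial supply. Hepatic elimination is
driven by the unbound liver venous concentration (venous-equilibrium
convention):

    rate_met  = CLint * fu * C_liver / Kp_liver
    rate_bile = CL_bile * fu * C_liver / Kp_liver

with biliary drug collected in the gallbladder and returned to the gut
lumen by continuous first-order emptying (`k_empty`). The blood:plasma
concentration ratio is taken as 1 (not measured for this compound; flows
are then interchangeable between blood and plasma reference). Renal
clearance is fixed at zero.

Two non-structural choices deserve justification because the underlying
processes are only characterized qualitatively:

* **Time-dependent absorption.** Sertraline is a low-solubility compound;
  dissolution delays absorption well beyond a first-order depot. We use
  `Ka(t) = ka_max (1 - exp(-t/tau_a))` with the clock reset at every dose.
  The form is monotone, two-parameter, preserves linearity in dose, and
  reproduces a late peak (model Tmax 5 h at steady state) without
  introducing lag-time discontinuities.
* **Enterohepatic recirculation (EHC).** A gallbladder compartment with
  *continuous* first-order emptying was chosen over meal-triggered pulsatile
  emptying: it keeps the system linear and time-invariant between doses,
  which in turn preserves superposition and dose-proportionality — both
  properties the model is required (and tested) to have. What is lost is
  the distinct post-prandial secondary peak; for once-daily steady-state
  profiles this is a second-order feature.

An important structural consequence: with all elimination hepatic and
absorption eventually complete (nothing leaves the lumen except into the
gut wall), the apparent oral clearance is exactly `CL/F = fu * CLint`,
independent of flows, volumes and partition coefficients. Exposure changes
in pregnancy therefore follow binding and metabolism; volumes and flows
shape Cmax, Tmax and half-life.

## Parameterization

**Hepatic clearance by IVIVE.** Per-CYP recombinant-enzyme intrinsic
clearance is `(Vmax/S)/fu_mic` (substrate concentration 0.5 µM; `fu_mic`
taken as 1), scaled by an inter-system extrapolation factor, hepatic enzyme
abundance (pmol/mg microsomal protein), MPPGL (40 mg/g) and liver mass
(1400 g), and summed over CYP3A4, CYP2B6, CYP2C9, CYP2C19 and CYP2D6. The
packaged kinetic table is a synthetic reconstruction (the original in vitro
report is not redistributable); its constants were fixed once so the chain
yields the nonpregnant contribution shares 73/9/8/7/3% — the quantity the
downstream gestational scaling actually consumes. One absolute scalar
(6.333) calibrates total CLint to the nonpregnant plasma profile; shares are
never touched by calibration.

**Distribution.** Tissue:plasma partition coefficients come from the
tissue-composition method for highly lipophilic compounds,
`Kp = [P(Vnl + 0.3 Vph) + (Vw + 0.7 Vph)]_tissue / [...]_plasma * fu_p/fu_t`
with `P = 10^logP`, adipose treated as binding-protein-free and other
tissues assigned half-plasma binding-protein content. Ionization is ignored
(logP, not logD): sertraline is a base with pKa well above plasma pH, so the
neutral-fraction correction would be a single factor common to all tissues,
and it is absorbed by the calibrated adjustment factors. Lumped-compartment
Kp values are volume-weighted means over conventional members (richly:
brain, heart, kidney; slowly: muscle, skin, adipose, bone). Per-compartment
adjustment factors (1.52 gut/liver, 9.24 richly, 4.20 slowly) were fitted
once against the nonpregnant steady-state profile and frozen; they are
large because composition-based Kp underestimates the very large
distribution volume of this lysosomotropic base, a mechanism outside the
model's scope.

**Calibration targets.** The frozen absorption (`ka_max` 0.201/h, `tau_a`
1.71 h), EHC (`CL_bile` 400 L/h unbound, `k_empty` 0.35/h), clearance
scalar and Kp adjustments jointly reproduce the nonpregnant steady-state
profile of 200 mg daily for 30 days: AUC24 3092 µg·h/L, Cmax 159 µg/L,
Tmax 5.0 h, terminal half-life 26.2 h.

## Gestational scaling

Each pregnancy-dependent quantity is a smooth function of GA that equals
its nonpregnant reference at GA 0 and is non-decreasing through term:

| quantity | form | behaviour at term (GA 40) |
|---|---|---|
| body-weight gain | quadratic | +12.5 kg |
| plasma volume | quadratic ratio | +45% |
| cardiac output | quadratic ratio (vertex at 40) | +38% |
| placental-fetal volume | quadratic | 4.8 L |
| serum albumin | quadratic ratio | −27% |
| CYP3A4 activity | saturating sigmoid | ×2.04 |
| CYP2D6 activity | linear | ×1.8 |

Gained mass is routed by mechanism: the lumped placental-fetal volume joins
the richly perfused compartment, plasma expansion stays in plasma, and the
residual gain (predominantly maternal fat) joins the slowly perfused
compartment. Binding follows albumin:
`fu = fu0 / (fu0 + (1 - fu0) * albumin_ratio)`, i.e. binding capacity
proportional to albumin concentration. Only CYP3A4 and CYP2D6 carry
gestational activity functions; the other three enzymes keep multiplier 1 —
a documented limitation, mitigated by CYP3A4 dominating the metabolic
share.

The CYP3A4 function is a sigmoid rather than a polynomial by necessity,
not taste: the total-clearance trajectory it must reproduce (+11/37/63% at
weeks 10/20/30, consistent with a +143% clearance rise at week 40 once the
binding change is included) is nearly linear over weeks 10–30 but flat near
0 and decelerating after 30. No low-order polynomial through those
points is monotone on [0, 40] — exact cubic/quartic fits dip below 1 near
GA 0 — while a saturating sigmoid (amplitude 1.222, midpoint 21 wk, width
8 wk) satisfies monotonicity, the GA-0 identity, and all trajectory
constraints simultaneously. Saturating induction is also the biologically
plausible shape for a hormone-driven process.

The remaining coefficient choices were made once, from typical values in
the pregnancy-physiology literature (term weight gain ~12.5 kg, plasma
volume ~+45%, albumin falling to ~73% of baseline), and validated against
the aggregate trimester outputs above; they were not tuned afterwards.

## Population simulation and sensitivity

Monte Carlo variability assigns each parameter a truncated distribution:
lognormal for drug-specific parameters (partition coefficients CV 20%;
absorption, elimination, binding CV 30%) and for body weight and cardiac
output (CV 30%); normal for fractional tissue volumes and blood flows
(CV 30%). Draws outside the family's own 2.5th/97.5th percentiles are
rejected and redrawn (rejection, not clipping, to preserve the shape of the
interior distribution). Each draw's flow fractions are renormalized to sum
exactly to 1; volume fractions to the baseline total fraction (0.907 of
body weight — the compartments deliberately exclude non-distributing
mass). Gestational *changes* are applied as identical deterministic
increments for every subject: pregnancy-specific variability is not
sampled, and parameter correlations are not modeled. The default
population run uses 1000 iterations; the reported curve statistics are the
pointwise 2.5/50/97.5 percentiles, and the population NCA is computed on
the pointwise-median curve.

Local sensitivity uses the normalized coefficient
`SC = ((MO' - MO)/(IP' - IP)) * (IP/MO)` at a +10% forward step, screening
at a 0.5% output change in steady-state Cmax or AUC24. In the calibrated
model, fraction unbound and intrinsic clearance dominate (SC ≈ −0.9 on
AUC24), followed by absorption rate, body weight, richly perfused
volume/partition and gut/slow flows — while inert identity constants
(molecular weight, pKa) correctly produce SC = 0.

## Numerical choices

* Integration: `lsoda` (stiff-capable, adaptive) with relative tolerance
  1e-8 and absolute tolerance 1e-10 µg, hard restart at every dose event
  (the dose is added to the lumen state and the absorption clock reset);
  the right-hand side is compiled C, with an equivalent R implementation
  kept as a cross-checked reference.
* Output: 0.25 h resolution over the final dosing interval and washout,
  coarser earlier; grids always include chunk endpoints.
* Steady state is operationalized as the 30th daily dose; with a 26 h
  half-life the residual approach-to-steady-state error is below 1e-8.
* NCA: Cmax/Tmax by grid maximum; AUC by linear trapezoid; terminal slope
  by log-linear regression from 12 h after the final Tmax (minimum 5
  points), flagged unreliable below r² = 0.95; `CL/F = dose/AUC_tau`;
  `Vd/F = (CL/F)/lambda_z`.
* Dose rounding: totals composable from at most `max_tablets` tablets
  (default 2) of the available strengths; midpoint ties round *down*, the
  conservative direction for fetal exposure.
* Calibration fitting (`pbpk_fit`): Levenberg-Marquardt on
  log-concentration residuals with log-scale parameters; the
  finite-difference step (`epsfcn = 1e-8`) is set well above the
  integrator tolerance, because machine-precision steps make the numerical
  Jacobian noise-dominated and stall the fit far from the optimum.
* Degenerate inputs: zero dose yields an identically zero profile; zero
  CVs collapse population bands onto the deterministic curve; negative
  gestational age, out-of-range fractions and missing enzymes are rejected
  with errors naming the offending field.

## What the synthetic fixtures do and do not show

`make_calibration_like()` emulates the *structure* of a steady-state
nonpregnant PK study (daily dosing to day 30, serial sampling over the
final interval plus washout, multiplicative lognormal residual error);
`make_verification_like()` emulates a sparse pregnancy study (per-subject
doses, second- and third-trimester visit windows, summary-level Cmax/AUC24,
between-subject body weights). Because both are generated *by the model
itself*, closed-loop tests (parameter recovery, AFE = AAFE = 1 at zero
noise) demonstrate the internal consistency of the estimation and
evaluation machinery — they cannot demonstrate that the model is right
about real pregnant women. Structural misspecification, digitization error,
assay error correlation, adherence, and CYP genotype variation are all
absent from the fixtures by construction.

## Problem sizes

Default analyses use 30-day regimens at 0.25 h output resolution
(~1000 output points), Monte Carlo n = 1000, 20-replicate recovery studies,
and sensitivity screens over ~20 parameters; the full test suite and the
reproduction script run in a few minutes on a single core.

## Known limitations

* CYP2B6/2C9/2C19 gestational activity is not modeled (no equations
  available); clearance rise is carried by CYP3A4 and CYP2D6.
* The fetus is not resolved: the placental-fetal unit is a lumped volume
  inside the richly perfused compartment, so fetal exposure is out of
  scope.
* Absorption is assumed unchanged by pregnancy.
* No ionization/logD correction, no lysosomal trapping mechanism, no
  transporters, no metabolite kinetics (desmethylsertraline is inactive),
  no CYP genetic polymorphism covariates.
* The per-CYP in vitro constants are reconstructed to the contribution
  shares, not transcribed from the primary assay report; analyses that
  depend on absolute (rather than fractional) single-enzyme clearances
  should not rely on them.
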