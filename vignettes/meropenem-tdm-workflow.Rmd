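---
title: "Individualized meropenem dosing: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized meropenem dosing: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(merotdm)
```

## The problem

Critically ill septic patients show extreme between-patient variability in
meropenem clearance — acute kidney injury, renal replacement therapy, and
(in other cohorts) augmented renal clearance can each shift the required
dose several-fold. Because meropenem is a time-dependent beta-lactam, the
efficacy driver is the fraction of time free drug stays above the
pathogen's MIC. Under continuous infusion this reduces to holding the
steady-state concentration in a band: 8–16 mg/L, i.e. 4–8 times the
*Pseudomonas aeruginosa* epidemiological cut-off of 2 mg/L. Concentrations
above 24 mg/L are treated as potentially harmful (neurotoxicity risk
without added benefit), and 16–24 mg/L as moderately high but acceptable
for less-susceptible organisms or deep-seated infections.

`merotdm` codifies the two-stage dosing program used in ICU monitoring
practice: an empiric, renal-function-based dose at therapy start, refined
within 24–48 h by therapeutic drug monitoring (TDM).

## The pharmacokinetic model

All predictions use a linear one-compartment model with zero-order input
and first-order elimination, parameterized by clearance `CL` (L/h) and
volume `V` (L), with `k_e = CL/V`:

* constant-rate infusion from a drug-free state:
  `C(t) = (R0/CL)(1 − e^{−k_e t})`, approaching `Css = R0/CL`;
* steady-state intermittent infusions (duration `Tinf`, interval `tau`):
  the standard multiple-dose closed form with accumulation factor
  `1/(1 − e^{−k_e tau})`; the classified value for intermittent regimens is
  the steady-state **trough**, the binding quantity for 100% fT>MIC;
* arbitrary administration plans by linear superposition
  (`conc_profile()`), e.g. loading dose plus continuous infusion.

Assumptions: meropenem protein binding is negligible (free ≈ total);
elimination is first-order (no saturation); "steady state" for band
classification is the analytic steady state rather than a fixed dose
count. The closed forms are verified in the test suite against independent
numeric integration (`deSolve::lsoda`) of `dC/dt = R(t)/V − k_e C` to a
relative tolerance of 1e-6 over a 100-point clearance × volume grid.

The volume of distribution is not identifiable from steady-state
continuous-infusion data and is fixed at **V = 25 L**, a typical ICU
meropenem value; it is configurable and affects only transients and
intermittent troughs, never `Css`.

## Renal function and clearance prediction

Creatinine clearance comes from Cockcroft–Gault on actual body weight
(no adjusted-weight rule is applied). Degenerate ages ≥ 140 years clamp
the estimate to zero with a warning instead of going negative.

The Dettli method predicts drug clearance as an affine function of renal
function:

```
CL = Q0·CL_normal + (1 − Q0)·CL_normal · CrCL / CrCL_ref
```

Defaults: `CL_normal = 12.5 L/h`, `Q0 = 0.25`, `CrCL_ref = 100 mL/min`.
These population anchors are chosen so the prediction at a septic-cohort
median CrCL of 45.3 mL/min is ≈ 7.4 L/h, consistent with published
software-predicted clearances in comparable populations; all four values
are overridable through `population_pk()` or the JSON config key
`"population_pk"`. On CRRT the renal term is replaced by
`saturation_coefficient × effluent_flow` (defaults 1.0 — meropenem is
freely filtered — and patient-specific flow, ~2 L/h typical). Residual
renal clearance on CRRT is **excluded by default** (the conservative
choice when the dialyzed kidney's contribution is uncertain) and available
via `include_residual_renal = TRUE`. CrCL capping is config-exposed
(`crcl_cap`) for settings without augmented renal clearance.

## Dosing and TDM adjustment

The empiric continuous-infusion dose inverts the steady state to the band
midpoint: `daily dose = 12 mg/L × CL_pred × 24 h`. The setpoint is the
midpoint because it maximizes the margin to both band edges; the band
itself is never a dose-solving target above 16 mg/L. Doses are rounded
half-up to a 100 mg increment (syringe-practical) and clamped to
500–6000 mg/day; increment and bounds are configurable. A fixed 500 mg /
15 min loading dose precedes the infusion regardless of renal function and
is excluded from maintenance daily-dose accounting.

The TDM step estimates clearance from a steady-state level,
`CL_obs = (daily dose/24)/c`, and re-doses proportionally,
`new dose = dose × 12/c`. Two practice rules are codified: a **no-touch
band** (measurements already in 8–16 mg/L leave the dose unchanged), and a
**steady-state lag** (`flag_steady_state()`, default 6 h) excluding
samples drawn too soon after a dose change from clearance estimation. With
noise-free measurements one adjustment step provably centers every
steady state in the band up to rounding slack; this is asserted in the
tests.

The comparison arm uses the German label (SmPC) tiers:
CrCL > 50 → 1000 mg q8h; 26–50 → 1000 mg q12h; 10–25 → 500 mg q12h;
< 10 → 500 mg q24h; CRRT → 1000 mg q12h — as a configuration table
(`smpc_tiers()`), either as 0.5-h boluses or as the same daily dose by
continuous infusion.

## Band conventions and numerical choices

* Band edges are half-open on the left: 2, 8 and 16 mg/L belong to the
  higher band ("8–16" includes 8), while exactly 24.0 mg/L stays in 16–24
  because "harmful" is defined strictly as > 24 mg/L.
* Percentages print with one decimal, rounded half away from zero (base
  R's `round()` is round-half-even, which clinical tables do not use).
* Strategy-predicted troughs at extreme clearances can underflow to 0 in
  double precision; they are floored at 1e-12 mg/L so the classifier (a
  total function on (0, ∞)) still applies.
* Odds ratios with a zero cell use the Haldane–Anscombe +0.5 correction
  and flag the result; a fully zero margin is an error.
* Chi-square tests are uncorrected by default (the convention that
  reproduces published uncorrected p-values from printed 2×2 counts);
  when any expected count falls below 5 the default path switches to
  Fisher's exact test and flags it. The Woolf interval is computed on the
  log scale with `SE = sqrt(1/a + 1/b + 1/c + 1/d)` and is cross-checked
  in the tests against a logistic-regression oracle, whose log-OR standard
  error equals the Woolf SE exactly.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` draws virtual septic-ICU patients with marginals
targeting a typical monitoring-program population: age truncated-normal
(median 73 y, IQR 18, range 18–100), weight and creatinine clearance
log-normal (medians 80 kg and 45.3 mL/min, IQRs 20 and 53.7; parameters
solved from median/IQR), 66% male, 13% CRRT, SOFA 8 (8), SAPS 41 (18).
Three generator choices deserve explanation:

* **CrCL is generated directly and serum creatinine is back-solved**
  through the Cockcroft–Gault identity. Medians of correlated ratios do
  not compose — generating age, weight and creatinine independently at
  their own medians puts the CrCL median near 55 mL/min, not 45.3 — and
  CrCL is the quantity every downstream computation consumes. The price is
  a serum-creatinine marginal median near 1.6 mg/dL rather than 1.3; the
  generated table remains internally consistent, which the tests verify.
* **True clearance** is the Dettli prediction times `exp(eta)`,
  `eta ~ N(0, omega²)`. The default **omega = 0.20** is a calibration:
  it makes the predicted-vs-observed clearance Pearson correlation of a
  default cohort land near 0.88, the value reported for software-predicted
  vs measured meropenem clearance in septic patients. This is a
  calibration, not a validation — the generator has no prediction bias,
  whereas real cohorts show software over-prediction. A consequence is
  that synthetic first-48-h attainment (~85–90%) exceeds the ~60% observed
  in practice; attainment claims in the tests are therefore directional
  (TDM raises attainment, harmful exposure vanishes), never equalities
  against published percentages.
* **Mortality is drawn from SOFA alone** (logistic, odds ratio 1.161 per
  point, intercept solved for 39% mortality at the median SOFA of 8), so
  the generator's ground truth is a null exposure–mortality association —
  matching the finding that concentration bands do not predict death.

Assay noise is proportional, `c = Css × (1 + e)`, `e ~ N(0, cv²)` with
`cv = 0.10` by default (typical HPLC performance), floored away from zero.
Each patient contributes one first-48-h sample and 1–3 post-adjustment
samples (discrete uniform). Not emulated: correlation between severity
scores and renal function, within-patient time-varying clearance, and the
real measurement schedule's informative sampling.

## Problem sizes and determinism

Cohorts of n = 500 (n = 1000 for marginal checks) give stable attainment
fractions and regression slopes while keeping the full suite in seconds;
these sizes are stated in the tests and the acceptance script. Everything
is deterministic given a seed: the generator seeds the cohort draw, the
simulator seeds measurement noise and the sampling schedule, and repeated
runs are asserted identical.

## Known limitations and open points

* The proportional re-dosing rule codifies what is, in practice, expert
  clinical-pharmacological judgement; it is the simplest rule consistent
  with the reported behaviour of such programs (no post-TDM value above
  24 mg/L) but not a transcription of any individual decision.
* Reconstructing the published attainment comparison (60% → 70%) as an
  unpaired two-proportion test on the printed counts gives p ≈ 0.15, not
  the ≤ 0.05 reported; the original test construction (possibly paired
  per patient) is not recoverable from printed counts. The package reports
  the unpaired test and does not attempt to match the published
  significance.
* One printed percentage (standard-bolus 2–8 mg/L band, 62/229) rounds to
  27.1%, not the printed 27.0%; the verification harness reports the 0.1
  discrepancy rather than hiding it.
* A one-compartment model cannot represent distribution-phase kinetics
  after the loading dose; for steady-state banding under continuous
  infusion this is immaterial.
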