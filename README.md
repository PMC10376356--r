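# merotdm

Software- and TDM-guided meropenem dosing for critically ill patients,
as a tested, reproducible R pipeline.

Beta-lactam efficacy in sepsis is driven by the time free drug spends above
the pathogen's MIC (fT > MIC). Under continuous infusion this collapses to a
single number — the steady-state concentration — and a practical target band
of **8–16 mg/L** (4–8 × the *Pseudomonas aeruginosa* ECOFF of 2 mg/L)
balances killing against toxicity. `merotdm` implements the full
individualized-dosing workflow used in ICU monitoring programs:

1. **Renal function** — Cockcroft–Gault creatinine clearance,
   `CrCL = (140 − age)·weight / (72·SCr)` (× 0.85 for women).
2. **Clearance prediction** — the Dettli method: clearance is affine in
   renal function, `CL = Q0·CL_normal + (1 − Q0)·CL_normal·CrCL/CrCL_ref`,
   with an anuric non-renal floor `Q0·CL_normal`; on CRRT the renal term is
   replaced by the extracorporeal clearance
   `saturation coefficient × effluent flow`.
3. **Empiric dosing** — a 500 mg / 15 min loading dose, then a 24-h
   continuous infusion solving `Css = dose/(24·CL)` to the band midpoint
   (12 mg/L), rounded to practical increments.
4. **TDM** — observed clearance from a steady-state level,
   `CL = (daily dose / 24 h) / c`, and proportional re-dosing
   `new dose = dose × setpoint / c` with a no-touch rule inside the band.
5. **Exposure grading** — the five bands <2, 2–8, 8–16, 16–24, >24 mg/L
   (the last defined as potentially harmful), band tallies, and a
   three-strategy comparison (standard intermittent bolus, standard
   continuous infusion, individualized continuous infusion) built on
   closed-form one-compartment kinetics.
6. **Cohort statistics** — 2×2 odds ratios with Woolf confidence intervals,
   chi-square/Fisher tests, two-proportion comparisons.
7. **Synthetic cohorts** — a seeded generator of virtual septic-ICU
   populations (median age 73 y, weight 80 kg, CrCL 45.3 mL/min, 13% CRRT)
   with latent true clearances and proportional assay noise, so the whole
   pipeline is testable end to end without patient data.

Everything is data-frame-first and pipe-friendly; results come back as
tibbles with `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(merotdm)

# empiric dose for a typical patient
pt <- tibble::tibble(patient_id = "icu-01", age = 73, weight_kg = 80,
                     scr_mg_dl = 1.3, sex = "male")
dose_table(pt)
#>   patient_id  crcl cl_pred crrt_branch loading_dose_mg ci_daily_dose_mg
#> 1 icu-01      57.3    8.49 FALSE                   500             2400
```

The Cockcroft–Gault clearance is 57.3 mL/min, the Dettli-predicted meropenem
clearance 8.49 L/h, and the empiric continuous infusion
12 × 8.49 × 24 ≈ 2400 mg/day after a 500 mg load.

```r
# a first-48-h level of 19.8 mg/L under that dose
rec <- tibble::tibble(patient_id = "icu-01", time_h = 30,
                      daily_dose_mg = 2400, conc_mg_l = 19.8)
estimate_clearance(rec)$cl_obs   # 5.05 L/h — the patient clears less than predicted
adjust_daily_dose(2400, 19.8)    # 1500 mg/day, re-centering Css on 12 mg/L

# the published mortality contrast (>24 mg/L vs 8-16 mg/L band)
odds_ratio_woolf(4, 5, 22, 33)
#> Odds ratio 1.200, 95% CI (Woolf) 0.290-4.970

# end-to-end synthetic program
sim <- simulate_tdm_program(generate_cohort(91, seed = 2024), seed = 2025)
glance(sim)
#> therapeutic_pct_first48 = 87.9, therapeutic_pct_post48 = 93.3, ...
autoplot(sim)  # predicted vs observed clearance
```

The simulation shows the program's signature pattern: TDM adjustment raises
the therapeutic fraction (87.9% → 93.3% here) and removes all potentially
harmful (>24 mg/L) exposure.

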