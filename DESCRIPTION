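Package: merotdm
Title: Software- and TDM-Guided Meropenem Dosing for Critically Ill Patients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for individualized meropenem dosing in intensive-care
    patients under continuous infusion: Cockcroft-Gault renal function
    estimation, Dettli-method clearance prediction (including continuous
    renal replacement therapy), empiric dose calculation to a steady-state
    target band, therapeutic-drug-monitoring (TDM) based clearance
    estimation and proportional dose adjustment, one-compartment
    pharmacokinetic predictions for loading, continuous-infusion and
    intermittent regimens, exposure-band classification against the
    8-16 mg/L target, strategy comparison (standard bolus, standard
    continuous infusion, individualized continuous infusion), 2x2
    contingency statistics (Woolf odds-ratio interval, chi-square), and a
    seeded synthetic ICU cohort generator that exercises the whole
    pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
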