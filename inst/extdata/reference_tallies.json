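{
  "description": "Printed exposure-band counts and mortality counts from a published software- and TDM-guided meropenem monitoring program in 91 septic ICU patients (229 concentration measurements). Bands in mg/L. Used by verify_reference_tallies() to recompute percentages and contingency statistics from raw counts.",
  "bands": ["<2", "2-8", "8-16", "16-24", ">24"],
  "phase_tallies": {
    "software_guided_first48": [0, 6, 55, 21, 9],
    "tdm_guided_post48": [0, 13, 96, 29, 0]
  },
  "strategy_tallies": {
    "standard_bolus": [45, 62, 61, 35, 26],
    "standard_ci": [0, 15, 110, 60, 44],
    "individualized_ci": [0, 19, 151, 50, 9]
  },
  "printed_percent": {
    "software_guided_first48": [0.0, 6.6, 60.4, 23.1, 9.9],
    "tdm_guided_post48": [0.0, 9.4, 69.6, 21.0, 0.0],
    "standard_bolus": [19.7, 27.0, 26.6, 15.3, 11.4],
    "standard_ci": [0.0, 6.6, 48.0, 26.2, 19.2],
    "individualized_ci": [0.0, 8.3, 65.9, 21.8, 3.9]
  },
  "mortality": {
    "exposed_band": ">24",
    "reference_band": "8-16",
    "died_exposed": 4,
    "survived_exposed": 5,
    "died_reference": 22,
    "survived_reference": 33,
    "printed_or": 1.2,
    "printed_ci": [0.29, 4.97],
    "printed_p": 0.801
  }
}
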