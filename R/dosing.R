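#' Therapeutic exposure target
#'
#' The target band for meropenem steady-state concentrations under
#' continuous infusion. The default 8-16 mg/L corresponds to four to eight
#' times the Pseudomonas aeruginosa epidemiological cut-off (ECOFF,
#' 2 mg/L), balancing bacterial killing against potentially harmful
#' exposure. Dose solving aims at the band midpoint (setpoint 12 mg/L).
#'
#' @param lower,upper Band edges, mg/L.
#' @param setpoint Concentration the dose is solved for, mg/L; must lie
#'   strictly inside the band.
#' @return A list of class `exposure_target`.
#' @export
exposure_target <- function(lower = 8, upper = 16, setpoint = (lower + upper) / 2) {
  abort_if(
    !(0 < lower && lower < setpoint && setpoint < upper),
    "require 0 < lower < setpoint < upper."
  )
  structure(
    list(lower = lower, upper = upper, setpoint = setpoint),
    class = "exposure_target"
  )
}

#' Empiric daily dose for a target steady-state concentration
#'
#' Inverts the continuous-infusion steady state `Css = dose / (24 * CL)`:
#' `daily dose = setpoint * CL * 24`, rounded to a practical increment and
#' clamped to configurable bounds.
#'
#' @param cl_pred Predicted clearance, L/h (> 0). Vectorized.
#' @param target An [exposure_target()].
#' @param rounding_increment_mg Dose rounding increment, mg (default 100).
#' @param bounds_mg Length-2 daily-dose bounds, mg (default `c(500, 6000)`).
#' @return Daily dose, mg/day.
#' @examples
#' empiric_daily_dose(5) # 12 * 5 * 24 = 1440
#' empiric_daily_dose(7.1, rounding_increment_mg = 250) # 2044.8 -> 2000
#' @export
empiric_daily_dose <- function(cl_pred, target = exposure_target(),
                               rounding_increment_mg = 100,
                               bounds_mg = c(500, 6000)) {
  check_positive(cl_pred, "cl_pred")
  stopifnot(inherits(target, "exposure_target"), length(bounds_mg) == 2)
  dose <- round_to_increment(target$setpoint * cl_pred * 24,
                             rounding_increment_mg)
  pmin(pmax(dose, bounds_mg[1]), bounds_mg[2])
}

#' Empiric continuous-infusion regimen
#'
#' [empiric_daily_dose()] packaged as a 24-h continuous [dose_regimen()].
#'
#' @inheritParams empiric_daily_dose
#' @param start_h Start time, h.
#' @return A `dose_regimen` tibble row.
#' @export
empiric_regimen <- function(cl_pred, target = exposure_target(),
                            rounding_increment_mg = 100,
                            bounds_mg = c(500, 6000), start_h = 0) {
  stopifnot(length(cl_pred) == 1)
  dose_regimen(
    "continuous",
    dose_mg = empiric_daily_dose(cl_pred, target, rounding_increment_mg,
                                 bounds_mg),
    interval_h = 24, start_h = start_h
  )
}

#' Standard loading regimen
#'
#' A fixed loading dose of 500 mg infused over 15 minutes, given at the
#' start of therapy regardless of renal function, immediately followed by
#' the empiric continuous infusion. The loading dose is excluded from
#' maintenance daily-dose accounting.
#'
#' @param start_h Start time, h.
#' @return A `dose_regimen` tibble row (`mode = "loading"`).
#' @export
loading_regimen <- function(start_h = 0) {
  dose_regimen("loading", dose_mg = 500, infusion_duration_h = 0.25,
               interval_h = 24, start_h = start_h)
}

#' Default label-dosing tiers (German SmPC)
#'
#' Renal-impairment tiers of the approved meropenem label used for the
#' standard-dosing comparison arm. Tiers are a configuration table
#' (`smpc_tiers` key of the JSON run configuration) so local labels can be
#' swapped in.
#'
#' @return A tibble with one row per tier, most-impaired last: `crcl_min`
#'   (mL/min), `min_inclusive` (whether the bound is `>=` rather than `>`),
#'   `dose_mg`, `interval_h`, plus one `crrt` row. A patient matches the
#'   first non-CRRT row whose bound holds, so the defaults read:
#'   CrCL > 50 -> 1000 mg q8h; 26-50 -> 1000 mg q12h; 10-25 -> 500 mg q12h;
#'   < 10 -> 500 mg q24h; CRRT -> 1000 mg q12h.
#' @export
smpc_tiers <- function() {
  tibble::tibble(
    crcl_min = c(50, 25, 10, -Inf, NA),
    min_inclusive = c(FALSE, FALSE, TRUE, TRUE, NA),
    crrt = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    dose_mg = c(1000, 1000, 500, 500, 1000),
    interval_h = c(8, 12, 12, 24, 12)
  )
}

#' Standard (label) regimen for a given renal function
#'
#' Looks up the approved-dose tier for the patient's creatinine clearance
#' (or the CRRT tier) and returns it either as a 0.5-h intermittent bolus
#' regimen or as a 24-h continuous infusion carrying the same daily dose.
#'
#' @param crcl Creatinine clearance, mL/min (scalar, >= 0).
#' @param mode `"bolus"` (0.5-h infusions at the label interval) or `"ci"`
#'   (same daily dose as a 24-h continuous infusion).
#' @param on_crrt Use the CRRT tier instead of the CrCL tiers.
#' @param tiers Tier table, see [smpc_tiers()].
#' @return A `dose_regimen` tibble row.
#' @examples
#' smpc_standard_regimen(80, "bolus") # 1000 mg q8h -> 3000 mg/day
#' @export
smpc_standard_regimen <- function(crcl, mode = c("bolus", "ci"),
                                  on_crrt = FALSE, tiers = smpc_tiers()) {
  mode <- match.arg(mode)
  stopifnot(length(crcl) == 1)
  check_non_negative(crcl, "crcl")
  row <- if (isTRUE(on_crrt)) {
    tiers[which(tiers$crrt), , drop = FALSE][1, ]
  } else {
    t2 <- tiers[!tiers$crrt, , drop = FALSE]
    hit <- ifelse(t2$min_inclusive, crcl >= t2$crcl_min, crcl > t2$crcl_min)
    t2[which(hit)[1], ]
  }
  abort_if(nrow(row) == 0 || is.na(row$dose_mg), "no dosing tier matches.")
  daily <- row$dose_mg * 24 / row$interval_h
  if (mode == "bolus") {
    dose_regimen("intermittent", row$dose_mg, infusion_duration_h = 0.5,
                 interval_h = row$interval_h)
  } else {
    dose_regimen("continuous", daily, interval_h = 24)
  }
}

#' Per-patient dose recommendation table
#'
#' Pipeline verb composing the empiric workflow: renal function, predicted
#' clearance, loading dose, and the empiric continuous-infusion daily dose
#' for every patient row.
#'
#' @param patients Patient table, see [add_renal_predictions()].
#' @param pop A [population_pk()] configuration.
#' @param target An [exposure_target()].
#' @param rounding_increment_mg,bounds_mg See [empiric_daily_dose()].
#' @return A tibble with one row per patient: `patient_id` (if present),
#'   `crcl`, `cl_pred`, `crrt_branch` (logical, effluent-based clearance
#'   used), `loading_dose_mg`, `ci_daily_dose_mg`.
#' @export
dose_table <- function(patients, pop = population_pk(),
                       target = exposure_target(),
                       rounding_increment_mg = 100,
                       bounds_mg = c(500, 6000)) {
  abort_if(
    !is.data.frame(patients) || nrow(patients) == 0,
    "`patients` must be a non-empty data frame."
  )
  out <- add_renal_predictions(patients, pop)
  keep <- intersect(c("patient_id"), names(out))
  dplyr::bind_cols(
    out[keep],
    tibble::tibble(
      crcl = out$crcl,
      cl_pred = out$cl_pred,
      crrt_branch = out$on_crrt,
      loading_dose_mg = loading_regimen()$dose_mg,
      ci_daily_dose_mg = empiric_daily_dose(
        out$cl_pred, target, rounding_increment_mg, bounds_mg
      )
    )
  )
}
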