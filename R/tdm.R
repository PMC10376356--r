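#' Observed clearance from a steady-state concentration under CI
#'
#' At continuous-infusion steady state the measured concentration and the
#' infusion rate determine the clearance:
#' `CL = (daily dose / 24 h) / c`,
#' with `c` the measured meropenem concentration (mg/L). The sample is
#' assumed to be drawn at steady state; samples taken shortly after a dose
#' change should be excluded (see [flag_steady_state()]).
#'
#' @param daily_dose_mg Daily dose in effect at sampling, mg/day (> 0).
#' @param conc_mg_l Measured concentration, mg/L (> 0).
#' @return Observed clearance, L/h. Vectorized.
#' @examples
#' observed_clearance(2400, 10) # 100 mg/h / 10 mg/L = 10 L/h
#' @export
observed_clearance <- function(daily_dose_mg, conc_mg_l) {
  check_positive(daily_dose_mg, "daily_dose_mg")
  if (any(!is.finite(conc_mg_l)) || any(conc_mg_l <= 0)) {
    rlang::abort(
      "`conc_mg_l` must be > 0: clearance estimation divides by the measured concentration."
    )
  }
  (daily_dose_mg / 24) / conc_mg_l
}

#' Flag measurements as steady-state or not
#'
#' Samples drawn within `lag_h` hours of the most recent dose change do not
#' satisfy the steady-state assumption of [observed_clearance()] and are
#' flagged for exclusion.
#'
#' @param time_since_dose_change_h Hours since the last dose change.
#' @param lag_h Equilibration lag, h (default 6).
#' @return Logical vector: `TRUE` where the steady-state assumption holds.
#' @export
flag_steady_state <- function(time_since_dose_change_h, lag_h = 6) {
  check_non_negative(time_since_dose_change_h, "time_since_dose_change_h")
  time_since_dose_change_h >= lag_h
}

#' TDM-guided proportional dose adjustment
#'
#' Codifies the monitoring step of the program as proportional re-dosing:
#' if the measured concentration is already inside the target band the dose
#' is left untouched (the "no-touch" rule, configurable); otherwise the new
#' daily dose solves the steady state to the setpoint given the observed
#' clearance,
#' `new dose = current dose * setpoint / c  (= setpoint * CL_obs * 24)`,
#' rounded to the increment and clamped to the bounds.
#'
#' @param current_daily_dose_mg Daily dose in effect at sampling, mg/day.
#' @param conc_mg_l Measured concentration, mg/L (> 0). Vectorized with the
#'   dose.
#' @param target An [exposure_target()].
#' @param rounding_increment_mg,bounds_mg See [empiric_daily_dose()].
#' @param no_touch Keep the dose unchanged when the measurement is inside
#'   `[lower, upper]` (default `TRUE`).
#' @return Adjusted daily dose, mg/day.
#' @examples
#' adjust_daily_dose(2400, 24) # halved: 1200
#' adjust_daily_dose(1500, 6) # doubled: 3000
#' adjust_daily_dose(2400, 12) # in band at the setpoint: unchanged
#' @export
adjust_daily_dose <- function(current_daily_dose_mg, conc_mg_l,
                              target = exposure_target(),
                              rounding_increment_mg = 100,
                              bounds_mg = c(500, 6000),
                              no_touch = TRUE) {
  check_positive(current_daily_dose_mg, "current_daily_dose_mg")
  stopifnot(inherits(target, "exposure_target"))
  cl_obs <- observed_clearance(current_daily_dose_mg, conc_mg_l)
  new_dose <- empiric_daily_dose(cl_obs, target, rounding_increment_mg,
                                 bounds_mg)
  in_band <- conc_mg_l >= target$lower & conc_mg_l <= target$upper
  if (isTRUE(no_touch)) ifelse(in_band, current_daily_dose_mg, new_dose)
  else new_dose
}

#' Estimate clearance for a measurement table
#'
#' Pipeline verb: adds `cl_obs` (L/h) to a concentration-measurement table
#' and derives the observation `phase` (`"first48"` for samples at
#' `time_h <= 48`, `"post48"` after) when absent.
#'
#' @param measurements Data frame with columns `daily_dose_mg`,
#'   `conc_mg_l`, and `time_h`.
#' @return The input as a tibble with `cl_obs` and `phase` columns.
#' @export
estimate_clearance <- function(measurements) {
  stopifnot(is.data.frame(measurements))
  out <- tibble::as_tibble(measurements)
  out <- dplyr::mutate(
    out,
    cl_obs = observed_clearance(.data$daily_dose_mg, .data$conc_mg_l)
  )
  if (!"phase" %in% names(out)) {
    out <- dplyr::mutate(
      out,
      phase = ifelse(.data$time_h <= 48, "first48", "post48")
    )
  }
  out
}
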