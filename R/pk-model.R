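#' One-compartment pharmacokinetic parameters
#'
#' Constructs the parameter set of the linear one-compartment model used
#' throughout the package: total drug clearance `CL` (L/h) and apparent
#' volume of distribution `V` (L). The elimination rate constant is derived
#' as `k_e = CL / V` (1/h). Meropenem has negligible protein binding, so
#' total and free concentrations are treated as equal.
#'
#' The default volume of 25 L is a typical ICU meropenem value. Steady-state
#' concentrations under continuous infusion do not depend on `V`; it only
#' shapes transients and intermittent-infusion troughs.
#'
#' @param clearance Total drug clearance, L/h. Must be > 0.
#' @param volume Volume of distribution, L. Must be > 0.
#' @return An object of class `pk_parameters`: a list with elements
#'   `clearance`, `volume` and `k_e`.
#' @examples
#' pk <- pk_parameters(clearance = 7.1, volume = 25)
#' pk$k_e
#' @export
pk_parameters <- function(clearance, volume = 25) {
  check_positive(clearance, "clearance")
  check_positive(volume, "volume")
  structure(
    list(clearance = clearance, volume = volume, k_e = clearance / volume),
    class = "pk_parameters"
  )
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf(
    "<pk_parameters> CL = %.3g L/h, V = %.3g L, k_e = %.4g 1/h\n",
    x$clearance, x$volume, x$k_e
  ))
  invisible(x)
}

as_pk <- function(pk) {
  if (inherits(pk, "pk_parameters")) return(pk)
  rlang::abort("`pk` must be a `pk_parameters` object (see `pk_parameters()`).")
}

#' Dose regimen constructor
#'
#' A regimen is one mode of meropenem administration: a short loading
#' infusion, a 24-h continuous infusion (CI), or repeated intermittent
#' infusions. Returned as a one-row tibble so regimens can be stacked with
#' `dplyr::bind_rows()` into an administration plan for [conc_profile()].
#'
#' @param mode One of `"loading"`, `"continuous"`, `"intermittent"`.
#' @param dose_mg Amount per administration, mg (> 0). For `"continuous"`,
#'   the amount infused per interval (i.e. the daily dose when
#'   `interval_h = 24`).
#' @param infusion_duration_h Infusion duration, h. Defaults by mode: 0.25
#'   (loading), 24 (continuous), 0.5 (intermittent).
#' @param interval_h Dosing interval tau, h. Must satisfy
#'   `0 < infusion_duration_h <= interval_h`. A loading dose is a single
#'   administration; its interval is only used for bookkeeping.
#' @param start_h Start time of the first administration, h (default 0).
#' @return A one-row tibble of class `dose_regimen` with columns `mode`,
#'   `dose_mg`, `infusion_duration_h`, `interval_h`, `start_h`, and derived
#'   `daily_dose_mg = dose_mg * 24 / interval_h` (0 for a loading dose,
#'   which is excluded from maintenance daily-dose accounting).
#' @examples
#' dose_regimen("intermittent", 1000, interval_h = 8)
#' @export
dose_regimen <- function(mode = c("continuous", "intermittent", "loading"),
                         dose_mg,
                         infusion_duration_h = NULL,
                         interval_h = 24,
                         start_h = 0) {
  mode <- match.arg(mode)
  if (is.null(infusion_duration_h)) {
    infusion_duration_h <- switch(mode,
      loading = 0.25, continuous = interval_h, intermittent = 0.5
    )
  }
  check_positive(dose_mg, "dose_mg")
  check_positive(infusion_duration_h, "infusion_duration_h")
  check_positive(interval_h, "interval_h")
  abort_if(
    infusion_duration_h > interval_h,
    "`infusion_duration_h` must not exceed `interval_h`."
  )
  daily <- if (mode == "loading") 0 else dose_mg * 24 / interval_h
  out <- tibble::tibble(
    mode = mode,
    dose_mg = dose_mg,
    infusion_duration_h = infusion_duration_h,
    interval_h = interval_h,
    start_h = start_h,
    daily_dose_mg = daily
  )
  class(out) <- c("dose_regimen", class(out))
  out
}

#' Concentration under a constant-rate infusion started from a drug-free state
#'
#' Closed form of the one-compartment model with zero-order input and
#' first-order elimination:
#' `C(t) = (R0 / CL) * (1 - exp(-k_e * t))`,
#' which rises monotonically to the steady state `Css = R0 / CL`.
#'
#' @param rate_mg_h Infusion rate R0, mg/h (>= 0).
#' @param pk A [pk_parameters()] object.
#' @param t_h Time(s) since infusion start, h (>= 0). Vectorized.
#' @return Concentration(s), mg/L.
#' @examples
#' pk <- pk_parameters(5, 25)
#' conc_continuous_infusion(100, pk, t_h = c(0, 5, 100))
#' @export
conc_continuous_infusion <- function(rate_mg_h, pk, t_h) {
  pk <- as_pk(pk)
  check_non_negative(rate_mg_h, "rate_mg_h")
  check_non_negative(t_h, "t_h")
  (rate_mg_h / pk$clearance) * (1 - exp(-pk$k_e * t_h))
}

# concentration after a single infusion (dose over Tinf starting at 0),
# evaluated at any t >= 0; 0 for t < 0
conc_single_infusion <- function(dose_mg, tinf_h, pk, t_h) {
  r0 <- dose_mg / tinf_h
  k <- pk$k_e
  during <- (r0 / pk$clearance) * (1 - exp(-k * pmin(t_h, tinf_h)))
  after <- exp(-k * pmax(t_h - tinf_h, 0))
  ifelse(t_h < 0, 0, during * after)
}

#' Steady-state concentration within an intermittent-infusion interval
#'
#' Standard multiple-infusion closed form for the one-compartment model at
#' steady state. During the infusion (`0 <= t <= Tinf`):
#' `C(t) = (R0/CL) * [(1 - e^{-k t}) + (1 - e^{-k Tinf}) e^{-k (t - Tinf)} e^{-k tau} / (1 - e^{-k tau})]`
#' and after it (`Tinf <= t <= tau`):
#' `C(t) = (R0/CL) * (1 - e^{-k Tinf}) e^{-k (t - Tinf)} / (1 - e^{-k tau})`,
#' where the `1 / (1 - e^{-k tau})` factor is the accumulation factor. The
#' steady-state trough is the value at `t = tau`.
#'
#' @param regimen A [dose_regimen()] row with `mode = "intermittent"` (a
#'   continuous regimen is accepted and returns its constant `Css`).
#' @param pk A [pk_parameters()] object.
#' @param t_h Time(s) within the dosing interval, h, in `[0, interval_h]`.
#' @return Concentration(s), mg/L.
#' @examples
#' reg <- dose_regimen("intermittent", 1000, interval_h = 8)
#' pk <- pk_parameters(7.1, 25)
#' conc_intermittent_ss(reg, pk, t_h = 8) # steady-state trough
#' @export
conc_intermittent_ss <- function(regimen, pk, t_h) {
  pk <- as_pk(pk)
  stopifnot(is.data.frame(regimen), nrow(regimen) == 1)
  tau <- regimen$interval_h
  tinf <- regimen$infusion_duration_h
  abort_if(
    any(t_h < 0 | t_h > tau),
    "`t_h` must lie within the dosing interval [0, interval_h]."
  )
  if (regimen$mode == "continuous" || tinf == tau) {
    # back-to-back infusions are a constant-rate input: flat Css
    return(rep(regimen$dose_mg / (tau * pk$clearance), length(t_h)))
  }
  k <- pk$k_e
  r0 <- regimen$dose_mg / tinf
  acc <- 1 / (1 - exp(-k * tau))
  tail_prev <- (r0 / pk$clearance) * (1 - exp(-k * tinf)) *
    exp(-k * (t_h - tinf)) * exp(-k * tau) * acc
  during <- (r0 / pk$clearance) * (1 - exp(-k * t_h)) + tail_prev
  post <- (r0 / pk$clearance) * (1 - exp(-k * tinf)) * exp(-k * (t_h - tinf)) * acc
  ifelse(t_h <= tinf, during, post)
}

#' Steady-state trough of an intermittent regimen
#'
#' Convenience wrapper: the end-of-interval concentration, the
#' pharmacodynamically binding value for 100% fT>MIC under intermittent
#' dosing.
#'
#' @inheritParams conc_intermittent_ss
#' @return Trough concentration, mg/L.
#' @export
trough_intermittent_ss <- function(regimen, pk) {
  conc_intermittent_ss(regimen, pk, t_h = regimen$interval_h)
}

#' Concentration-time profile under superposed regimens
#'
#' Linear pharmacokinetics make the concentration under several concurrent
#' or sequential regimens the sum of the single-regimen contributions. A
#' `"continuous"` regimen contributes an uninterrupted constant-rate
#' infusion from its `start_h` onward; `"loading"` contributes a single
#' short infusion; `"intermittent"` contributes repeated infusions every
#' `interval_h` from `start_h` onward.
#'
#' @param regimens A tibble of [dose_regimen()] rows (stack with
#'   `dplyr::bind_rows()`); must be non-empty.
#' @param pk A [pk_parameters()] object.
#' @param times_h Sorted evaluation times, h (>= 0).
#' @return A tibble of class `merotdm_profile` with columns `time_h`,
#'   `conc_mg_L`.
#' @examples
#' pk <- pk_parameters(7, 25)
#' plan <- dplyr::bind_rows(
#'   loading_regimen(),
#'   dose_regimen("continuous", 2000, interval_h = 24)
#' )
#' conc_profile(plan, pk, times_h = c(0.25, 6, 48))
#' @export
conc_profile <- function(regimens, pk, times_h) {
  pk <- as_pk(pk)
  abort_if(
    !is.data.frame(regimens) || nrow(regimens) == 0,
    "`regimens` must be a non-empty tibble of dose_regimen rows."
  )
  check_non_negative(times_h, "times_h")
  total <- numeric(length(times_h))
  for (i in seq_len(nrow(regimens))) {
    reg <- regimens[i, ]
    rel <- times_h - reg$start_h
    contrib <- if (reg$mode == "loading") {
      conc_single_infusion(reg$dose_mg, reg$infusion_duration_h, pk, rel)
    } else if (reg$mode == "continuous") {
      ifelse(rel < 0, 0,
        conc_continuous_infusion(reg$daily_dose_mg / 24, pk, pmax(rel, 0))
      )
    } else {
      # repeated infusions: superpose every administration started before t
      v <- numeric(length(rel))
      n_max <- max(0, floor(max(rel) / reg$interval_h))
      for (j in 0:n_max) {
        v <- v + conc_single_infusion(
          reg$dose_mg, reg$infusion_duration_h, pk, rel - j * reg$interval_h
        )
      }
      v
    }
    total <- total + contrib
  }
  out <- tibble::tibble(time_h = times_h, conc_mg_L = total)
  class(out) <- c("merotdm_profile", class(out))
  out
}

#' Steady-state concentration under continuous infusion
#'
#' `Css = daily dose / (24 h * CL)` — independent of the volume of
#' distribution. This is the quantity banded against the 8-16 mg/L target.
#'
#' @param daily_dose_mg Daily dose, mg/day.
#' @param clearance Drug clearance, L/h.
#' @return Css, mg/L. Vectorized.
#' @export
css_continuous <- function(daily_dose_mg, clearance) {
  check_non_negative(daily_dose_mg, "daily_dose_mg")
  check_positive(clearance, "clearance")
  daily_dose_mg / (24 * clearance)
}

#' @rdname conc_profile
#' @param object,x A `merotdm_profile` tibble.
#' @param ... Unused.
#' @method autoplot merotdm_profile
#' @export
autoplot.merotdm_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_h, .data$conc_mg_L)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (h)", y = "Meropenem concentration (mg/L)",
      title = "Predicted concentration-time profile"
    )
}
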