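#' Exposure band labels
#'
#' The five concentration classes used for exposure grading: <2 mg/L
#' (subtherapeutic, below the Pseudomonas ECOFF), 2-8 (below target),
#' 8-16 (therapeutic), 16-24 (moderately high but acceptable for
#' less-susceptible pathogens and deep-seated infections), and >24 mg/L
#' (potentially harmful).
#'
#' @return Character vector of the five band labels, in concentration order.
#' @export
band_levels <- function() {
  c("<2", "2-8", "8-16", "16-24", ">24")
}

#' Classify a concentration into its exposure band
#'
#' Bands are half-open on the left edge — a value equal to 2, 8 or 16 mg/L
#' falls in the higher band ("8-16" includes 8) — while 24.0 mg/L stays in
#' the 16-24 band because "harmful" is defined strictly as >24 mg/L.
#' Together the bands partition (0, Inf).
#'
#' @param conc_mg_l Concentration(s), mg/L (> 0).
#' @return An ordered factor with levels [band_levels()].
#' @examples
#' classify_band(c(1.9, 14.1, 24, 24.0001))
#' @export
classify_band <- function(conc_mg_l) {
  if (any(!is.finite(conc_mg_l)) || any(conc_mg_l <= 0)) {
    rlang::abort("`conc_mg_l` must be finite and > 0 to be classified.")
  }
  lv <- band_levels()
  out <- dplyr::case_when(
    conc_mg_l < 2 ~ lv[1],
    conc_mg_l < 8 ~ lv[2],
    conc_mg_l < 16 ~ lv[3],
    conc_mg_l <= 24 ~ lv[4],
    TRUE ~ lv[5]
  )
  factor(out, levels = lv, ordered = TRUE)
}

#' Tally concentrations by exposure band
#'
#' Counts and relative incidences (percent, one decimal, half-up — the
#' formatting used in clinical exposure tables) per band, optionally per
#' group (e.g. observation phase or dosing strategy).
#'
#' @param x A numeric vector of concentrations (mg/L) or a data frame.
#' @param ... Passed to methods.
#' @return A tibble of class `merotdm_tally` with columns (`group`,)
#'   `band`, `n`, `percent`; every band appears (zero counts included) and
#'   counts sum to the number of values per group.
#' @examples
#' tally_bands(c(1, 5, 12, 20, 30))
#' @export
tally_bands <- function(x, ...) UseMethod("tally_bands")

#' @export
tally_bands.default <- function(x, ...) {
  abort_if(length(x) == 0, "empty input: nothing to tally.")
  band_tally_tbl(tibble::tibble(band = classify_band(x)), group = NULL)
}

#' @rdname tally_bands
#' @param conc Column of `x` holding concentrations (bare name; default
#'   `conc_mg_l`).
#' @param by Optional bare column name to group by.
#' @export
tally_bands.data.frame <- function(x, conc = conc_mg_l, by = NULL, ...) {
  abort_if(nrow(x) == 0, "empty input: nothing to tally.")
  conc <- rlang::enquo(conc)
  by <- rlang::enquo(by)
  d <- tibble::tibble(band = classify_band(dplyr::pull(x, !!conc)))
  if (!rlang::quo_is_null(by)) d$group <- dplyr::pull(x, !!by)
  band_tally_tbl(d, group = if (rlang::quo_is_null(by)) NULL else "group")
}

band_tally_tbl <- function(d, group = NULL) {
  lv <- factor(band_levels(), levels = band_levels(), ordered = TRUE)
  keys <- c(group, "band")
  counted <- dplyr::count(d, dplyr::across(dplyr::all_of(keys)), name = "n")
  if (is.null(group)) {
    out <- tidyr::complete(counted, band = lv, fill = list(n = 0L)) |>
      dplyr::mutate(percent = round_half_up(100 * .data$n / sum(.data$n), 1))
  } else {
    out <- tidyr::complete(counted, group = unique(d$group), band = lv,
                           fill = list(n = 0L)) |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(percent = round_half_up(100 * .data$n / sum(.data$n), 1)) |>
      dplyr::ungroup()
  }
  out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(keys)))
  class(out) <- c("merotdm_tally", class(out))
  out
}

#' Tally from pre-computed band counts
#'
#' Builds a `merotdm_tally` directly from integer counts per band — the
#' entry point of the verification harness that re-derives published table
#' percentages from their printed counts.
#'
#' @param counts Integer vector of length 5, ordered as [band_levels()].
#' @param group Optional single group label.
#' @return A `merotdm_tally` tibble.
#' @examples
#' band_tally_from_counts(c(0, 6, 55, 21, 9))
#' @export
band_tally_from_counts <- function(counts, group = NULL) {
  stopifnot(length(counts) == 5, all(counts >= 0), sum(counts) > 0)
  out <- tibble::tibble(
    band = factor(band_levels(), levels = band_levels(), ordered = TRUE),
    n = as.integer(counts),
    percent = round_half_up(100 * counts / sum(counts), 1)
  )
  if (!is.null(group)) out <- dplyr::bind_cols(tibble::tibble(group = group), out)
  class(out) <- c("merotdm_tally", class(out))
  out
}

#' Compare dosing strategies on a measurement table
#'
#' For each measurement occasion (one observed clearance per row), predicts
#' the concentration that each dosing strategy would have produced and
#' tallies exposure bands:
#' \describe{
#'   \item{standard_bolus}{label-tier dose as 0.5-h intermittent infusions;
#'     classified at the steady-state trough, the binding value for
#'     100% fT>MIC.}
#'   \item{standard_ci}{the same label daily dose as a 24-h continuous
#'     infusion; classified at `Css = daily dose / (24 CL)`.}
#'   \item{individualized_ci}{continuous infusion with the daily dose
#'     solved from the row's clearance to the target setpoint.}
#' }
#'
#' @param measurements Data frame with columns `cl_obs` (L/h), `crcl`
#'   (mL/min) and logical `on_crrt` (assumed `FALSE` when absent). With
#'   `per_patient = TRUE` a `patient_id` column is required and each
#'   patient's rows are collapsed to their mean clearance first.
#' @param strategies Character subset of the three strategy names.
#' @param pop A [population_pk()] (supplies the distribution volume for
#'   trough computation).
#' @param target An [exposure_target()].
#' @param tiers Label tier table, see [smpc_tiers()].
#' @param rounding_increment_mg,bounds_mg Dose rounding for the
#'   individualized arm.
#' @param per_patient Collapse to one clearance per patient before
#'   simulating (default `FALSE`: per measurement, as many occasions as
#'   rows).
#' @return A `merotdm_tally` tibble with a `group` column naming the
#'   strategy.
#' @export
compare_strategies <- function(measurements,
                               strategies = c("standard_bolus", "standard_ci",
                                              "individualized_ci"),
                               pop = population_pk(),
                               target = exposure_target(),
                               tiers = smpc_tiers(),
                               rounding_increment_mg = 100,
                               bounds_mg = c(500, 6000),
                               per_patient = FALSE) {
  known <- c("standard_bolus", "standard_ci", "individualized_ci")
  abort_if(
    !all(strategies %in% known),
    paste("unknown strategy; choose from:", paste(known, collapse = ", "))
  )
  stopifnot(is.data.frame(measurements), nrow(measurements) > 0)
  m <- tibble::as_tibble(measurements)
  if (!"on_crrt" %in% names(m)) m$on_crrt <- FALSE
  if (per_patient) {
    m <- m |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        cl_obs = mean(.data$cl_obs),
        crcl = mean(.data$crcl),
        on_crrt = any(.data$on_crrt),
        .groups = "drop"
      )
  }
  tier <- smpc_lookup(m$crcl, m$on_crrt, tiers)
  preds <- purrr::map(strategies, function(s) {
    conc <- switch(s,
      standard_bolus = trough_ss_vec(
        tier$dose_mg, 0.5, tier$interval_h, m$cl_obs, pop$volume
      ),
      standard_ci = css_continuous(
        tier$dose_mg * 24 / tier$interval_h, m$cl_obs
      ),
      individualized_ci = css_continuous(
        empiric_daily_dose(m$cl_obs, target, rounding_increment_mg, bounds_mg),
        m$cl_obs
      )
    )
    # extreme clearances can underflow a trough to exactly 0; keep the
    # mathematically positive prediction classifiable
    tibble::tibble(strategy = s, conc_mg_l = pmax(conc, 1e-12))
  }) |> purrr::list_rbind()
  tally_bands(preds, conc = conc_mg_l, by = strategy)
}

# vectorized label-tier lookup: per-administration dose and interval
smpc_lookup <- function(crcl, on_crrt, tiers = smpc_tiers()) {
  n <- length(crcl)
  dose <- numeric(n)
  interval <- numeric(n)
  t2 <- tiers[!tiers$crrt, , drop = FALSE]
  crrt_row <- tiers[which(tiers$crrt)[1], , drop = FALSE]
  # rows are ordered most-generous first; later (more impaired) rows must not
  # overwrite an earlier match, so walk bottom-up
  for (i in rev(seq_len(nrow(t2)))) {
    hit <- if (t2$min_inclusive[i]) crcl >= t2$crcl_min[i] else crcl > t2$crcl_min[i]
    dose[hit] <- t2$dose_mg[i]
    interval[hit] <- t2$interval_h[i]
  }
  if (any(on_crrt)) {
    dose[on_crrt] <- crrt_row$dose_mg
    interval[on_crrt] <- crrt_row$interval_h
  }
  tibble::tibble(dose_mg = dose, interval_h = interval)
}

# vectorized steady-state trough of repeated infusions
trough_ss_vec <- function(dose_mg, tinf_h, tau_h, cl, v) {
  k <- cl / v
  r0 <- dose_mg / tinf_h
  (r0 / cl) * (1 - exp(-k * tinf_h)) * exp(-k * (tau_h - tinf_h)) /
    (1 - exp(-k * tau_h))
}

#' @rdname tally_bands
#' @param object A `merotdm_tally`.
#' @method autoplot merotdm_tally
#' @export
autoplot.merotdm_tally <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$band, .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "Meropenem concentration band (mg/L)", y = "Measurements (%)",
      title = "Exposure-band distribution"
    )
  if ("group" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$group))
  }
  p
}
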