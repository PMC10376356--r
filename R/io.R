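#' Read a patient cohort CSV
#'
#' Comma-separated, UTF-8, header row required, `.` decimal separator
#' (clinical exports using `;` must be converted first). Required columns:
#' `patient_id`, `age`, `sex`, `weight_kg`, `scr_mg_dl`; optional:
#' `height_cm`, `on_crrt`, `effluent_flow_l_h`, `sofa`, `saps`,
#' `died_in_hospital`, `crcl`. Out-of-range values are reported with their
#' row numbers.
#'
#' @param path CSV file path.
#' @return A tibble, one row per patient.
#' @export
read_patient_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  abort_if(nrow(df) == 0, sprintf("'%s': empty data section.", path))
  required <- c("patient_id", "age", "sex", "weight_kg", "scr_mg_dl")
  missing <- setdiff(required, names(df))
  abort_if(
    length(missing) > 0,
    sprintf("'%s': missing column(s): %s.", path, paste(missing, collapse = ", "))
  )
  bad <- which(!is.finite(df$age) | df$age < 18 | !is.finite(df$weight_kg) |
    df$weight_kg <= 0 | !is.finite(df$scr_mg_dl) | df$scr_mg_dl <= 0)
  abort_if(
    length(bad) > 0,
    sprintf("'%s': out-of-range age/weight/creatinine at data row(s) %s.",
            path, paste(utils::head(bad, 10), collapse = ", "))
  )
  if (!"on_crrt" %in% names(df)) df$on_crrt <- FALSE
  df$on_crrt <- as.logical(df$on_crrt)
  tibble::as_tibble(df)
}

#' Write a patient cohort CSV
#'
#' Drops generator-internal latent columns (`true_clearance`) so simulated
#' cohorts round-trip as pipeline inputs indistinguishable from real ones.
#' Numeric columns are written with six decimals, which keeps the file
#' byte-stable under write-read-write cycles.
#'
#' @param patients Patient tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_csv <- function(patients, path) {
  out <- patients[setdiff(names(patients), "true_clearance")]
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
                                          \(x) round(x, 6)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a concentration-measurement CSV
#'
#' Required columns: `patient_id`, `time_h`, `daily_dose_mg`, `conc_mg_l`.
#' The observation phase (`first48` / `post48`) is derived from `time_h`,
#' never stored.
#'
#' @param path CSV file path.
#' @return A tibble with `cl_obs` and `phase` added (see
#'   [estimate_clearance()]).
#' @export
read_concentration_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  abort_if(nrow(df) == 0, sprintf("'%s': empty data section.", path))
  required <- c("patient_id", "time_h", "daily_dose_mg", "conc_mg_l")
  missing <- setdiff(required, names(df))
  abort_if(
    length(missing) > 0,
    sprintf("'%s': missing column(s): %s.", path, paste(missing, collapse = ", "))
  )
  bad <- which(!is.finite(df$conc_mg_l) | df$conc_mg_l <= 0 |
                 !is.finite(df$daily_dose_mg) | df$daily_dose_mg <= 0)
  abort_if(
    length(bad) > 0,
    sprintf("'%s': non-positive dose/concentration at data row(s) %s.",
            path, paste(utils::head(bad, 10), collapse = ", "))
  )
  estimate_clearance(df[required])
}

#' Write a band-tally CSV
#'
#' Columns: (`group`,) `band`, `n`, `percent` — the layout of clinical
#' exposure tables.
#'
#' @param tally A `merotdm_tally` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tally_csv <- function(tally, path) {
  readr::write_csv(tally, path, progress = FALSE)
  invisible(path)
}

#' Read and validate a JSON run configuration
#'
#' Recognized keys: `population_pk`, `target`, `rounding_increment_mg`,
#' `dose_bounds_mg`, `smpc_tiers`, `synthetic`, `seed`, `output_dir`,
#' `log_level`. Unknown keys are rejected before any stage runs. Absent
#' keys fall back to package defaults.
#'
#' @param path JSON file path, or `NULL` for the all-defaults
#'   configuration.
#' @return A list of class `run_config` with elements `pop`
#'   ([population_pk()]), `target` ([exposure_target()]),
#'   `rounding_increment_mg`, `dose_bounds_mg`, `tiers`, `synthetic`
#'   ([cohort_config()]), `seed`, `output_dir`, `log_level`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) {
    list()
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("population_pk", "target", "rounding_increment_mg",
             "dose_bounds_mg", "smpc_tiers", "synthetic", "seed",
             "output_dir", "log_level")
  unknown <- setdiff(names(raw), known)
  abort_if(
    length(unknown) > 0,
    sprintf("unknown config key(s): %s.", paste(unknown, collapse = ", "))
  )
  pop <- do.call(population_pk, as.list(raw$population_pk))
  target <- do.call(exposure_target, as.list(raw$target))
  tiers <- if (is.null(raw$smpc_tiers)) {
    smpc_tiers()
  } else {
    tibble::as_tibble(raw$smpc_tiers)
  }
  syn_args <- as.list(raw$synthetic)
  n <- syn_args$n %||% 91
  syn_args$n <- NULL
  synthetic <- do.call(cohort_config, syn_args)
  structure(
    list(
      pop = pop, target = target,
      rounding_increment_mg = raw$rounding_increment_mg %||% 100,
      dose_bounds_mg = raw$dose_bounds_mg %||% c(500, 6000),
      tiers = tiers, synthetic = synthetic, n = n,
      seed = raw$seed %||% 1L,
      output_dir = raw$output_dir %||% ".",
      log_level = raw$log_level %||% "info"
    ),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Verify published exposure tables against their printed counts
#'
#' The package ships the printed band counts and mortality counts of a
#' published software/TDM meropenem program (91 septic ICU patients, 229
#' concentration measurements) as a plain-JSON fixture. This harness
#' recomputes every percentage, the Woolf odds ratio with its 95% CI, and
#' the (uncorrected) chi-square p-value from those raw counts and diffs
#' them against the values printed in the source tables.
#'
#' @param path Fixture path; defaults to the installed copy.
#' @return A list of class `reference_verification`:
#'   \describe{
#'     \item{tallies}{tibble `table`, `band`, `n`, `percent` (recomputed),
#'       `printed_percent`, `diff`.}
#'     \item{mortality}{tibble `quantity`, `computed`, `printed`, `diff`
#'       for the odds ratio, its CI bounds, and the chi-square p.}
#'   }
#' @export
verify_reference_tallies <- function(path = reference_tally_path()) {
  abort_if(!file.exists(path), sprintf("fixture not found: '%s'.", path))
  fx <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- c(fx$phase_tallies, fx$strategy_tallies)
  printed <- c(fx$printed_percent[names(fx$phase_tallies)],
               fx$printed_percent[names(fx$strategy_tallies)])
  tallies <- purrr::imap(groups, function(counts, nm) {
    t <- band_tally_from_counts(counts, group = nm)
    t$printed_percent <- as.numeric(printed[[nm]])
    t
  }) |>
    purrr::list_rbind() |>
    dplyr::rename(table = "group") |>
    dplyr::mutate(diff = .data$percent - .data$printed_percent)
  mo <- fx$mortality
  or <- odds_ratio_woolf(mo$died_exposed, mo$survived_exposed,
                         mo$died_reference, mo$survived_reference)
  tab <- matrix(c(mo$died_exposed, mo$died_reference,
                  mo$survived_exposed, mo$survived_reference), 2, 2)
  # printed p is the plain Pearson chi-square, no exact-test fallback
  test <- chi_square_test(tab, correct = FALSE, fisher_fallback = FALSE)
  mortality <- tibble::tibble(
    quantity = c("odds_ratio", "ci_lower", "ci_upper", "p_value"),
    computed = c(or$estimate, or$conf.low, or$conf.high, test$p.value),
    printed = c(mo$printed_or, mo$printed_ci[1], mo$printed_ci[2],
                mo$printed_p)
  ) |>
    dplyr::mutate(diff = .data$computed - .data$printed)
  structure(list(tallies = tallies, mortality = mortality),
            class = "reference_verification")
}

#' @rdname verify_reference_tallies
#' @export
reference_tally_path <- function() {
  system.file("extdata", "reference_tallies.json", package = "merotdm",
              mustWork = FALSE)
}

#' @export
print.reference_verification <- function(x, ...) {
  cat("Recomputed vs printed percentages (max |diff|",
      sprintf("%.2f):\n", max(abs(x$tallies$diff))))
  print(tibble::as_tibble(x$tallies), n = Inf)
  cat("\nMortality 2x2 statistics:\n")
  print(x$mortality)
  invisible(x)
}
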