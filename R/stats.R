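#' 2x2 odds ratio with Woolf confidence interval
#'
#' For a 2x2 table with rows = exposure groups and columns =
#' died / survived,
#' `OR = a d / (b c)` and the Woolf interval is computed on the log scale,
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' If any cell is zero the Haldane-Anscombe correction adds 0.5 to every
#' cell and the result is flagged; a fully zero row or column leaves the
#' odds ratio undefined and is an error.
#'
#' @param x A 2x2 matrix/table of non-negative counts, or the count `a`
#'   when `b`, `c`, `d` are given separately (row 1 = exposed:
#'   `a` died, `b` survived; row 2 = reference: `c` died, `d` survived).
#' @param b,c,d Remaining cell counts when `x` is scalar.
#' @param alpha Significance level of the interval (default 0.05 for a 95%
#'   CI).
#' @return An object of class `or_woolf`: a list with `estimate`,
#'   `conf.low`, `conf.high`, `alpha`, `continuity_corrected`, and the
#'   (possibly corrected) `table`. Has [generics::tidy()] and
#'   [generics::glance()] methods.
#' @examples
#' odds_ratio_woolf(4, 5, 22, 33) # OR 1.200, 95% CI 0.290-4.970
#' @export
odds_ratio_woolf <- function(x, b = NULL, c = NULL, d = NULL, alpha = 0.05) {
  tab <- if (is.matrix(x) || is.table(x)) {
    stopifnot(all(dim(x) == c(2, 2)))
    matrix(as.numeric(x), 2, 2)
  } else {
    matrix(c(x, c, b, d), 2, 2)
  }
  abort_if(any(tab < 0) || any(!is.finite(tab)), "counts must be non-negative.")
  abort_if(
    any(rowSums(tab) == 0) || any(colSums(tab) == 0),
    "a zero row or column margin leaves the odds ratio undefined."
  )
  corrected <- any(tab == 0)
  if (corrected) tab <- tab + 0.5
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  se <- sqrt(sum(1 / tab))
  z <- stats::qnorm(1 - alpha / 2)
  structure(
    list(
      estimate = or,
      conf.low = exp(log(or) - z * se),
      conf.high = exp(log(or) + z * se),
      alpha = alpha,
      continuity_corrected = corrected,
      table = tab
    ),
    class = "or_woolf"
  )
}

#' @export
print.or_woolf <- function(x, ...) {
  cat(sprintf(
    "Odds ratio %.3f, %d%% CI (Woolf) %.3f-%.3f%s\n",
    x$estimate, round(100 * (1 - x$alpha)), x$conf.low, x$conf.high,
    if (x$continuity_corrected) " [Haldane-Anscombe corrected]" else ""
  ))
  invisible(x)
}

#' @method tidy or_woolf
#' @export
tidy.or_woolf <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate,
    conf.low = x$conf.low,
    conf.high = x$conf.high,
    method = "Woolf",
    continuity_corrected = x$continuity_corrected
  )
}

#' @method glance or_woolf
#' @export
glance.or_woolf <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate,
    conf.low = x$conf.low,
    conf.high = x$conf.high,
    alpha = x$alpha
  )
}

#' Chi-square test of independence with exact-test fallback
#'
#' Pearson chi-square on a 2xk (or rxk) contingency table, without Yates
#' continuity correction by default — the convention that reproduces
#' published uncorrected p-values from printed 2x2 counts. When any
#' expected cell count is below 5 and `fisher_fallback = TRUE`, Fisher's
#' exact test is used instead and flagged in the result.
#'
#' @param x A matrix/table of non-negative counts with at least 2 rows and
#'   2 columns.
#' @param correct Apply the Yates continuity correction (2x2 only; default
#'   `FALSE`).
#' @param fisher_fallback Use Fisher's exact test when any expected count
#'   is < 5 (default `TRUE`).
#' @return A list of class `merotdm_test`: `statistic` (NA for the exact
#'   test), `p.value`, `df`, `method`, `min_expected`, `fisher_used`. Has a
#'   [generics::tidy()] method.
#' @examples
#' chi_square_test(matrix(c(4, 22, 5, 33), 2, 2))
#' @export
chi_square_test <- function(x, correct = FALSE, fisher_fallback = TRUE) {
  tab <- as.matrix(x)
  abort_if(any(tab < 0) || any(!is.finite(tab)), "counts must be non-negative.")
  abort_if(any(dim(tab) < 2), "need at least a 2x2 table.")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  min_exp <- min(expected)
  if (fisher_fallback && min_exp < 5) {
    ft <- stats::fisher.test(tab)
    res <- list(statistic = NA_real_, p.value = ft$p.value, df = NA_real_,
                method = "Fisher's exact test", min_expected = min_exp,
                fisher_used = TRUE)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    res <- list(statistic = unname(ct$statistic), p.value = ct$p.value,
                df = unname(ct$parameter), method = ct$method,
                min_expected = min_exp, fisher_used = FALSE)
  }
  structure(res, class = "merotdm_test")
}

#' @export
print.merotdm_test <- function(x, ...) {
  if (x$fisher_used) {
    cat(sprintf("%s: p = %.4g (min expected %.2f)\n",
                x$method, x$p.value, x$min_expected))
  } else {
    cat(sprintf("%s: X2 = %.4g, df = %g, p = %.4g\n",
                x$method, x$statistic, x$df, x$p.value))
  }
  invisible(x)
}

#' @method tidy merotdm_test
#' @export
tidy.merotdm_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    p.value = x$p.value,
    df = x$df,
    method = x$method,
    fisher_used = x$fisher_used
  )
}

#' Unpaired two-proportion comparison
#'
#' Chi-square comparison of two attainment proportions (e.g. therapeutic
#' fractions before and after TDM adjustment), uncorrected by default.
#' Built from the underlying 2x2 success/failure table via
#' [chi_square_test()].
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @param correct Yates correction flag.
#' @return A `merotdm_test` list.
#' @examples
#' two_proportion_test(55, 91, 96, 138)
#' @export
two_proportion_test <- function(x1, n1, x2, n2, correct = FALSE) {
  stopifnot(x1 <= n1, x2 <= n2)
  tab <- matrix(c(x1, x2, n1 - x1, n2 - x2), nrow = 2)
  chi_square_test(tab, correct = correct, fisher_fallback = FALSE)
}
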