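test_that("Woolf odds ratio reproduces the published mortality contrast", {
  or <- odds_ratio_woolf(4, 5, 22, 33)
  expect_equal(round(or$estimate, 3), 1.200)
  expect_equal(round(or$conf.low, 3), 0.290)
  expect_equal(round(or$conf.high, 3), 4.970)
  expect_false(or$continuity_corrected)
  td <- tidy(or)
  expect_equal(td$estimate, or$estimate)
  expect_true(td$conf.low <= td$estimate & td$estimate <= td$conf.high)
})

test_that("Woolf interval matches an independent logistic-regression oracle", {
  # expand the table to patient-level data and fit logit(death) ~ exposure:
  # the GLM's log-OR and its SE must equal the hand-computed Woolf values
  tabs <- list(c(4, 5, 22, 33), c(10, 20, 7, 40), c(3, 9, 11, 2))
  for (tb in tabs) {
    d <- data.frame(
      exposed = rep(c(1, 1, 0, 0), tb),
      died = rep(c(1, 0, 1, 0), tb)
    )
    fit <- stats::glm(died ~ exposed, family = stats::binomial(), data = d)
    or <- odds_ratio_woolf(tb[1], tb[2], tb[3], tb[4])
    expect_equal(unname(stats::coef(fit)["exposed"]), log(or$estimate),
                 tolerance = 1e-6)
    se_glm <- sqrt(stats::vcov(fit)["exposed", "exposed"])
    se_woolf <- (log(or$conf.high) - log(or$estimate)) / stats::qnorm(0.975)
    expect_equal(se_glm, se_woolf, tolerance = 1e-6)
  }
})

test_that("odds ratio symmetry, reciprocity and degenerate cases", {
  sym <- odds_ratio_woolf(7, 7, 7, 7)
  expect_equal(sym$estimate, 1)
  expect_true(sym$conf.low < 1 && sym$conf.high > 1)
  a <- odds_ratio_woolf(4, 5, 22, 33)
  b <- odds_ratio_woolf(22, 33, 4, 5) # swapped rows
  expect_equal(b$estimate, 1 / a$estimate)
  expect_equal(b$conf.low, 1 / a$conf.high)
  zc <- odds_ratio_woolf(0, 10, 5, 5)
  expect_true(zc$continuity_corrected)
  expect_error(odds_ratio_woolf(0, 0, 5, 5), "margin")
})

test_that("chi-square on the mortality table matches the published p-value", {
  tab <- matrix(c(4, 22, 5, 33), 2, 2)
  res <- chi_square_test(tab, correct = FALSE, fisher_fallback = FALSE)
  expect_equal(res$statistic, 0.0634, tolerance = 1e-2)
  expect_equal(round(res$p.value, 3), 0.801)
  # the smallest expected count is below 5, so the default falls back to Fisher
  res_fb <- chi_square_test(tab)
  expect_true(res_fb$fisher_used)
  expect_lt(res_fb$min_expected, 5)
})

test_that("chi-square structural properties hold", {
  tab <- matrix(c(10, 20, 30, 40), 2, 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  perfect <- chi_square_test(expected, fisher_fallback = FALSE)
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p.value, 1)
  # invariance under row/column permutation
  r1 <- chi_square_test(tab, fisher_fallback = FALSE)
  r2 <- chi_square_test(tab[2:1, 2:1], fisher_fallback = FALSE)
  expect_equal(r1$statistic, r2$statistic)
  # p decreases as effect size grows at fixed n
  weak <- chi_square_test(matrix(c(26, 24, 24, 26), 2, 2),
                          fisher_fallback = FALSE)
  strong <- chi_square_test(matrix(c(40, 10, 10, 40), 2, 2),
                            fisher_fallback = FALSE)
  expect_lt(strong$p.value, weak$p.value)
  expect_error(chi_square_test(matrix(c(-1, 2, 3, 4), 2, 2)), "non-negative")
})

test_that("two-proportion comparison equals the z/chi-square oracle", {
  res <- two_proportion_test(55, 91, 96, 138)
  oracle <- stats::prop.test(c(55, 96), c(91, 138), correct = FALSE)
  expect_equal(res$p.value, oracle$p.value, tolerance = 1e-10)
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-10)
  # the attainment improvement is not significant in the unpaired contrast
  expect_gt(res$p.value, 0.05)
  expect_lt(res$p.value, 0.25)
})
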