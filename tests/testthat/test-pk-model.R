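test_that("continuous infusion obeys initial condition and steady-state limit", {
  pk <- pk_parameters(10, 25)
  expect_equal(conc_continuous_infusion(100, pk, 0), 0)
  expect_equal(conc_continuous_infusion(100, pk, 1e6), 100 / 10)
  # Css = daily dose / (24 CL) exactly
  expect_equal(css_continuous(2400, 5), 2400 / (24 * 5))
  expect_error(pk_parameters(-1, 25), "clearance")
  expect_error(pk_parameters(5, 0), "volume")
})

test_that("continuous-infusion closed form matches the ODE oracle", {
  skip_if_not_installed("deSolve")
  pk <- pk_parameters(5, 25)
  expect_equal(conc_continuous_infusion(100, pk, 5), 12.642, tolerance = 1e-4)
  for (cl in c(2, 5, 9)) {
    for (v in c(15, 25, 40)) {
      times <- c(0.5, 3, 12, 36)
      closed <- conc_continuous_infusion(120, pk_parameters(cl, v), times)
      oracle <- ode_constant_infusion(120, cl, v, times)
      expect_rel_equal(closed, oracle, 1e-6)
    }
  }
})

test_that("intermittent steady state matches superposed-dose numeric integration", {
  skip_if_not_installed("deSolve")
  reg <- dose_regimen("intermittent", 1000, infusion_duration_h = 0.5,
                      interval_h = 8)
  pk <- pk_parameters(7.1, 25)
  n_doses <- 35
  # concentration within the final interval of a long superposition run
  t_grid <- c(0.25, 0.5, 2, 8)
  oracle <- ode_repeated_infusions(1000, 0.5, 8, n_doses, 7.1, 25,
                                   times = (n_doses - 1) * 8 + t_grid)
  closed <- conc_intermittent_ss(reg, pk, t_grid)
  expect_rel_equal(closed, oracle, 1e-4)
})

test_that("intermittent limits and monotonicity behave physiologically", {
  # infusion spanning the whole interval = continuous infusion steady state
  reg_ci_like <- dose_regimen("intermittent", 800, infusion_duration_h = 8,
                              interval_h = 8)
  pk <- pk_parameters(6, 25)
  expect_equal(conc_intermittent_ss(reg_ci_like, pk, c(0, 4, 8)),
               rep(css_continuous(800 * 3, 6), 3))
  # trough strictly decreases as clearance increases
  reg <- dose_regimen("intermittent", 1000, interval_h = 8)
  expect_gt(trough_intermittent_ss(reg, pk_parameters(4, 25)),
            trough_intermittent_ss(reg, pk_parameters(8, 25)))
  expect_error(conc_intermittent_ss(reg, pk, 9), "interval")
})

test_that("profiles superpose linearly and stay non-negative", {
  pk <- pk_parameters(7, 25)
  load <- loading_regimen()
  ci <- dose_regimen("continuous", 2000, interval_h = 24)
  times <- c(0.1, 0.25, 1, 6, 24, 120)
  p_load <- conc_profile(load, pk, times)
  p_ci <- conc_profile(ci, pk, times)
  p_both <- conc_profile(dplyr::bind_rows(load, ci), pk, times)
  # hand evaluation: (500 / (7 * 0.25)) * (1 - exp(-0.28 * 0.25))
  expect_equal(p_load$conc_mg_L[p_load$time_h == 0.25],
               (500 / (7 * 0.25)) * (1 - exp(-0.28 * 0.25)),
               tolerance = 1e-12)
  expect_equal(p_load$conc_mg_L[p_load$time_h == 0.25], 19.316, tolerance = 1e-4)
  # linearity: profile(loading + CI) - profile(CI) = profile(loading)
  expect_equal(p_both$conc_mg_L - p_ci$conc_mg_L, p_load$conc_mg_L)
  # loading washes out: long-time value is the CI steady state
  expect_equal(p_both$conc_mg_L[p_both$time_h == 120],
               css_continuous(2000, 7), tolerance = 1e-6)
  expect_true(all(p_both$conc_mg_L >= 0))
  expect_error(conc_profile(ci[0, ], pk, times), "non-empty")
})

test_that("loading profile matches the single-infusion ODE oracle", {
  skip_if_not_installed("deSolve")
  pk <- pk_parameters(7, 25)
  times <- c(0.1, 0.25, 1, 4)
  closed <- conc_profile(loading_regimen(), pk, times)$conc_mg_L
  oracle <- ode_single_infusion(500, 0.25, 7, 25, times)
  expect_rel_equal(closed, oracle, 1e-6)
})

test_that("dose_regimen derives the daily dose and validates durations", {
  reg <- dose_regimen("intermittent", 1000, interval_h = 8)
  expect_equal(reg$daily_dose_mg, 3000)
  expect_equal(loading_regimen()$daily_dose_mg, 0)
  expect_error(
    dose_regimen("intermittent", 1000, infusion_duration_h = 10, interval_h = 8),
    "interval"
  )
})
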