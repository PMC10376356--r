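test_that("empiric dose inverts the continuous-infusion steady state", {
  expect_equal(empiric_daily_dose(5, rounding_increment_mg = 1), 1440)
  expect_equal(empiric_daily_dose(7.1, rounding_increment_mg = 250), 2000)
  # unrounded dose round-trips to the setpoint exactly
  tgt <- exposure_target()
  for (cl in c(2.3, 5, 7.1, 11)) {
    expect_equal(css_continuous(tgt$setpoint * cl * 24, cl), tgt$setpoint,
                 tolerance = 1e-9)
  }
  expect_error(empiric_daily_dose(0), "cl_pred")
})

test_that("empiric dose is monotone, bounded, and rounds by at most half an increment", {
  cls <- seq(0.5, 25, by = 0.25)
  doses <- empiric_daily_dose(cls)
  expect_true(all(diff(doses) >= 0))
  expect_true(all(doses >= 500 & doses <= 6000))
  # away from the bound clamp, rounding moves the dose <= increment/2
  unclamped <- cls[cls * 12 * 24 > 600 & cls * 12 * 24 < 5900]
  expect_true(all(abs(empiric_daily_dose(unclamped) - unclamped * 12 * 24) <= 50))
  # monotone in the setpoint too
  expect_gt(empiric_daily_dose(5, exposure_target(setpoint = 14)),
            empiric_daily_dose(5, exposure_target(setpoint = 10)))
})

test_that("loading regimen is a fixed 500 mg over 15 minutes", {
  lr <- loading_regimen()
  expect_equal(lr$mode, "loading")
  expect_equal(lr$dose_mg, 500)
  expect_equal(lr$infusion_duration_h, 0.25)
  expect_equal(lr$daily_dose_mg, 0) # excluded from maintenance accounting
  # a 500 mg load can never exceed dose/volume
  pk <- pk_parameters(7, 25)
  prof <- conc_profile(lr, pk, seq(0, 6, by = 0.05))
  expect_true(all(prof$conc_mg_L <= 500 / 25))
})

test_that("label tiers map renal function to the approved regimens", {
  r <- smpc_standard_regimen(80, "bolus")
  expect_equal(c(r$dose_mg, r$interval_h, r$infusion_duration_h,
                 r$daily_dose_mg), c(1000, 8, 0.5, 3000))
  expect_equal(smpc_standard_regimen(30, "bolus")$daily_dose_mg, 2000)
  expect_equal(smpc_standard_regimen(15, "bolus")$dose_mg, 500)
  expect_equal(smpc_standard_regimen(5, "bolus")$interval_h, 24)
  expect_equal(smpc_standard_regimen(0, "bolus", on_crrt = TRUE)$daily_dose_mg,
               2000)
  # ci mode carries the same daily dose as the bolus tier
  for (crcl in c(5, 15, 30, 80)) {
    expect_equal(smpc_standard_regimen(crcl, "ci")$daily_dose_mg,
                 smpc_standard_regimen(crcl, "bolus")$daily_dose_mg)
  }
})

test_that("vectorized tier lookup agrees with the scalar regimen constructor", {
  crcls <- c(0, 5, 9.9, 10, 25.9, 26, 49.9, 50, 50.1, 80, 130)
  vec <- merotdm:::smpc_lookup(crcls, rep(FALSE, length(crcls)))
  for (i in seq_along(crcls)) {
    r <- smpc_standard_regimen(crcls[i], "bolus")
    expect_equal(vec$dose_mg[i], r$dose_mg)
    expect_equal(vec$interval_h[i], r$interval_h)
  }
  vec_crrt <- merotdm:::smpc_lookup(c(40, 80), c(TRUE, TRUE))
  expect_equal(vec_crrt$dose_mg, c(1000, 1000))
  expect_equal(vec_crrt$interval_h, c(12, 12))
})

test_that("dose_table composes renal estimation with empiric dosing", {
  pts <- tibble::tibble(
    patient_id = "P1", age = 73, weight_kg = 80, scr_mg_dl = 1.3, sex = "male"
  )
  out <- dose_table(pts)
  expect_equal(out$crcl, 57.26496, tolerance = 1e-6)
  cl <- predict_clearance(out$crcl)
  expect_equal(out$ci_daily_dose_mg, round(12 * cl * 24 / 100) * 100)
  expect_equal(out$loading_dose_mg, 500)
  expect_false(out$crrt_branch)
  # CRRT rows are flagged and use the effluent branch
  crrt <- tibble::tibble(
    patient_id = "P2", age = 60, weight_kg = 70, scr_mg_dl = 2.5, sex = "female",
    on_crrt = TRUE, effluent_flow_l_h = 2
  )
  out2 <- dose_table(crrt)
  expect_true(out2$crrt_branch)
  expect_equal(out2$cl_pred, 0.25 * 12.5 + 2)
  expect_error(dose_table(pts[0, ]), "non-empty")
})
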