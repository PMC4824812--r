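test_that("incremental AUC matches hand trapezoids and is additive", {
  expect_equal(incremental_auc(c(0, 10, 20), c(5, 7, 5), 5), 20)
  expect_equal(incremental_auc(c(0, 10, 20), c(5, 5, 5), 5), 0)
  # net area keeps negative lobes; clipping removes them
  expect_equal(incremental_auc(c(0, 10, 20), c(5, 3, 5), 5), -20)
  expect_equal(incremental_auc(c(0, 10, 20), c(5, 3, 5), 5,
                               clip_negative = TRUE), 0)
  # additive over adjacent windows
  tt <- c(0, 15, 30, 60, 90)
  vv <- c(5, 8, 7, 4, 6)
  whole <- incremental_auc(tt, vv, 5, c(0, 90))
  parts <- incremental_auc(tt, vv, 5, c(0, 30)) +
    incremental_auc(tt, vv, 5, c(30, 90))
  expect_equal(whole, parts)
  # invariant to inserting a collinear point
  tt2 <- c(0, 15, 22.5, 30, 60, 90)
  vv2 <- c(5, 8, 7.5, 7, 4, 6)
  expect_equal(incremental_auc(tt2, vv2, 5, c(0, 90)), whole)
  expect_error(incremental_auc(tt, vv, 5, c(0, 120)), "window")
})

test_that("post-load incremental AUC uses the nine positive sampling times", {
  ser <- make_series()
  post <- ser$times > 0
  expect_length(ser$times[post], 9)
  auc <- incremental_auc(ser$times[post], ser$glucose[post], 5.0)
  # hand check on the same grid
  tt <- ser$times[post]
  vv <- ser$glucose[post] - 5.0
  expect_equal(auc, sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2))
})

test_that("disposition indices are exact bilinear products", {
  di <- disposition_indices(phi_basal = 4.4, phi_static = 10,
                            phi_dynamic = 250, phi_oral = 13, s_i = 2)
  expect_identical(di$di_static, 20)
  expect_identical(di$di_basal, 8.8)
  expect_identical(di$di_dynamic, 500)
  expect_identical(di$di_oral, 26)
  di0 <- disposition_indices(4.4, 10, 250, 13, s_i = 0)
  expect_true(all(unlist(di0) == 0))
  dina <- disposition_indices(NA_real_, 10, 250, 13, s_i = 2)
  expect_true(is.na(dina$di_basal))
  expect_identical(dina$di_static, 20)
})

test_that("renal glucose clearance is linear and guards its domain", {
  u <- urine_collection(volume_l = 0.4, glucose_mmol_l = 25,
                        cpeptide_nmol_l = 20, creatinine_mmol_l = 6)
  cl <- renal_glucose_clearance(u, total_plasma_glucose_auc = 2500)
  expect_equal(cl$amount_mmol, 10)
  expect_equal(cl$pct, 100 * 10 / 2500)
  u0 <- urine_collection(0.4, 0, 20, 6)
  expect_equal(renal_glucose_clearance(u0, 2500)$pct, 0)
  u2 <- urine_collection(0.8, 25, 20, 6)   # double volume, same concentration
  expect_equal(renal_glucose_clearance(u2, 2500)$pct, 2 * cl$pct)
  expect_true(is.na(renal_glucose_clearance(NULL, 2500)$pct))
  expect_true(is.na(renal_glucose_clearance(u, 0)$pct))
})

test_that("MDRD eGFR matches hand evaluation and is monotone", {
  expect_equal(egfr_mdrd(1.0, 40, "male"), 175 * 40^-0.203, tolerance = 1e-12)
  expect_equal(egfr_mdrd(1.0, 40, "male"), 82.8, tolerance = 1e-3)
  expect_equal(egfr_mdrd(1.0, 40, "female"),
               0.742 * egfr_mdrd(1.0, 40, "male"))
  expect_equal(egfr_mdrd(1.0, 40, "male", black = TRUE),
               1.212 * egfr_mdrd(1.0, 40, "male"))
  scr <- seq(0.5, 3, by = 0.1)
  expect_true(all(diff(egfr_mdrd(scr, 40, "male")) < 0))
  expect_error(egfr_mdrd(0, 40, "male"), "positive")
})

test_that("creatinine adjustment is plain division with a guarded zero", {
  expect_equal(creatinine_adjust(0, 6), 0)
  expect_equal(creatinine_adjust(7, 7), 1)
  expect_equal(creatinine_adjust(25, 6), 25 / 6)
  expect_true(is.na(creatinine_adjust(25, 0)))
})
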