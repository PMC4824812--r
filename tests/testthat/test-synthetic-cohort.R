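test_that("a fixed seed reproduces the cohort bit for bit", {
  a <- generate_cohort(cohort_config(n_ngt = 3, n_ifg_igt = 2, n_t2d = 2,
                                     seed = 14))
  b <- generate_cohort(cohort_config(n_ngt = 3, n_ifg_igt = 2, n_t2d = 2,
                                     seed = 14))
  expect_identical(a$truth, b$truth)
  for (i in seq_along(a$cohort)) {
    expect_identical(a$cohort[[i]]$series$glucose, b$cohort[[i]]$series$glucose)
    expect_identical(a$cohort[[i]]$urine$glucose_mmol_l,
                     b$cohort[[i]]$urine$glucose_mmol_l)
  }
  d <- generate_cohort(cohort_config(n_ngt = 3, n_ifg_igt = 2, n_t2d = 2,
                                     seed = 15))
  expect_false(identical(a$truth$s_i, d$truth$s_i))
})

test_that("non-spilling subjects carry only the urinary assay floor", {
  gen <- generate_cohort(quiet_config(n_ngt = 12, n_ifg_igt = 0, n_t2d = 0,
                                      seed = 22))
  peaks <- vapply(gen$cohort, function(r) max(r$series$glucose), numeric(1))
  expect_true(all(peaks < 10))
  ug <- vapply(gen$cohort, function(r) r$urine$glucose_mmol_l, numeric(1))
  expect_true(all(ug < run_config()$urine_positivity_cutoff))
  expect_true(all(gen$truth$urine_glucose_amount_mmol == 0))
})

test_that("subgroup locations are respected in the large-sample limit", {
  gen <- generate_cohort(cohort_config(n_ngt = 200, n_ifg_igt = 0, n_t2d = 0,
                                       seed = 33))
  # lognormal draws: compare on the log scale (location log(20), sd 0.5)
  m <- mean(log(gen$truth$s_i))
  expect_lt(abs(m - log(20)), 3 * 0.5 / sqrt(200))
})

test_that("subgroup gradients mirror the expected ordering", {
  gen <- generate_cohort(cohort_config(seed = 60))   # default 22/12/18
  idx <- split(seq_along(gen$cohort), gen$truth$tolerance_class)
  gauc <- vapply(gen$cohort, function(r) {
    p <- ommurine:::.postload(r$series)
    total_auc(p$times, p$glucose, c(0, 210))
  }, numeric(1))
  ug <- vapply(gen$cohort, function(r) r$urine$glucose_mmol_l, numeric(1))
  expect_lt(mean(gauc[idx$NGT]), mean(gauc[idx$IFG_IGT]))
  expect_lt(mean(gauc[idx$IFG_IGT]), mean(gauc[idx$T2D]))
  expect_lt(mean(ug[idx$NGT]), mean(ug[idx$T2D]))
  expect_lt(mean(ug[idx$IFG_IGT]), mean(ug[idx$T2D]))
})

test_that("urinary C-peptide tracks the k01 flux AUC by construction", {
  gen <- generate_cohort(cohort_config(n_ngt = 20, n_ifg_igt = 20, n_t2d = 20,
                                       seed = 44))
  ucp <- vapply(gen$cohort, function(r) r$urine$cpeptide_nmol_l, numeric(1))
  amount <- ucp * gen$truth$urine_volume_l   # concentration x volume
  r <- cor(amount, gen$truth$k01_flux_auc, method = "spearman")
  expect_gt(r, 0.5)
})

test_that("degenerate and invalid configurations are handled", {
  empty <- generate_cohort(cohort_config(n_ngt = 0, n_ifg_igt = 0, n_t2d = 0,
                                         seed = 1))
  expect_length(empty$cohort, 0)
  expect_equal(nrow(empty$truth), 0)
  expect_error(cohort_config(n_ngt = -1), "subgroup sizes")
  expect_error(cohort_config(noise_cv = list(glucose = -0.1, insulin = 0,
                                             cpeptide = 0)),
               "CV")
  expect_error(cohort_config(renal = list(threshold_nont2d = -2)), "renal")
})

test_that("generated records pass their own type validation and labels", {
  gen <- generate_cohort(cohort_config(n_ngt = 2, n_ifg_igt = 2, n_t2d = 2,
                                       seed = 3))
  for (rec in gen$cohort) {
    expect_s3_class(rec$series, "ogtt_series")
    expect_s3_class(rec$subject, "subject_record")
    expect_true(rec$subject$tolerance_class %in% c("NGT", "IFG_IGT", "T2D"))
    expect_length(rec$series$times, 11)
    b <- basal_values(rec$series)
    expect_true(all(unlist(b) > 0))
  }
  expect_setequal(unique(gen$truth$tolerance_class),
                  c("NGT", "IFG_IGT", "T2D"))
})
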