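test_that("domain types enforce their invariants", {
  expect_error(ogtt_series(c(15, 30), c(5, 5), c(50, 50), c(400, 400)),
               "pre-load")
  expect_error(ogtt_series(c(-60, 30, 30), c(5, 5, 5), c(50, 50, 50),
                           c(400, 400, 400)),
               "strictly increasing")
  expect_error(ogtt_series(c(-60, 30), c(5, -1), c(50, 50), c(400, 400)),
               "negative")
  expect_error(subject_record("a", "f", sex = "male", age = -1, weight = 70,
                              height = 1.7, serum_creatinine = 0.9),
               "age")
  expect_error(urine_collection(0, 1, 1, 1), "volume")
  expect_error(run_config(threshold_grid = c(9, 9)), "increasing")
})

test_that("WHO classification partitions the plane with inclusive cutoffs", {
  expect_equal(classify_who(5.0, 6.0), "NGT")
  expect_equal(classify_who(7.0, 6.0), "T2D")      # fasting boundary
  expect_equal(classify_who(5.0, 11.1), "T2D")     # 2-h boundary
  expect_equal(classify_who(5.5, 8.0), "IFG_IGT")  # IGT band
  expect_equal(classify_who(6.1, 6.0), "IFG_IGT")  # IFG boundary
  expect_error(classify_who(0, 5), "positive")
  # total over a grid of positive values: always one of the three classes
  fg <- seq(3, 12, by = 0.25)
  th <- seq(3, 15, by = 0.25)
  grid <- expand.grid(fg = fg, th = th)
  cls <- classify_who(grid$fg, grid$th)
  expect_true(all(cls %in% c("NGT", "IFG_IGT", "T2D")))
  expect_setequal(unique(cls), c("NGT", "IFG_IGT", "T2D"))
})

test_that("cohort round-trips through CSV at full precision", {
  gen <- generate_cohort(quiet_config(n_ngt = 2, n_ifg_igt = 1, n_t2d = 1,
                                      seed = 5))
  td <- withr::local_tempdir()
  plasma <- file.path(td, "plasma.csv")
  urine <- file.path(td, "urine.csv")
  write_cohort(gen$cohort, plasma, urine)
  back <- read_cohort(plasma, urine)
  expect_length(back, 4)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$subject$subject_id,
                     gen$cohort[[i]]$subject$subject_id)
    expect_equal(back[[i]]$series$times, gen$cohort[[i]]$series$times)
    expect_equal(back[[i]]$series$glucose, gen$cohort[[i]]$series$glucose)
    expect_equal(back[[i]]$series$cpeptide, gen$cohort[[i]]$series$cpeptide)
    expect_equal(back[[i]]$urine$volume_l, gen$cohort[[i]]$urine$volume_l)
  }
  expect_length(back[[1]]$series$times, 11)
})

test_that("subjects without urine rows come back with urine missing, not zero", {
  gen <- generate_cohort(quiet_config(n_ngt = 2, n_ifg_igt = 0, n_t2d = 0,
                                      seed = 5))
  gen$cohort[[2]]$urine <- NULL
  td <- withr::local_tempdir()
  plasma <- file.path(td, "plasma.csv")
  urine <- file.path(td, "urine.csv")
  write_cohort(gen$cohort, plasma, urine)
  back <- read_cohort(plasma, urine)
  expect_false(is.null(back[[1]]$urine))
  expect_null(back[[2]]$urine)
})

test_that("schema and validation errors are specific", {
  td <- withr::local_tempdir()
  bad <- file.path(td, "bad.csv")
  readr::write_csv(tibble::tibble(subject_id = "S1", time_min = 15), bad)
  expect_error(read_cohort(bad), "family_id")

  gen <- generate_cohort(quiet_config(n_ngt = 1, n_ifg_igt = 0, n_t2d = 0,
                                      seed = 5))
  plasma <- file.path(td, "plasma.csv")
  write_cohort(gen$cohort, plasma)
  tab <- readr::read_csv(plasma, show_col_types = FALSE)
  tab$time_min[2] <- tab$time_min[3]   # duplicate a timepoint
  readr::write_csv(tab, plasma)
  expect_error(read_cohort(plasma), "S001")
})
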