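test_that("secretion rate honours basal steady state and step asymptote", {
  p <- secretion_params(phi_static = 15, phi_dynamic = 200, t_delay = 10,
                        h_threshold = 5)
  # glucose pinned at basal with h = Gb: SR identically SRb
  tt <- seq(0, 210, by = 15)
  sr <- secretion_rate(p, tt, rep(5, length(tt)), srb = 30, t_eval = tt)
  expect_equal(sr, rep(30, length(tt)))
  # step to G = 8 held long: static state approaches phi_s * (G - h)
  tt2 <- c(0, 1, seq(10, 600, by = 10))
  g2 <- c(5, rep(8, length(tt2) - 1))
  sr2 <- secretion_rate(p, tt2, g2, srb = 30, t_eval = 600)
  expect_equal(sr2, 30 + 15 * 3, tolerance = 1e-4)
})

test_that("integrated dynamic secretion equals phi_dynamic times the rise", {
  p <- secretion_params(phi_static = 0, phi_dynamic = 250, t_delay = 10,
                        h_threshold = 20)  # static silenced (h above range)
  tt <- seq(0, 60, by = 15)
  g <- c(5, 6.5, 8, 8.8, 9.2)              # monotone ramp Gb -> Gmax
  # SR_dynamic is piecewise constant, so integrate by the midpoint rule on a
  # grid aligned with the sample knots (exact for step functions)
  dt <- 0.05
  mids <- seq(dt / 2, 60 - dt / 2, by = dt)
  sr <- secretion_rate(p, tt, g, srb = 0, t_eval = mids)
  auc <- sum(sr * dt)
  expect_equal(auc, 250 * (9.2 - 5), tolerance = 1e-6)
})

test_that("ODE and exact-recursion secretion paths agree", {
  p <- secretion_params(phi_static = 18, phi_dynamic = 220, t_delay = 9,
                        h_threshold = 5.2)
  kin <- test_kinetics()
  ser <- make_series()
  post <- ser$times > 0
  gt <- c(0, ser$times[post])
  gv <- c(5.0, ser$glucose[post])
  tt <- seq(0, 210, by = 2.5)
  sim <- simulate_secretion_cpeptide(p, kin, gt, gv, cpb = 450, times = tt,
                                     rtol = 1e-10)
  # the ODE's static secretion state must match the exact per-segment
  # exponential recursion used by secretion_rate
  p_static <- secretion_params(phi_static = 18, phi_dynamic = 0, t_delay = 9,
                               h_threshold = 5.2)
  y_exact <- secretion_rate(p_static, gt, gv, srb = 0, t_eval = tt)
  expect_lt(max(abs(sim$y - y_exact)), 1e-5 * max(abs(y_exact)))
})

test_that("noise-free synthetic curves refit to the generating parameters", {
  gen <- generate_cohort(quiet_config(n_ngt = 2, n_ifg_igt = 0, n_t2d = 1,
                                      seed = 31))
  # priors off: this checks exact self-consistency of the WNLS estimator
  cfg <- run_config(t_delay_prior_sdlog = Inf)
  for (i in seq_along(gen$cohort)) {
    rec <- gen$cohort[[i]]
    kin <- population_kinetics(rec$subject)
    fit <- fit_secretion(rec$series, kin, cfg)
    expect_true(fit$converged)
    expect_equal(fit$params$phi_static, gen$truth$phi_static[i],
                 tolerance = 1e-2)
    expect_equal(fit$params$phi_dynamic, gen$truth$phi_dynamic[i],
                 tolerance = 1e-2)
    expect_equal(fit$params$t_delay, gen$truth$t_delay[i], tolerance = 5e-2)
    expect_length(fit$residuals, 9)
  }
})

test_that("flat curves drive both responsivities to the zero bound", {
  flat <- ogtt_series(ref_times, rep(5.2, 11), rep(55, 11), rep(480, 11))
  fit <- fit_secretion(flat, test_kinetics(), run_config())
  expect_equal(fit$params$phi_static, 0)
  expect_equal(fit$params$phi_dynamic, 0)
  expect_equal(fit$phi_basal, test_kinetics()$k01 * 480 / 5.2)
})

test_that("scaling the C-peptide excursion scales the fitted responsivities", {
  gen <- generate_cohort(quiet_config(n_ngt = 1, n_ifg_igt = 0, n_t2d = 0,
                                      seed = 8))
  rec <- gen$cohort[[1]]
  kin <- population_kinetics(rec$subject)
  cfg <- run_config()
  fit1 <- fit_secretion(rec$series, kin, cfg)
  lam <- 1.7
  ser2 <- rec$series
  cpb <- ser2$cpeptide[1]
  ser2$cpeptide <- cpb + lam * (ser2$cpeptide - cpb)
  fit2 <- fit_secretion(ser2, kin, cfg)
  expect_equal(fit2$params$phi_static / fit1$params$phi_static, lam,
               tolerance = 1e-3)
  expect_equal(fit2$params$phi_dynamic / fit1$params$phi_dynamic, lam,
               tolerance = 1e-2)
})

test_that("fit refuses non-monotone input and too-few samples", {
  ser <- make_series()
  expect_error(ogtt_series(rev(ser$times), ser$glucose, ser$insulin,
                           ser$cpeptide),
               "strictly increasing")
  short <- ogtt_series(c(-60, 15, 30, 60), c(5, 7, 8, 6), c(50, 200, 300, 150),
                       c(450, 800, 1200, 900))
  expect_error(fit_secretion(short, test_kinetics(), run_config()), ">= 8")
})

test_that("phi_oral decomposes exactly and handles degenerate inputs", {
  tt <- c(0, 30, 60, 90, 120)          # triangular excursion
  g <- c(5, 7, 9, 7, 5)
  p <- secretion_params(phi_static = 10, phi_dynamic = 0, t_delay = 8,
                        h_threshold = 5)
  # phi_dynamic = 0 and h = Gb: ratio collapses to phi_static
  expect_equal(phi_oral(p, tt, g, gb = 5), 10)
  # phi_static = 0: single-term form against a hand trapezoid
  p2 <- secretion_params(phi_static = 0, phi_dynamic = 120, t_delay = 8,
                         h_threshold = 5)
  hand_auc <- 240  # triangle: 1/2 * 120 min * 4 mmol/L
  expect_equal(phi_oral(p2, tt, g, gb = 5), 120 * 4 / hand_auc)
  # general case: static part + dynamic part, both non-negative
  p3 <- secretion_params(phi_static = 10, phi_dynamic = 120, t_delay = 8,
                         h_threshold = 5)
  expect_equal(phi_oral(p3, tt, g, gb = 5), 10 + 120 * 4 / hand_auc)
  expect_gte(phi_oral(p3, tt, g, gb = 5), p3$phi_static)
  # glucose never above basal: undefined
  expect_true(is.na(phi_oral(p3, tt, rep(5, 5), gb = 5)))
})
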