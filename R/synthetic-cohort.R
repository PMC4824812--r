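#' Configuration of the synthetic OGTT cohort generator
#'
#' Defines the statistical structure of a simulated family-screening cohort:
#' per-subgroup sample sizes, lognormal parameter distributions anchored to
#' the orders of magnitude typical of NGT / IFG-IGT / T2D subgroups, assay
#' noise, the renal spill model and the urine collection.  All randomness is
#' driven by `seed`; a fixed seed gives a bit-identical cohort.
#'
#' Subgroup anchors (medians of the lognormal draws): insulin sensitivity
#' `s_i` 20 / 10 / 6.5 (1e-5 dL/kg/min per pM), `phi_static` 20 / 12 / 6
#' (1e-9 1/min), `phi_dynamic` 300 / 180 / 110 (1e-9), delay 12 / 11 / 14
#' min, basal glucose 5.1 / 6.1 / 8.0 mmol/L for NGT / IFG-IGT / T2D.
#' Glucose excursions are steered to a drawn target peak by scaling the
#' insulin input (insulin is an input signal, not a modelled state), keeping
#' every curve exactly consistent with the forward model so that fits can be
#' validated against the stored truth.  Non-T2D peaks stay below the renal
#' threshold except for a separated "spiller" component well above it, which
#' makes the grid threshold identifiable; T2D peaks all exceed their
#' (per-subject jittered) thresholds, reproducing the all-excretor behaviour.
#'
#' @param n_ngt,n_ifg_igt,n_t2d Subjects per WHO subgroup.
#' @param ethnicity Ethnicity label stamped on every subject.
#' @param noise_cv Named list of multiplicative assay CVs: `glucose`,
#'   `insulin`, `cpeptide`.
#' @param subgroups Per-subgroup parameter distributions; see Details in the
#'   source.  Override individual entries with care.
#' @param renal Renal spill model: `threshold_nont2d` (mmol/L, shared true
#'   threshold), `threshold_t2d_mean`/`threshold_t2d_sd` (per-subject T2D
#'   jitter), `spill_clearance_l_min` (effective clearance of above-threshold
#'   glucose into urine), `assay_floor_meanlog`/`assay_floor_sdlog` (lognormal
#'   assay floor added to urinary glucose), `cpep_fraction` (median fraction
#'   of the k01 flux recovered in urine) with `cpep_fraction_sdlog`,
#'   `urine_volume_meanlog`/`sdlog` (L), `urine_creatinine_meanlog`/`sdlog`
#'   (mmol/L).
#' @param family_size_probs Probabilities of family sizes 1..4; families are
#'   assigned across subgroups (screened families span tolerance classes).
#' @param missing_urine_frac Fraction of subjects whose urine collection is
#'   dropped (missing, not zero).
#' @param run A [run_config()] supplying model constants and sampling times.
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_ngt = 22, n_ifg_igt = 12, n_t2d = 18,
                          ethnicity = "synthetic",
                          noise_cv = list(glucose = 0.02, insulin = 0.05,
                                          cpeptide = 0.05),
                          subgroups = NULL,
                          renal = NULL,
                          family_size_probs = c(0.35, 0.35, 0.2, 0.1),
                          missing_urine_frac = 0,
                          run = run_config(),
                          seed = 1L) {
  if (any(c(n_ngt, n_ifg_igt, n_t2d) < 0)) {
    rlang::abort("cohort_config: subgroup sizes must be >= 0",
                 class = "ommurine_config_error")
  }
  if (any(unlist(noise_cv) < 0)) {
    rlang::abort("cohort_config: noise CVs must be >= 0",
                 class = "ommurine_config_error")
  }
  default_subgroups <- list(
    NGT = list(s_i = 20, phi_static = 20, phi_dynamic = 300, t_delay = 12,
               gb = 5.1, gb_sdlog = 0.04, ib = 45, cpb = 420, sdlog = 0.5,
               age_mean = 40, peak_min = 7.4, peak_max = 9.8,
               spill_prob = 0, spill_peak_min = NA, spill_peak_max = NA,
               insulin_shape = "prompt"),
    IFG_IGT = list(s_i = 10, phi_static = 12, phi_dynamic = 180, t_delay = 11,
                   gb = 6.1, gb_sdlog = 0.04, ib = 60, cpb = 500, sdlog = 0.5,
                   age_mean = 46, peak_min = 8.4, peak_max = 9.9,
                   spill_prob = 0.25, spill_peak_min = 12.0,
                   spill_peak_max = 13.5, insulin_shape = "prompt"),
    T2D = list(s_i = 6.5, phi_static = 6, phi_dynamic = 110, t_delay = 14,
               gb = 8.0, gb_sdlog = 0.06, ib = 70, cpb = 550, sdlog = 0.5,
               age_mean = 55, peak_min = 12.5, peak_max = 15.5,
               spill_prob = 0, spill_peak_min = NA, spill_peak_max = NA,
               insulin_shape = "delayed"))
  default_renal <- list(
    threshold_nont2d = 10.0, threshold_t2d_mean = 10.0, threshold_t2d_sd = 1.5,
    spill_clearance_l_min = 0.02,
    assay_floor_meanlog = log(0.2), assay_floor_sdlog = 0.5,
    cpep_fraction = 0.12, cpep_fraction_sdlog = 0.3,
    urine_volume_meanlog = log(0.35), urine_volume_sdlog = 0.35,
    urine_creatinine_meanlog = log(6), urine_creatinine_sdlog = 0.3)
  sg <- default_subgroups
  for (nm in names(subgroups %||% list())) {
    sg[[nm]][names(subgroups[[nm]])] <- subgroups[[nm]]
  }
  rn <- default_renal
  rn[names(renal %||% list())] <- renal
  if (rn$threshold_nont2d <= 0 || rn$spill_clearance_l_min < 0) {
    rlang::abort("cohort_config: invalid renal model parameters",
                 class = "ommurine_config_error")
  }
  structure(
    list(n = c(NGT = n_ngt, IFG_IGT = n_ifg_igt, T2D = n_t2d),
         ethnicity = ethnicity, noise_cv = noise_cv, subgroups = sg,
         renal = rn, family_size_probs = family_size_probs,
         missing_urine_frac = missing_urine_frac, run = run,
         seed = as.integer(seed)),
    class = "cohort_config")
}

# Reference 11-point sampling schedule (min relative to the 75 g load).
.sampling_times <- c(-60, -15, 15, 30, 45, 60, 90, 120, 150, 180, 210)

# Normalized insulin excursion shapes at the post-load sampling times.
.insulin_shapes <- list(
  prompt  = c(0.35, 0.70, 0.90, 1.00, 0.85, 0.55, 0.32, 0.17, 0.08),
  delayed = c(0.15, 0.35, 0.55, 0.75, 1.00, 0.90, 0.65, 0.40, 0.20))

#' Generate a synthetic OGTT cohort
#'
#' Draws per-subject true parameters, forward-simulates glucose (oral glucose
#' minimal model) and C-peptide (secretion model + two-compartment kinetics),
#' samples the curves at the reference 11-point schedule with multiplicative
#' assay noise, and builds the pooled urine collection from the renal spill
#' model: urinary glucose amount = effective clearance x above-threshold
#' glucose AUC (+ assay floor), urinary C-peptide = a drawn fraction of the
#' k01-flux AUC times the central volume.  The hidden truth table retains
#' every generating parameter; it is written next to the cohort for
#' parameter-recovery checks and is never read by the fitting pipeline.
#'
#' @param config A [cohort_config()].
#' @return List with `cohort` (list of per-subject records: `subject`,
#'   `series`, `urine`) and `truth` (tibble of generating parameters).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  run <- config$run
  t_post <- .sampling_times[.sampling_times > 0]
  classes <- rep(names(config$n), times = config$n)
  n_total <- length(classes)
  if (n_total == 0) {
    return(list(cohort = list(), truth = tibble::tibble()))
  }

  # family assignment across subgroups
  fam_sizes <- c()
  while (sum(fam_sizes) < n_total) {
    fam_sizes <- c(fam_sizes, sample(1:4, 1, prob = config$family_size_probs))
  }
  fam_of <- rep(seq_along(fam_sizes), times = fam_sizes)[seq_len(n_total)]
  fam_of <- sample(fam_of)   # shuffle so families span subgroups

  cohort <- vector("list", n_total)
  truth <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    cls <- classes[i]
    sg <- config$subgroups[[cls]]
    rn <- config$renal

    # --- anthropometrics -------------------------------------------------
    sex <- if (runif(1) < 0.5) "male" else "female"
    age <- min(max(rnorm(1, sg$age_mean, 10), 20), 80)
    weight <- min(max(rlnorm(1, log(78), 0.15), 45), 140)
    height <- min(max(rnorm(1, 1.70, 0.09), 1.45), 1.95)
    scr <- rlnorm(1, log(0.85), 0.18)
    subj <- subject_record(
      subject_id = sprintf("S%03d", i), family_id = sprintf("F%03d", fam_of[i]),
      ethnicity = config$ethnicity, sex = sex, age = age, weight = weight,
      height = height, serum_creatinine = scr, tolerance_class = cls)

    # --- true model parameters -------------------------------------------
    spiller <- runif(1) < sg$spill_prob
    # spillers are the insulin-resistant tail of their subgroup: lower S_I,
    # so the marked hyperglycaemic excursion is attainable
    s_i <- rlnorm(1, log(sg$s_i) + if (spiller) log(0.45) else 0, sg$sdlog)
    p2 <- min(max(rlnorm(1, log(0.02), 0.2), 0.005), 0.1)
    phi_s <- rlnorm(1, log(sg$phi_static), sg$sdlog)
    phi_d <- rlnorm(1, log(sg$phi_dynamic), sg$sdlog)
    t_del <- min(max(rlnorm(1, log(sg$t_delay), 0.15), 4), 40)
    gb <- rlnorm(1, log(sg$gb), sg$gb_sdlog)
    ib <- rlnorm(1, log(sg$ib), 0.2)
    cpb <- rlnorm(1, log(sg$cpb), 0.2)
    peak_target <- if (spiller) {
      runif(1, sg$spill_peak_min, sg$spill_peak_max)
    } else {
      runif(1, sg$peak_min, sg$peak_max)
    }
    peak_target <- max(peak_target, gb + 0.8)  # guarantee an excursion
    theta <- if (cls == "T2D") {
      max(rnorm(1, rn$threshold_t2d_mean, rn$threshold_t2d_sd), 5)
    } else {
      rn$threshold_nont2d
    }
    # oral glucose appearance peaks early (~30-45 min) and tails off; the
    # T2D profile is flatter and more sustained
    ra_rel_base <- if (sg$insulin_shape == "delayed") {
      c(1.0, 1.0, 0.55, 0.20)
    } else {
      c(1.4, 0.9, 0.35, 0.12)
    }
    nh <- length(run$ra_breakpoints) - 1
    ra_rel <- (ra_rel_base[seq_len(nh)] * rlnorm(nh, 0, 0.2))
    kin <- if (inherits(run$cpep_kinetics, "cpeptide_kinetics")) {
      run$cpep_kinetics
    } else {
      population_kinetics(subj, obese_bmi_cutoff = run$obese_bmi_cutoff)
    }

    # draw all measurement noise now so the RNG stream is independent of the
    # ODE/bisection path (determinism contract)
    nz <- list(glucose = rnorm(11), insulin = rnorm(11), cpeptide = rnorm(11))
    urine_draws <- list(vol = rlnorm(1, rn$urine_volume_meanlog, rn$urine_volume_sdlog),
                        floor = rlnorm(1, rn$assay_floor_meanlog, rn$assay_floor_sdlog),
                        frac = rn$cpep_fraction * rlnorm(1, 0, rn$cpep_fraction_sdlog),
                        creat = rlnorm(1, rn$urine_creatinine_meanlog,
                                       rn$urine_creatinine_sdlog),
                        miss = runif(1))

    # --- glucose arm: steer the insulin amplitude to the target peak ------
    total_ra <- run$f_abs * 75 * .mmol_per_g / weight
    ra <- ra_profile(run$ra_breakpoints, ra_rel, total_ra)
    gpar <- list(s_i = s_i, p2 = p2, s_g = run$s_g, v_g = run$v_g)
    t_grid <- c(0, t_post)
    ins_values <- function(amp) c(ib, ib + amp * .insulin_shapes[[sg$insulin_shape]])
    peak_at <- function(amp) {
      sim <- simulate_glucose(gpar, t_grid, ins_values(amp), ib, gb,
                              ra$times, ra$values, t_grid, rtol = 1e-5)
      max(sim$glucose)
    }
    # every subject keeps a post-load insulin excursion of at least amp_min
    # (even insulin-deficient T2D secrete post-load, and a flat insulin input
    # would leave S_I structurally unidentifiable)
    amp_min <- 150
    amp_max <- 8000
    amp <- if (peak_at(amp_min) <= peak_target) {
      amp_min
    } else if (peak_at(amp_max) >= peak_target) {
      amp_max
    } else {
      stats::uniroot(function(a) peak_at(a) - peak_target, c(amp_min, amp_max),
                     tol = 2)$root
    }
    g_true <- simulate_glucose(gpar, t_grid, ins_values(amp), ib, gb,
                               ra$times, ra$values, t_grid,
                               rtol = run$ode_rtol)$glucose
    i_true <- ins_values(amp)

    # --- C-peptide arm, driven by the sampled (piecewise-linear) glucose --
    spar <- secretion_params(phi_static = phi_s, phi_dynamic = phi_d,
                             t_delay = t_del, h_threshold = gb)
    fine <- sort(unique(c(t_grid, seq(0, 210, by = 5))))
    cp_sim <- simulate_secretion_cpeptide(spar, kin, t_grid, g_true, cpb,
                                          fine, rtol = run$ode_rtol)
    cp_true <- cp_sim$cp1[match(t_post, cp_sim$time)]
    flux_auc <- kin$k01 * .trapz(cp_sim$time, cp_sim$cp1)

    # --- sampled series with multiplicative assay noise -------------------
    noisy <- function(x, cv, z) pmax(x * (1 + cv * z), 0.01 * x)
    series <- ogtt_series(
      times = .sampling_times,
      glucose = noisy(c(gb, gb, g_true[-1]), config$noise_cv$glucose, nz$glucose),
      insulin = noisy(c(ib, ib, i_true[-1]), config$noise_cv$insulin, nz$insulin),
      cpeptide = noisy(c(cpb, cpb, cp_true), config$noise_cv$cpeptide, nz$cpeptide))

    # --- urine: renal spill + C-peptide recovery --------------------------
    spill_e <- above_threshold_auc(t_grid, g_true, theta)
    glc_amount <- rn$spill_clearance_l_min * spill_e
    u_glc <- glc_amount / urine_draws$vol + urine_draws$floor
    cp_amount_nmol <- urine_draws$frac * kin$v_c * flux_auc / 1000
    urine <- if (urine_draws$miss < config$missing_urine_frac) {
      NULL
    } else {
      urine_collection(volume_l = urine_draws$vol, glucose_mmol_l = u_glc,
                       cpeptide_nmol_l = cp_amount_nmol / urine_draws$vol,
                       creatinine_mmol_l = urine_draws$creat)
    }

    cohort[[i]] <- list(subject = subj, series = series, urine = urine)
    truth[[i]] <- tibble::tibble(
      subject_id = subj$subject_id, family_id = subj$family_id,
      tolerance_class = cls, s_i = s_i, p2 = p2, phi_static = phi_s,
      phi_dynamic = phi_d, t_delay = t_del, gb = gb, ib = ib, cpb = cpb,
      peak_target = peak_target, peak_attained = max(g_true),
      insulin_amplitude = amp, renal_threshold = theta, spill_auc = spill_e,
      urine_glucose_amount_mmol = glc_amount, k01_flux_auc = flux_auc,
      urine_cpep_fraction = urine_draws$frac, urine_volume_l = urine_draws$vol,
      ra_scale = ra$scale,
      spiller = spiller, k01 = kin$k01, v_c = kin$v_c)
  }
  list(cohort = cohort, truth = dplyr::bind_rows(truth))
}

#' Write a generated cohort (and its truth table) to CSV
#'
#' @param generated Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_generated_cohort <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plasma <- file.path(dir, "cohort_plasma.csv")
  urine <- file.path(dir, "cohort_urine.csv")
  truth <- file.path(dir, "truth.csv")
  write_cohort(generated$cohort, plasma, urine)
  readr::write_csv(generated$truth, truth, progress = FALSE)
  invisible(c(plasma, urine, truth))
}
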