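#' Subject record: anthropometrics and cohort labels
#'
#' Container for one study participant's fixed data: identifiers (subject and
#' family), ethnicity label, sex, age, weight, height, serum creatinine and the
#' WHO glucose-tolerance class.  The tolerance class may be left `NA` and
#' computed later from the OGTT curve with [classify_who()].
#'
#' @param subject_id,family_id Character identifiers.  Family membership is
#'   used by the family-clustered bootstrap in [family_adjusted_cindex()].
#' @param ethnicity Free-text ethnicity label (stratum for correlation tables).
#' @param sex `"male"` or `"female"`.
#' @param age Age in years (> 0).
#' @param weight Body weight in kg (> 0).
#' @param height Height in m (> 0).
#' @param serum_creatinine Serum creatinine in mg/dL (> 0); input to the MDRD
#'   eGFR formula.
#' @param tolerance_class One of `"NGT"`, `"IFG_IGT"`, `"T2D"`, or `NA`.
#'
#' @return An object of class `subject_record` (a named list).
#' @export
subject_record <- function(subject_id, family_id, ethnicity = "unspecified",
                           sex = c("male", "female"), age, weight, height,
                           serum_creatinine, tolerance_class = NA_character_) {
  sex <- match.arg(sex)
  for (nm in c("age", "weight", "height", "serum_creatinine")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      .stop_validation("subject_record: `", nm, "` must be a positive number (subject ",
                       subject_id, ")")
    }
  }
  if (!is.na(tolerance_class) &&
      !tolerance_class %in% c("NGT", "IFG_IGT", "T2D")) {
    .stop_validation("subject_record: unknown tolerance_class '", tolerance_class, "'")
  }
  structure(
    list(subject_id = as.character(subject_id),
         family_id = as.character(family_id),
         ethnicity = as.character(ethnicity), sex = sex,
         age = age, weight = weight, height = height,
         serum_creatinine = serum_creatinine,
         tolerance_class = tolerance_class),
    class = "subject_record")
}

#' OGTT time series of plasma glucose, insulin and C-peptide
#'
#' Time-aligned plasma concentrations around a 75 g oral glucose load.  The
#' reference sampling schedule is -60, -15, 15, 30, 45, 60, 90, 120, 150, 180,
#' 210 min; at least one pre-load (negative-time) sample is required because
#' all basal quantities are read from the configured baseline sample.
#'
#' @param times Sampling times in minutes relative to the load (strictly
#'   increasing, at least one negative).
#' @param glucose Plasma glucose, mmol/L.
#' @param insulin Plasma insulin, pmol/L.
#' @param cpeptide Plasma C-peptide, pmol/L.
#' @param dose_g Glucose load in grams (default 75).
#'
#' @return An object of class `ogtt_series`.
#' @export
ogtt_series <- function(times, glucose, insulin, cpeptide, dose_g = 75) {
  n <- length(times)
  if (length(glucose) != n || length(insulin) != n || length(cpeptide) != n) {
    .stop_validation("ogtt_series: analyte vectors must all have length(times) = ", n)
  }
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    .stop_validation("ogtt_series: times must be finite and strictly increasing")
  }
  if (!any(times < 0)) {
    .stop_validation("ogtt_series: at least one pre-load (negative) time is required")
  }
  for (nm in c("glucose", "insulin", "cpeptide")) {
    v <- get(nm)
    if (any(v < 0, na.rm = TRUE)) {
      .stop_validation("ogtt_series: negative ", nm, " concentration")
    }
  }
  if (!is.numeric(dose_g) || dose_g <= 0) {
    .stop_validation("ogtt_series: dose_g must be > 0")
  }
  structure(
    list(times = as.numeric(times), glucose = as.numeric(glucose),
         insulin = as.numeric(insulin), cpeptide = as.numeric(cpeptide),
         dose_g = dose_g),
    class = "ogtt_series")
}

#' Pooled post-load urine collection
#'
#' One urine void pooled over the post-load window (default 0--210 min):
#' volume plus glucose, C-peptide and creatinine concentrations.  C-peptide is
#' carried in nmol/L at this boundary (the customary urine unit); plasma
#' C-peptide stays in pmol/L.
#'
#' @param volume_l Urine volume, L (> 0).
#' @param glucose_mmol_l Urinary glucose, mmol/L (>= 0).
#' @param cpeptide_nmol_l Urinary C-peptide, nmol/L (>= 0).
#' @param creatinine_mmol_l Urinary creatinine, mmol/L (>= 0).
#' @param window Collection window in minutes post-load, `c(start, end)` with
#'   start >= 0.
#'
#' @return An object of class `urine_collection`.
#' @export
urine_collection <- function(volume_l, glucose_mmol_l, cpeptide_nmol_l,
                             creatinine_mmol_l, window = c(0, 210)) {
  if (!is.numeric(volume_l) || volume_l <= 0) {
    .stop_validation("urine_collection: volume_l must be > 0")
  }
  for (nm in c("glucose_mmol_l", "cpeptide_nmol_l", "creatinine_mmol_l")) {
    v <- get(nm)
    if (!is.na(v) && v < 0) .stop_validation("urine_collection: negative ", nm)
  }
  if (length(window) != 2L || window[1] < 0 || window[2] <= window[1]) {
    .stop_validation("urine_collection: window must be c(start >= 0, end > start)")
  }
  structure(
    list(volume_l = volume_l, glucose_mmol_l = glucose_mmol_l,
         cpeptide_nmol_l = cpeptide_nmol_l,
         creatinine_mmol_l = creatinine_mmol_l, window = window),
    class = "urine_collection")
}

#' Run configuration for the OMM pipeline
#'
#' Central bag of tunable constants.  Defaults are the literature-standard
#' choices for oral-minimal-model work on an 11-point schedule; every value can
#' be overridden.  Units are stated per field.
#'
#' @param baseline_time Minutes; which pre-load sample supplies all basal
#'   values (default -60; the -15 min sample is retained but unused).
#' @param s_g Fractional glucose effectiveness, 1/min (fixed, default 0.025).
#' @param v_g Glucose distribution volume, dL/kg (fixed, default 1.7).
#' @param f_abs Fraction of the oral dose appearing in plasma (fixed, 0.9).
#' @param ra_breakpoints Minutes; nodes of the piecewise-linear oral glucose
#'   appearance profile, `Ra(0) = 0` (default `c(0, 30, 90, 150, 210)`).
#' @param glucose_cv,cpeptide_cv Assumed constant coefficients of variation of
#'   the glucose and C-peptide assays, used as weights in the fits.
#' @param ode_rtol Relative tolerance of the stiff-capable ODE integrator for
#'   forward simulation.
#' @param fit_rtol Relative tolerance used during parameter estimation.
#' @param t_delay_grid Minutes; log-spaced multi-start grid for the secretion
#'   delay T.
#' @param t_delay_bounds Minutes; search interval for T.
#' @param n_multistart Number of optimizer starts for the glucose-model fit.
#' @param p2_prior_meanlog,p2_prior_sdlog Lognormal prior on the remote-insulin
#'   rate `p2` used as a penalty in the glucose fit (MAP estimation).  `p2` is
#'   weakly identified from 11-point OGTT data and, unpenalized, forms a ridge
#'   with S_I (p2 -> 0, S_I -> infinity); the standard remedy is a population
#'   prior.  Defaults: median 0.02 1/min, sd 0.5 on the log scale.  Set
#'   `p2_prior_sdlog = Inf` to disable.
#' @param t_delay_prior_meanlog,t_delay_prior_sdlog Lognormal prior on the
#'   secretion delay T (MAP estimation, as in the original C-peptide minimal
#'   model practice); tempers the T / Phi_dynamic trade-off on noisy 11-point
#'   data.  Defaults: median 12 min, sd 0.5 on the log scale; `Inf` disables.
#' @param threshold_grid Candidate renal glucose thresholds, mmol/L.
#' @param urine_positivity_cutoff Urinary glucose above this concentration
#'   (mmol/L) counts as "glucose present in urine" (default 1.0).
#' @param phi_basal_scale Multiplier applied to the SRb/Gb ratio when reporting
#'   Phi_basal; the normalization behind the published min^-1 magnitude is not
#'   derivable, so the ratio is reported as-is by default (scale 1).
#' @param clip_negative_incremental Clip negative lobes of incremental AUCs
#'   (default `FALSE`: net area).
#' @param cpep_kinetics Either `"population"` (van Cauter formulas) or a
#'   `cpeptide_kinetics` object applied to every subject.
#' @param obese_bmi_cutoff BMI (kg/m^2) at or above which the obese population
#'   kinetic constants are used for non-diabetic subjects (default 30).
#' @param who_cutoffs WHO 1999 classification cutoffs, mmol/L (named list with
#'   `fasting_t2d`, `two_hour_t2d`, `fasting_ifg`, `two_hour_igt`).
#' @param n_boot Bootstrap draws for c-index confidence intervals.
#' @param seed Integer seed used by any stochastic step downstream.
#'
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(baseline_time = -60,
                       s_g = 0.025,
                       v_g = 1.7,
                       f_abs = 0.9,
                       ra_breakpoints = c(0, 30, 90, 150, 210),
                       glucose_cv = 0.02,
                       cpeptide_cv = 0.05,
                       ode_rtol = 1e-8,
                       fit_rtol = 1e-7,
                       t_delay_grid = exp(seq(log(2), log(50), length.out = 8)),
                       t_delay_bounds = c(1, 60),
                       n_multistart = 8,
                       p2_prior_meanlog = log(0.02),
                       p2_prior_sdlog = 0.5,
                       t_delay_prior_meanlog = log(12),
                       t_delay_prior_sdlog = 0.5,
                       threshold_grid = seq(8.5, 11.5, by = 0.5),
                       urine_positivity_cutoff = 1.0,
                       phi_basal_scale = 1,
                       clip_negative_incremental = FALSE,
                       cpep_kinetics = "population",
                       obese_bmi_cutoff = 30,
                       who_cutoffs = list(fasting_t2d = 7.0, two_hour_t2d = 11.1,
                                          fasting_ifg = 6.1, two_hour_igt = 7.8),
                       n_boot = 1000,
                       seed = 1L) {
  if (any(diff(threshold_grid) <= 0)) {
    .stop_validation("run_config: threshold_grid must be strictly increasing")
  }
  if (baseline_time >= 0) {
    .stop_validation("run_config: baseline_time must be a pre-load (negative) time")
  }
  structure(
    list(baseline_time = baseline_time, s_g = s_g, v_g = v_g, f_abs = f_abs,
         ra_breakpoints = ra_breakpoints, glucose_cv = glucose_cv,
         cpeptide_cv = cpeptide_cv, ode_rtol = ode_rtol, fit_rtol = fit_rtol,
         t_delay_grid = t_delay_grid, t_delay_bounds = t_delay_bounds,
         n_multistart = n_multistart,
         p2_prior_meanlog = p2_prior_meanlog, p2_prior_sdlog = p2_prior_sdlog,
         t_delay_prior_meanlog = t_delay_prior_meanlog,
         t_delay_prior_sdlog = t_delay_prior_sdlog,
         threshold_grid = threshold_grid,
         urine_positivity_cutoff = urine_positivity_cutoff,
         phi_basal_scale = phi_basal_scale,
         clip_negative_incremental = clip_negative_incremental,
         cpep_kinetics = cpep_kinetics, obese_bmi_cutoff = obese_bmi_cutoff,
         who_cutoffs = who_cutoffs, n_boot = n_boot, seed = as.integer(seed)),
    class = "run_config")
}

#' WHO 1999 OGTT classification
#'
#' Classifies glucose tolerance from fasting and 2-h plasma glucose.  The
#' cutoffs are the 1999 WHO values: T2D when fasting >= 7.0 mmol/L or 2-h >=
#' 11.1 mmol/L; IFG/IGT when fasting in \[6.1, 7.0) or 2-h in \[7.8, 11.1);
#' NGT otherwise.  Boundaries are inclusive on the diseased side.  Vectorized.
#'
#' @param fasting_glucose Fasting plasma glucose, mmol/L (> 0).
#' @param two_hour_glucose 2-h post-load plasma glucose, mmol/L (> 0).
#' @param cutoffs Cutoff list as in [run_config()].
#'
#' @return Character vector: `"NGT"`, `"IFG_IGT"` or `"T2D"`.
#' @export
#' @examples
#' classify_who(5.0, 6.0)   # NGT
#' classify_who(7.0, 6.0)   # T2D (fasting boundary)
#' classify_who(5.5, 8.0)   # IFG_IGT (2-h in IGT band)
classify_who <- function(fasting_glucose, two_hour_glucose,
                         cutoffs = run_config()$who_cutoffs) {
  if (any(!is.finite(fasting_glucose)) || any(!is.finite(two_hour_glucose)) ||
      any(fasting_glucose <= 0) || any(two_hour_glucose <= 0)) {
    .stop_validation("classify_who: glucose values must be positive")
  }
  t2d <- fasting_glucose >= cutoffs$fasting_t2d |
    two_hour_glucose >= cutoffs$two_hour_t2d
  ifg_igt <- !t2d & (fasting_glucose >= cutoffs$fasting_ifg |
                       two_hour_glucose >= cutoffs$two_hour_igt)
  out <- rep("NGT", length(t2d))
  out[ifg_igt] <- "IFG_IGT"
  out[t2d] <- "T2D"
  out
}

#' Basal (baseline) values of an OGTT series
#'
#' Reads basal glucose, insulin and C-peptide from the configured baseline
#' sample (default -60 min).
#'
#' @param series An [ogtt_series()].
#' @param baseline_time Which sampling time to use (must be present).
#' @return Named list `gb`, `ib`, `cpb`.
#' @export
basal_values <- function(series, baseline_time = -60) {
  i <- match(baseline_time, series$times)
  if (is.na(i)) {
    .stop_validation("basal_values: baseline time ", baseline_time,
                     " is not in the sampling schedule")
  }
  list(gb = series$glucose[i], ib = series$insulin[i], cpb = series$cpeptide[i])
}

# Post-load view of a series: times > 0, with the basal value prepended at
# t = 0 (the load instant, where concentrations still equal basal).
.postload <- function(series, baseline_time = -60) {
  b <- basal_values(series, baseline_time)
  keep <- series$times > 0
  list(times = c(0, series$times[keep]),
       glucose = c(b$gb, series$glucose[keep]),
       insulin = c(b$ib, series$insulin[keep]),
       cpeptide = c(b$cpb, series$cpeptide[keep]),
       gb = b$gb, ib = b$ib, cpb = b$cpb)
}
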