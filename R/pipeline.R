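#' Fit both minimal models and derive all indices for one subject
#'
#' Runs the glucose-model and C-peptide-model fits, then assembles the full
#' per-subject index row: incremental AUCs, Phi indices, S_I, disposition
#' indices, the k01-flux AUC (from the fitted secretion model on a 1-min
#' grid), total glucose AUC, renal glucose clearance, eGFR and the
#' creatinine-adjusted urine markers.  A failed fit marks the dependent
#' indices missing (never silently zero).
#'
#' @param rec Per-subject record: list with `subject`, `series`, `urine`.
#' @param config A [run_config()].
#' @return One-row tibble.
#' @export
fit_subject <- function(rec, config = run_config()) {
  s <- rec$subject
  ser <- rec$series
  p <- .postload(ser, config$baseline_time)
  post <- ser$times > 0

  kin <- if (inherits(config$cpep_kinetics, "cpeptide_kinetics")) {
    config$cpep_kinetics
  } else {
    population_kinetics(s, obese_bmi_cutoff = config$obese_bmi_cutoff)
  }

  gfit <- tryCatch(fit_glucose(ser, s$weight, config), error = function(e) NULL)
  sfit <- tryCatch(fit_secretion(ser, kin, config), error = function(e) NULL)
  g_ok <- !is.null(gfit) && gfit$converged
  s_ok <- !is.null(sfit) && sfit$converged

  s_i <- if (g_ok) gfit$params$s_i else NA_real_
  phi_b <- if (s_ok) sfit$phi_basal else NA_real_
  phi_s <- if (s_ok) sfit$params$phi_static else NA_real_
  phi_d <- if (s_ok) sfit$params$phi_dynamic else NA_real_
  t_del <- if (s_ok) sfit$params$t_delay else NA_real_
  phi_o <- if (s_ok) {
    phi_oral(sfit$params, p$times, p$glucose, p$gb)
  } else {
    NA_real_
  }
  di <- disposition_indices(phi_b, phi_s, phi_d, phi_o, s_i)

  flux <- if (s_ok) {
    fine <- seq(0, 210, by = 5)
    cp_hat <- simulate_secretion_cpeptide(sfit$params, kin, p$times, p$glucose,
                                          p$cpb, fine, rtol = config$ode_rtol)
    k01_flux_auc(kin, cp_hat$time, cp_hat$cp1, c(0, 210))
  } else {
    NA_real_
  }

  tot_g_auc <- total_auc(p$times, p$glucose, c(0, 210))
  clearance <- renal_glucose_clearance(rec$urine, tot_g_auc)
  u <- rec$urine
  tibble::tibble(
    subject_id = s$subject_id, family_id = s$family_id,
    ethnicity = s$ethnicity, tolerance_class = s$tolerance_class,
    gb = p$gb, ib = p$ib, cpb = p$cpb,
    incr_auc_glucose = incremental_auc(ser$times[post], ser$glucose[post],
                                       p$gb,
                                       clip_negative = config$clip_negative_incremental),
    incr_auc_insulin = incremental_auc(ser$times[post], ser$insulin[post],
                                       p$ib,
                                       clip_negative = config$clip_negative_incremental),
    incr_auc_cpeptide = incremental_auc(ser$times[post], ser$cpeptide[post],
                                        p$cpb,
                                        clip_negative = config$clip_negative_incremental),
    phi_basal = phi_b, phi_static = phi_s, phi_dynamic = phi_d,
    phi_oral = phi_o, t_delay = t_del, s_i = s_i,
    di_basal = di$di_basal, di_static = di$di_static,
    di_dynamic = di$di_dynamic, di_oral = di$di_oral,
    k01_flux_auc = flux, total_glucose_auc = tot_g_auc,
    urine_glucose = if (!is.null(u)) u$glucose_mmol_l else NA_real_,
    urine_cpeptide = if (!is.null(u)) u$cpeptide_nmol_l else NA_real_,
    urine_glucose_amount_mmol = clearance$amount_mmol,
    renal_clearance_pct = clearance$pct,
    urine_glucose_creatinine_ratio =
      if (!is.null(u)) creatinine_adjust(u$glucose_mmol_l, u$creatinine_mmol_l)
      else NA_real_,
    urine_cpeptide_creatinine_ratio =
      if (!is.null(u)) creatinine_adjust(u$cpeptide_nmol_l, u$creatinine_mmol_l)
      else NA_real_,
    egfr = egfr_mdrd(s$serum_creatinine, s$age, s$sex,
                     black = identical(tolower(s$ethnicity), "black")),
    glucose_fit_converged = g_ok, secretion_fit_converged = s_ok)
}

#' Fit a whole cohort
#'
#' Maps [fit_subject()] over the cohort; fit failures are reported in the
#' convergence flags, never fatal.
#'
#' @param cohort List of per-subject records.
#' @param config A [run_config()].
#' @param progress Print one line per subject (default `FALSE`).
#' @return Tibble, one row per subject.
#' @export
fit_cohort <- function(cohort, config = run_config(), progress = FALSE) {
  rows <- lapply(seq_along(cohort), function(i) {
    if (progress) {
      message("fitting subject ", cohort[[i]]$subject$subject_id,
              " (", i, "/", length(cohort), ")")
    }
    fit_subject(cohort[[i]], config)
  })
  dplyr::bind_rows(rows)
}

#' ROC c-indices of the urine markers for the three status contrasts
#'
#' Computes [family_adjusted_cindex()] for urinary glucose and C-peptide
#' (unadjusted and creatinine-adjusted) against the three contrasts: T2D vs
#' the rest, non-NGT (IFG/IGT + T2D) vs NGT, and IFG/IGT vs NGT.
#'
#' @param indices Per-subject indices tibble from [fit_cohort()].
#' @param config A [run_config()] (bootstrap draws and seed).
#' @return Tibble: `marker`, `contrast`, `cindex`, `ci_lo`, `ci_hi`,
#'   `n_case`, `n_control`, `reason`.
#' @export
cindex_table <- function(indices, config = run_config()) {
  contrasts <- list(
    t2d_vs_rest = function(cl) cl == "T2D",
    ngt_vs_rest = function(cl) cl != "NGT",
    ngt_vs_ifg_igt = function(cl) ifelse(cl == "T2D", NA, cl == "IFG_IGT"))
  markers <- c("urine_glucose", "urine_glucose_creatinine_ratio",
               "urine_cpeptide", "urine_cpeptide_creatinine_ratio")
  grid <- tidyr::expand_grid(marker = markers, contrast = names(contrasts))
  rows <- purrr::pmap(grid, function(marker, contrast) {
    if (nrow(indices) == 0) {
      return(tibble::tibble(cindex = NA_real_, ci_lo = NA_real_,
                            ci_hi = NA_real_, n_case = 0L, n_control = 0L,
                            reason = "empty_cohort"))
    }
    status <- contrasts[[contrast]](indices$tolerance_class)
    res <- family_adjusted_cindex(indices[[marker]], status,
                                  indices$family_id, n_boot = config$n_boot,
                                  seed = config$seed)
    tibble::tibble(cindex = res$cindex, ci_lo = res$ci[1], ci_hi = res$ci[2],
                   n_case = res$n_case, n_control = res$n_control,
                   reason = res$reason)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(rows))
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> fit -> threshold -> report, fully deterministic for a fixed
#' configuration seed.  When `out_dir` is given, all tables are written as
#' CSV (`cohort_plasma.csv`, `cohort_urine.csv`, `truth.csv`, `indices.csv`,
#' `threshold_table.csv`, `threshold_estimates.csv`, `spearman.csv`,
#' `cindex.csv`).
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional output directory.
#' @param progress Passed to [fit_cohort()].
#' @return List with `cohort`, `truth`, `indices`, `threshold`, `spearman`,
#'   `cindex`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         progress = FALSE) {
  gen <- generate_cohort(config)
  indices <- fit_cohort(gen$cohort, config$run, progress = progress)
  thr <- estimate_threshold(gen$cohort, config$run)
  spear <- spearman_table(indices)
  cidx <- cindex_table(indices, config$run)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_generated_cohort(gen, out_dir)
    readr::write_csv(indices, file.path(out_dir, "indices.csv"), progress = FALSE)
    readr::write_csv(thr$table, file.path(out_dir, "threshold_table.csv"),
                     progress = FALSE)
    readr::write_csv(thr$estimates, file.path(out_dir, "threshold_estimates.csv"),
                     progress = FALSE)
    readr::write_csv(spear, file.path(out_dir, "spearman.csv"), progress = FALSE)
    readr::write_csv(cidx, file.path(out_dir, "cindex.csv"), progress = FALSE)
  }
  list(cohort = gen$cohort, truth = gen$truth, indices = indices,
       threshold = thr, spearman = spear, cindex = cidx)
}
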