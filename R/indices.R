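#' Incremental (above-basal) trapezoidal AUC
#'
#' Trapezoidal integral of `value - baseline` over the window.  Negative
#' lobes (values below basal) are included by default — the basal subtraction
#' yields a *net* incremental area; set `clip_negative = TRUE` to clip the
#' integrand at zero instead.
#'
#' @param times,values Sampled curve.
#' @param baseline_value Basal concentration to subtract.
#' @param window `c(start, end)`, must lie within the sampled span.
#' @param clip_negative Clip negative lobes (default `FALSE`).
#' @return AUC in (analyte unit) x min.
#' @export
#' @examples
#' incremental_auc(c(0, 10, 20), c(5, 7, 5), 5, c(0, 20))  # 20
incremental_auc <- function(times, values, baseline_value,
                            window = range(times), clip_negative = FALSE) {
  if (window[1] < min(times) || window[2] > max(times) || window[1] >= window[2]) {
    .stop_validation("incremental_auc: window must lie within the sampled span")
  }
  grid <- sort(unique(c(window, times[times >= window[1] & times <= window[2]])))
  vals <- stats::approx(times, values, xout = grid)$y - baseline_value
  if (clip_negative) {
    return(above_threshold_auc(grid, vals + baseline_value, baseline_value))
  }
  .trapz(grid, vals)
}

#' Total (baseline-inclusive) trapezoidal AUC
#'
#' Plain trapezoidal integral over the window, no basal subtraction; the
#' denominator of the renal glucose clearance ratio.
#'
#' @inheritParams incremental_auc
#' @return AUC in (analyte unit) x min.
#' @export
total_auc <- function(times, values, window = range(times)) {
  if (window[1] < min(times) || window[2] > max(times) || window[1] >= window[2]) {
    .stop_validation("total_auc: window must lie within the sampled span")
  }
  grid <- sort(unique(c(window, times[times >= window[1] & times <= window[2]])))
  .trapz(grid, stats::approx(times, values, xout = grid)$y)
}

#' Disposition indices
#'
#' Each disposition index is the exact product of a beta-cell responsivity
#' index and insulin sensitivity: `DI_x = Phi_x * S_I`.  With Phi on the
#' 1e-9 scales and S_I in 1e-5 dL/kg/min per pM the products are on the
#' published 1e-14 DI scales.  Missing factors propagate to `NA`.
#'
#' @param phi_basal,phi_static,phi_dynamic,phi_oral Responsivity indices.
#' @param s_i Insulin sensitivity.
#' @return Named list `di_basal`, `di_static`, `di_dynamic`, `di_oral`.
#' @export
disposition_indices <- function(phi_basal, phi_static, phi_dynamic, phi_oral,
                                s_i) {
  list(di_basal = phi_basal * s_i, di_static = phi_static * s_i,
       di_dynamic = phi_dynamic * s_i, di_oral = phi_oral * s_i)
}

#' Renal glucose clearance during the OGTT
#'
#' The absolute amount of glucose recovered in the pooled post-load urine
#' (concentration x volume, mmol) and that amount as a percentage of the
#' total plasma glucose AUC over 0--210 min.  The percentage is the published
#' ratio taken at face value (mmol over mmol min/L); it is a relative-loss
#' summary, not a dimensionally conventional clearance.
#'
#' @param urine A [urine_collection()] (or `NULL` for missing).
#' @param total_plasma_glucose_auc Total glucose AUC, mmol min/L (> 0).
#' @return List `amount_mmol`, `pct`; both `NA` when urine is missing or the
#'   AUC is not positive.
#' @export
renal_glucose_clearance <- function(urine, total_plasma_glucose_auc) {
  if (is.null(urine) || !is.finite(total_plasma_glucose_auc) ||
      total_plasma_glucose_auc <= 0) {
    return(list(amount_mmol = NA_real_, pct = NA_real_))
  }
  amount <- urine$glucose_mmol_l * urine$volume_l
  list(amount_mmol = amount, pct = 100 * amount / total_plasma_glucose_auc)
}

#' Estimated GFR by the 4-variable MDRD formula
#'
#' `175 * Scr^-1.154 * age^-0.203 * 0.742^[female] * 1.212^[black]`.
#'
#' @param serum_creatinine Serum creatinine, mg/dL (> 0).
#' @param age Age, years (> 0).
#' @param sex `"male"` or `"female"`.
#' @param black Ancestry flag for the 1.212 factor (default `FALSE`).
#' @return eGFR in mL/min/1.73 m^2.
#' @export
egfr_mdrd <- function(serum_creatinine, age, sex = c("male", "female"),
                      black = FALSE) {
  sex <- match.arg(sex)
  if (any(serum_creatinine <= 0) || any(age <= 0)) {
    .stop_validation("egfr_mdrd: creatinine and age must be positive")
  }
  175 * serum_creatinine^-1.154 * age^-0.203 *
    ifelse(sex == "female", 0.742, 1) * ifelse(black, 1.212, 1)
}

#' Creatinine-adjusted urine marker
#'
#' Marker concentration divided by urinary creatinine; `NA` when creatinine
#' is zero or missing.
#'
#' @param marker_conc Marker concentration.
#' @param creatinine_conc Urinary creatinine, same-volume concentration.
#' @return Unitless ratio.
#' @export
creatinine_adjust <- function(marker_conc, creatinine_conc) {
  ifelse(is.na(creatinine_conc) | creatinine_conc <= 0,
         NA_real_, marker_conc / creatinine_conc)
}
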