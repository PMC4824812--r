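#' Two-compartment C-peptide kinetic parameters
#'
#' Rate constants of the two-compartment C-peptide model: `k01` (irreversible
#' loss from the central compartment, the flux compared with urinary
#' C-peptide), `k21`/`k12` (central-to-peripheral and back transfer) and the
#' central distribution volume `v_c`.  The transfer matrix must have two
#' distinct negative real eigenvalues, which is checked on construction.
#'
#' @param k01,k12,k21 Rate constants, 1/min (> 0).
#' @param v_c Central distribution volume, L (> 0).
#' @return An object of class `cpeptide_kinetics`.
#' @export
cpeptide_kinetics <- function(k01, k12, k21, v_c) {
  for (nm in c("k01", "k12", "k21", "v_c")) {
    v <- get(nm)
    if (!is.numeric(v) || !is.finite(v) || v <= 0) {
      .stop_validation("cpeptide_kinetics: `", nm, "` must be a positive number")
    }
  }
  ev <- .cpep_eigen(k01, k12, k21)
  if (any(ev >= 0) || abs(diff(ev)) < 1e-12 * max(abs(ev))) {
    .stop_validation("cpeptide_kinetics: transfer matrix must have two distinct ",
                     "negative real eigenvalues")
  }
  structure(list(k01 = k01, k12 = k12, k21 = k21, v_c = v_c),
            class = "cpeptide_kinetics")
}

# Eigenvalues of [[-(k01+k21), k12], [k21, -k12]] (always real for positive
# rates; returned sorted, most negative first).
.cpep_eigen <- function(k01, k12, k21) {
  tr <- -(k01 + k21 + k12)
  det <- k01 * k12
  disc <- sqrt(tr^2 - 4 * det)
  sort(c((tr - disc) / 2, (tr + disc) / 2))
}

#' Convert a bi-exponential decay to compartmental rate constants
#'
#' The impulse response of the central compartment is the two-exponential
#' curve `F exp(-ln2 t / t_short) + (1 - F) exp(-ln2 t / t_long)`.  Given the
#' short-phase fraction and the two half-lives, this returns the unique
#' `(k01, k12, k21)` with that impulse response.  [compartments_to_biexponential()]
#' is its exact inverse.
#'
#' @param fraction_short Fraction of the short phase, in (0, 1).
#' @param halflife_short,halflife_long Half-lives, min, with
#'   `0 < halflife_short < halflife_long`.
#' @param v_c Central distribution volume, L.
#' @return A [cpeptide_kinetics()] object.
#' @export
biexponential_to_compartments <- function(fraction_short, halflife_short,
                                          halflife_long, v_c) {
  if (!(fraction_short > 0 && fraction_short < 1)) {
    .stop_validation("biexponential_to_compartments: fraction_short must be in (0, 1)")
  }
  if (!(halflife_short > 0 && halflife_short < halflife_long)) {
    .stop_validation("biexponential_to_compartments: need 0 < halflife_short < halflife_long")
  }
  a <- log(2) / halflife_short   # fast eigen-rate
  b <- log(2) / halflife_long    # slow eigen-rate
  f <- fraction_short
  # From CP1'(0)/CP1(0) = -(k01+k21) = -(f a + (1-f) b),
  # trace a + b = k01 + k21 + k12 and determinant a b = k01 k12.
  k12 <- (1 - f) * a + f * b
  k01 <- a * b / k12
  k21 <- a + b - k12 - k01
  cpeptide_kinetics(k01 = k01, k12 = k12, k21 = k21, v_c = v_c)
}

#' @rdname biexponential_to_compartments
#' @param kinetics A [cpeptide_kinetics()] object.
#' @return For `compartments_to_biexponential()`: a named list
#'   `fraction_short`, `halflife_short`, `halflife_long`.
#' @export
compartments_to_biexponential <- function(kinetics) {
  ev <- .cpep_eigen(kinetics$k01, kinetics$k12, kinetics$k21)
  a <- -ev[1]; b <- -ev[2]          # a > b > 0
  f <- (kinetics$k01 + kinetics$k21 - b) / (a - b)
  list(fraction_short = f, halflife_short = log(2) / a,
       halflife_long = log(2) / b)
}

# Van Cauter population constants for C-peptide kinetics, by subject class.
# Transcribed from the standard population-parameter tables of the cited
# reference (short-phase fraction, short and long half-lives in min); the
# central volume scales linearly with body surface area.  All constants are
# overridable through `run_config(cpep_kinetics = <explicit kinetics>)` and no
# downstream computation depends on this transcription.
.van_cauter_constants <- list(
  normal = list(fraction_short = 0.76, halflife_short = 4.95, halflife_long = 29.2),
  obese  = list(fraction_short = 0.78, halflife_short = 4.55, halflife_long = 33.0),
  t2d    = list(fraction_short = 0.78, halflife_short = 4.52, halflife_long = 35.0),
  v_c_bsa = list(slope = 1.92, intercept = 0.64)  # L per m^2, L
)

#' Body surface area (DuBois)
#'
#' @param weight Body weight, kg.
#' @param height Height, m.
#' @return BSA in m^2.
#' @export
body_surface_area <- function(weight, height) {
  0.007184 * weight^0.425 * (height * 100)^0.725
}

#' Population C-peptide kinetics (van Cauter formulas)
#'
#' Returns per-subject rate constants from the population bi-exponential
#' parameters: the long half-life and short-phase fraction depend on the
#' subject class (normal / obese / type 2 diabetic), and the central volume is
#' linear in body surface area.  Obesity is decided by BMI at
#' `obese_bmi_cutoff` for non-diabetic subjects.
#'
#' @param subject A [subject_record()].
#' @param tolerance_class Optional override of the subject's stored class.
#' @param obese_bmi_cutoff BMI cutoff, kg/m^2 (default 30).
#' @return A [cpeptide_kinetics()] object.
#' @export
population_kinetics <- function(subject, tolerance_class = NULL,
                                obese_bmi_cutoff = 30) {
  cls <- tolerance_class %||% subject$tolerance_class
  bmi <- subject$weight / subject$height^2
  key <- if (!is.na(cls) && cls == "T2D") {
    "t2d"
  } else if (bmi >= obese_bmi_cutoff) {
    "obese"
  } else {
    "normal"
  }
  k <- .van_cauter_constants[[key]]
  vb <- .van_cauter_constants$v_c_bsa
  v_c <- vb$slope * body_surface_area(subject$weight, subject$height) + vb$intercept
  biexponential_to_compartments(k$fraction_short, k$halflife_short,
                                k$halflife_long, v_c)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Forward-simulate the two-compartment C-peptide model
#'
#' Solves `dCP1/dt = -(k01 + k21) CP1 + k12 CP2 + SR(t)` and
#' `dCP2/dt = k21 CP1 - k12 CP2` with a stiff-capable adaptive integrator and
#' returns the central concentration at the requested times.
#'
#' @param kinetics A [cpeptide_kinetics()] object.
#' @param secretion Function of time returning the secretion rate SR(t) in
#'   (pmol/L)/min (already normalized by the central volume).
#' @param init Named numeric `c(cp1 = , cp2 = )`, pmol/L.
#' @param times Output times, min.
#' @param rtol Relative tolerance (default 1e-8).
#' @return A tibble with columns `time`, `cp1`, `cp2`.
#' @export
simulate_cpeptide <- function(kinetics, secretion, init, times, rtol = 1e-8) {
  stopifnot(all(c("cp1", "cp2") %in% names(init)))
  k <- kinetics
  rhs <- function(t, y, parms) {
    sr <- secretion(t)
    list(c(-(k$k01 + k$k21) * y[1] + k$k12 * y[2] + sr,
           k$k21 * y[1] - k$k12 * y[2]))
  }
  t0 <- min(times)
  out_times <- sort(unique(c(t0, times)))
  sol <- deSolve::lsoda(y = c(cp1 = init[["cp1"]], cp2 = init[["cp2"]]),
                        times = out_times, func = rhs, parms = NULL,
                        rtol = rtol, atol = rtol * 100)
  if (attr(sol, "istate")[1] < 0) {
    rlang::abort(paste0("simulate_cpeptide: ODE solver failed (istate ",
                        attr(sol, "istate")[1], ", ", nrow(sol), " steps)"),
                 class = "ommurine_numeric_error")
  }
  sol <- as.data.frame(sol)
  idx <- match(times, sol$time)
  tibble::tibble(time = times, cp1 = sol$cp1[idx], cp2 = sol$cp2[idx])
}

#' AUC of the irreversible C-peptide loss flux (k01 flux)
#'
#' Integrates `k01 * CP1(t)` over the window by the trapezoidal rule on the
#' supplied trajectory grid; this is the model-based amount of C-peptide (per
#' litre of distribution volume) irreversibly removed from the central
#' compartment, the quantity compared against the urinary C-peptide recovery.
#'
#' @param kinetics A [cpeptide_kinetics()] object.
#' @param times,cp1 Trajectory of the central concentration, min and pmol/L.
#' @param window `c(start, end)` in min; must lie within the trajectory.
#' @return Flux AUC in pmol min/L.
#' @export
k01_flux_auc <- function(kinetics, times, cp1, window = c(0, 210)) {
  if (window[1] < min(times) || window[2] > max(times) || window[1] >= window[2]) {
    .stop_validation("k01_flux_auc: window must lie within the trajectory span")
  }
  grid <- sort(unique(c(window, times[times >= window[1] & times <= window[2]])))
  vals <- stats::approx(times, cp1, xout = grid)$y
  kinetics$k01 * .trapz(grid, vals)
}
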