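#' Oral glucose appearance profile
#'
#' The rate of appearance of the oral glucose dose, `Ra(t)` in mmol/kg/min,
#' is piecewise linear over fixed breakpoints with `Ra(0) = 0`.  Heights are
#' supplied as a shape (relative, non-negative) and rescaled so that the
#' trapezoidal integral equals the target amount exactly — the total
#' appearance constraint `Int Ra dt = f_abs * dose / weight` holds by
#' construction on every profile the fitter can produce.
#'
#' @param breakpoints Node times, min, starting at 0.
#' @param rel_heights Relative heights at `breakpoints[-1]` (>= 0, not all 0).
#' @param total Target integral, mmol/kg.
#' @return List `times`, `values` (mmol/kg/min), `scale`.
#' @export
ra_profile <- function(breakpoints, rel_heights, total) {
  if (length(rel_heights) != length(breakpoints) - 1) {
    .stop_validation("ra_profile: need one height per breakpoint after t = 0")
  }
  if (any(rel_heights < 0) || all(rel_heights == 0)) {
    .stop_validation("ra_profile: heights must be >= 0 with at least one > 0")
  }
  raw <- .trapz(breakpoints, c(0, rel_heights))
  s <- total / raw
  list(times = breakpoints, values = c(0, rel_heights) * s, scale = s)
}

#' Forward-simulate the oral glucose minimal model
#'
#' Solves `dG/dt = -(S_G + X) G + S_G Gb + Ra(t)/V` and
#' `dX/dt = -p2 (X - (S_I/V_G) (I(t) - Ib))`, with glucose in mmol/L, insulin
#' in pmol/L and `Ra` in mmol/kg/min.  `S_I` is carried in the printed unit
#' convention (1e-5 dL/kg/min per pM, the volume-multiplied form), so the
#' fractional action on glucose is `S_I / V_G` in 1/min per pM.
#'
#' @param params List with `s_i` (1e-5 dL/kg/min per pM), `p2` (1/min),
#'   `s_g` (1/min) and `v_g` (dL/kg).
#' @param insulin_times,insulin_values Sampled insulin input, min and pmol/L.
#' @param ib Basal insulin, pmol/L.
#' @param gb Basal glucose, mmol/L.
#' @param ra_times,ra_values Appearance profile nodes, min and mmol/kg/min.
#' @param times Output times, min.
#' @param rtol ODE relative tolerance.
#' @param input_method Interpolation of the insulin and Ra inputs,
#'   `"linear"` (default) or `"constant"` (left-continuous steps).
#' @param g0,x0 Initial state (defaults: basal glucose, zero remote insulin).
#' @param t0 Time at which the initial state applies (default 0, the load).
#' @return Tibble with `time`, `glucose`, `x`.
#' @export
simulate_glucose <- function(params, insulin_times, insulin_values, ib, gb,
                             ra_times, ra_values, times, rtol = 1e-8,
                             input_method = c("linear", "constant"),
                             g0 = gb, x0 = 0, t0 = 0) {
  input_method <- match.arg(input_method)
  ifun <- stats::approxfun(insulin_times, insulin_values, rule = 2,
                           method = input_method, f = 0)
  rfun <- stats::approxfun(ra_times, ra_values, rule = 2,
                           method = input_method, f = 0)
  si_frac <- params$s_i * 1e-5 / params$v_g     # 1/min per pM
  v_l <- params$v_g / 10                        # L/kg
  s_g <- params$s_g
  p2 <- params$p2
  rhs <- function(t, s, parms) {
    list(c(-(s_g + s[2]) * s[1] + s_g * gb + rfun(t) / v_l,
           -p2 * (s[2] - si_frac * (ifun(t) - ib))))
  }
  if (t0 > min(times)) {
    .stop_validation("simulate_glucose: t0 must not exceed the first output time")
  }
  out_times <- sort(unique(c(t0, times)))
  sol <- deSolve::lsoda(c(g = g0, x = x0), out_times, rhs, parms = NULL,
                        rtol = rtol, atol = rtol * 10)
  if (attr(sol, "istate")[1] < 0) {
    rlang::abort("simulate_glucose: ODE solver failed",
                 class = "ommurine_numeric_error")
  }
  sol <- as.data.frame(sol)
  idx <- match(times, sol$time)
  tibble::tibble(time = times, glucose = sol$g[idx], x = sol$x[idx])
}

# mmol per gram of glucose (molar mass 180.156 g/mol)
.mmol_per_g <- 1000 / 180.156

# Remote insulin action X(t) for piecewise-linear insulin: exact
# exponential-plus-affine recursion of dX/dt = -p2 (X - si_frac (I - Ib)),
# returned as a function of t (X(0) = 0).
.remote_insulin_action <- function(insulin_times, insulin_values, ib,
                                   si_frac, p2) {
  u <- si_frac * (insulin_values - ib)
  tt <- insulin_times
  n <- length(tt)
  xk <- numeric(n)
  m <- c(diff(u) / diff(tt), 0)
  for (i in seq_len(n - 1)) {
    dt <- tt[i + 1] - tt[i]
    xp0 <- u[i] - m[i] / p2
    xp1 <- u[i + 1] - m[i] / p2
    xk[i + 1] <- xp1 + (xk[i] - xp0) * exp(-p2 * dt)
  }
  function(t) {
    i <- findInterval(t, tt, all.inside = TRUE)
    s <- t - tt[i]
    xp0 <- u[i] - m[i] / p2
    (u[i] + m[i] * s - m[i] / p2) + (xk[i] - xp0) * exp(-p2 * s)
  }
}

# Superposition of the glucose equation for fixed insulin action: one
# augmented ODE solve returns the homogeneous response (Ra = 0) and the
# response to each triangular Ra basis element (unit height at one
# breakpoint), all sharing the time-varying clearance S_G + X(t).
.glucose_basis <- function(xfun, gb, s_g, v_l, bp, times, rtol) {
  n_h <- length(bp) - 1
  # in segment [bp[i], bp[i+1]] only the hat functions peaked at its two ends
  # are non-zero: basis i rises with the within-segment fraction, basis i-1
  # falls with it
  bvals <- function(t) {
    b <- numeric(n_h)
    i <- findInterval(t, bp, all.inside = TRUE)
    frac <- (t - bp[i]) / (bp[i + 1] - bp[i])
    b[i] <- frac
    if (i > 1) b[i - 1] <- 1 - frac
    b
  }
  rhs <- function(t, s, parms) {
    cl <- s_g + xfun(t)
    list(c(-cl * s[1] + s_g * gb,
           -cl * s[-1] + bvals(t) / v_l))
  }
  out_times <- sort(unique(c(0, times)))
  sol <- deSolve::lsoda(c(gb, numeric(n_h)), out_times, rhs, parms = NULL,
                        rtol = rtol, atol = rtol * 10)
  sol <- as.data.frame(sol)
  idx <- match(times, sol[, 1])
  list(g0 = sol[idx, 2], L = as.matrix(sol[idx, 3:(2 + n_h), drop = FALSE]))
}

# Equality-constrained non-negative weighted least squares for the Ra
# heights: minimize ||sqrt(w)(d - L h)||^2 subject to c'h = total, h >= 0
# (KKT solve with a small active set).  The appearance constraint therefore
# holds exactly on every candidate.
.ra_heights_cls <- function(L, d, w, cvec, total) {
  n <- ncol(L)
  solve_free <- function(free) {
    Lf <- L[, free, drop = FALSE]
    A <- crossprod(Lf * w, Lf)
    K <- rbind(cbind(A, cvec[free]), c(cvec[free], 0))
    rhs <- c(crossprod(Lf * w, d), total)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    h <- numeric(n)
    h[free] <- sol[seq_along(free)]
    h
  }
  free <- seq_len(n)
  for (iter in seq_len(n)) {
    h <- solve_free(free)
    if (is.null(h)) return(NULL)
    if (all(h[free] >= -1e-12)) {
      h[h < 0] <- 0
      return(h)
    }
    free <- free[h[free] > 0]
    if (length(free) == 0) return(NULL)
  }
  NULL
}

#' Fit the oral glucose minimal model
#'
#' Weighted nonlinear least squares of simulated against observed post-load
#' plasma glucose (constant-CV weights).  `S_G`, `V_G` and `f_abs` are fixed
#' to the configured constants; `S_I`, `p2` and the appearance shape are
#' estimated subject to the exact total-appearance constraint
#' `Int Ra dt = f_abs * dose / weight`.  For fixed `(S_I, p2)` the model is
#' linear in the Ra heights, so the heights are profiled out by an
#' equality-constrained non-negative linear solve (one Ra degree of freedom
#' is eliminated by the constraint, which therefore holds exactly on every
#' candidate the optimizer can visit); the remaining 2-D weighted SSE surface
#' is minimized by multi-start Nelder-Mead.
#'
#' @param series An [ogtt_series()] with at least 8 post-load samples.
#' @param weight Body weight, kg.
#' @param config A [run_config()].
#' @return An object of class `glucose_fit`: list with `params` (`s_i` in
#'   1e-5 dL/kg/min per pM, `p2`, fixed constants), `ra` (profile nodes,
#'   mmol/kg/min), `total_ra` (mmol/kg), `appearance_rel_err`, `residuals`,
#'   `sse`, `converged`, `n_starts_used`.
#' @export
fit_glucose <- function(series, weight, config = run_config()) {
  p <- .postload(series, config$baseline_time)
  obs_t <- p$times[p$times > 0]
  obs_g <- p$glucose[p$times > 0]
  if (length(obs_t) < 8) {
    .stop_validation("fit_glucose: need >= 8 post-load samples, got ",
                     length(obs_t))
  }
  total_ra <- config$f_abs * series$dose_g * .mmol_per_g / weight
  bp <- config$ra_breakpoints
  n_h <- length(bp) - 1
  # trapezoidal quadrature weights of the heights (Ra(0) = 0 node dropped)
  cvec <- vapply(seq_len(n_h), function(j) {
    heights <- numeric(n_h)
    heights[j] <- 1
    .trapz(bp, c(0, heights))
  }, numeric(1))
  w <- 1 / (config$glucose_cv * pmax(obs_g, 1e-6))^2
  v_l <- config$v_g / 10
  p2_bounds <- c(1e-3, 0.5)

  eval_profile <- function(s_i, p2) {
    xfun <- .remote_insulin_action(p$times, p$insulin, p$ib,
                                   s_i * 1e-5 / config$v_g, p2)
    bas <- .glucose_basis(xfun, p$gb, config$s_g, v_l, bp, obs_t,
                          config$fit_rtol)
    h <- .ra_heights_cls(bas$L, obs_g - bas$g0, w, cvec, total_ra)
    if (is.null(h)) return(NULL)
    res <- obs_g - bas$g0 - drop(bas$L %*% h)
    list(h = h, residuals = res, sse = sum(w * res^2))
  }
  # lognormal MAP penalty on p2 (disabled when the prior sd is infinite)
  p2_penalty <- function(p2) {
    if (!is.finite(config$p2_prior_sdlog)) return(0)
    ((log(p2) - config$p2_prior_meanlog) / config$p2_prior_sdlog)^2
  }
  # parametrization keeps s_i >= 0 and p2 within bounds, smoothly
  sse_of <- function(par) {
    s_i <- par[1]^2
    p2 <- p2_bounds[1] + par[2]^2
    if (p2 > p2_bounds[2]) return(1e12 * (1 + p2))
    pr <- eval_profile(s_i, p2)
    if (is.null(pr)) return(1e12)
    pr$sse + p2_penalty(p2)
  }

  starts <- rbind(c(10, 0.02), c(2.5, 0.02), c(40, 0.02), c(10, 0.08))
  start_pars <- lapply(seq_len(nrow(starts)), function(k) {
    c(sqrt(starts[k, 1]), sqrt(starts[k, 2] - p2_bounds[1]))
  })
  # descend from every start, best basin first
  start_sse <- vapply(start_pars, sse_of, numeric(1))
  order_starts <- order(start_sse)
  best <- NULL
  n_used <- 0
  for (k in order_starts) {
    n_used <- n_used + 1
    opt <- tryCatch(
      stats::optim(start_pars[[k]], sse_of, method = "Nelder-Mead",
                   control = list(maxit = 250, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-12 ||
        (abs(opt$value - best$value) <= 1e-12 &&
         sum(opt$par^2) < sum(best$par^2))) {
      best <- opt
    }
    # early exit on an essentially exact data fit (noise-free input);
    # compare the data SSE, not the penalized objective
    if (best$value - p2_penalty(p2_bounds[1] + best$par[2]^2) < 1e-6) break
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e12) {
    return(structure(list(params = NULL, ra = NULL, total_ra = total_ra,
                          residuals = NULL, sse = Inf, converged = FALSE,
                          n_starts_used = n_used),
                     class = "glucose_fit"))
  }
  s_i_hat <- best$par[1]^2
  p2_hat <- p2_bounds[1] + best$par[2]^2
  pr <- eval_profile(s_i_hat, p2_hat)
  structure(
    list(params = list(s_i = s_i_hat, p2 = p2_hat,
                       s_g = config$s_g, v_g = config$v_g,
                       f_abs = config$f_abs),
         ra = list(times = bp, values = c(0, pr$h)),
         total_ra = total_ra,
         appearance_rel_err =
           abs(.trapz(bp, c(0, pr$h)) - total_ra) / total_ra,
         gb = p$gb, ib = p$ib,
         residuals = pr$residuals, sse = pr$sse,
         converged = TRUE, n_starts_used = n_used),
    class = "glucose_fit")
}
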