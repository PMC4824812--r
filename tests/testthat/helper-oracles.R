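# Independent oracles used across the suite.  These deliberately avoid the
# package's own solution paths: matrix exponentials for the linear C-peptide
# system, fixed-step Runge-Kutta for the glucose system, and explicit rank
# enumeration for the statistics.

# Matrix-exponential solution of the two-compartment C-peptide model under a
# piecewise-constant secretion rate: x' = A x + b_j on each interval.
matexp_cpeptide <- function(kinetics, sr_times, sr_values, init, times) {
  A <- matrix(c(-(kinetics$k01 + kinetics$k21), kinetics$k12,
                kinetics$k21, -kinetics$k12), 2, 2, byrow = TRUE)
  grid <- sort(unique(c(sr_times, times)))
  x <- matrix(NA_real_, length(grid), 2)
  x[1, ] <- init
  for (i in seq_len(length(grid) - 1)) {
    dt <- grid[i + 1] - grid[i]
    j <- findInterval(grid[i], sr_times)
    b <- c(sr_values[j], 0)
    eA <- as.matrix(Matrix::expm(A * dt))
    x[i + 1, ] <- drop(eA %*% x[i, ] + solve(A, (eA - diag(2)) %*% b))
  }
  x[match(times, grid), , drop = FALSE]
}

# Fixed-step RK4 integration of the oral glucose minimal model with
# piecewise-constant (left-continuous) insulin and Ra inputs.
rk4_glucose <- function(params, insulin_times, insulin_values, ib, gb,
                        ra_times, ra_values, times, dt = 0.05) {
  si_frac <- params$s_i * 1e-5 / params$v_g
  v_l <- params$v_g / 10
  step_fun <- function(ts, vs) {
    function(t) vs[max(findInterval(t, ts), 1)]
  }
  ifun <- step_fun(insulin_times, insulin_values)
  rfun <- step_fun(ra_times, ra_values)
  deriv <- function(t, s) {
    c(-(params$s_g + s[2]) * s[1] + params$s_g * gb + rfun(t) / v_l,
      -params$p2 * (s[2] - si_frac * (ifun(t) - ib)))
  }
  grid <- seq(0, max(times), by = dt)
  x <- c(gb, 0)
  out <- matrix(NA_real_, length(times), 2)
  for (i in seq_along(grid)) {
    t <- grid[i]
    hit <- which(abs(times - t) < dt / 2)
    if (length(hit)) out[hit, ] <- rep(x, each = length(hit))
    k1 <- deriv(t, x)
    k2 <- deriv(t + dt / 2, x + dt / 2 * k1)
    k3 <- deriv(t + dt / 2, x + dt / 2 * k2)
    k4 <- deriv(t + dt, x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  out[match(max(times), times), ] <- x
  out
}

# Brute-force Spearman rank correlation: explicit average ranks, explicit
# product-moment formula on the ranks.
brute_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Mann-Whitney AUC by explicit pair enumeration (ties count 1/2).
brute_mw_auc <- function(marker, status) {
  cases <- marker[as.logical(status)]
  controls <- marker[!as.logical(status)]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}

# Trapezoid on a dense grid for clipped-excess areas (geometric oracle).
dense_excess_auc <- function(times, glucose, thr, n = 200001) {
  tt <- seq(min(times), max(times), length.out = n)
  gg <- approx(times, glucose, xout = tt)$y
  ex <- pmax(gg - thr, 0)
  sum((head(ex, -1) + tail(ex, -1)) / 2 * diff(tt))
}
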