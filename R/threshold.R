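#' Above-threshold plasma glucose AUC
#'
#' Trapezoidal integral of `max(G(t) - thr, 0)` over the sampled span, with
#' exact interpolation of the threshold crossing inside each segment (the
#' clipped area of a crossing segment is the triangle/trapezoid above the
#' threshold, not the clipped trapezoid of the endpoints).
#'
#' @param times,glucose Sampled glucose curve, min and mmol/L.
#' @param thr Threshold, mmol/L (> 0).
#' @return AUC of the excess, mmol min/L (>= 0).
#' @export
above_threshold_auc <- function(times, glucose, thr) {
  if (!is.finite(thr) || thr <= 0) {
    .stop_validation("above_threshold_auc: thr must be > 0")
  }
  if (any(diff(times) <= 0)) {
    .stop_validation("above_threshold_auc: times must be strictly increasing")
  }
  t0 <- head(times, -1); t1 <- tail(times, -1)
  g0 <- head(glucose, -1) - thr; g1 <- tail(glucose, -1) - thr
  dt <- t1 - t0
  area <- numeric(length(dt))
  both_above <- g0 >= 0 & g1 >= 0
  area[both_above] <- (g0[both_above] + g1[both_above]) / 2 * dt[both_above]
  up <- g0 < 0 & g1 > 0    # crossing upward: triangle at the segment end
  area[up] <- g1[up]^2 * dt[up] / (2 * (g1[up] - g0[up]))
  down <- g0 > 0 & g1 < 0  # crossing downward: triangle at the segment start
  area[down] <- g0[down]^2 * dt[down] / (2 * (g0[down] - g1[down]))
  sum(area)
}

#' Stepwise-exclusion renal glucose threshold estimation
#'
#' For each candidate threshold on the grid, subjects are retained if their
#' above-threshold plasma glucose AUC is positive, and cross-tabulated by
#' subgroup (non-T2D vs T2D) and urine status (glucose present above the
#' positivity cutoff, or absent).  Raising the threshold excludes subjects
#' stepwise.  A subgroup's estimated threshold is the smallest grid value at
#' which *no urine-negative subject* retains a positive above-threshold AUC —
#' the lowest glucose level that all non-excretors stayed under.  The
#' estimate is "not assessable" when the subgroup is empty, has no
#' urine-negative subjects (everyone excretes), or the criterion is never met
#' on the grid.
#'
#' @param cohort List of per-subject records (see [read_cohort()]); subjects
#'   without a urine collection are excluded.
#' @param config A [run_config()] (supplies the grid, the positivity cutoff
#'   and the baseline time).
#' @return List with `estimates` (tibble: `group`, `threshold`, `assessable`,
#'   `reason`) and `table` (tibble: `threshold`, `group`, `urine_status`,
#'   `n`, `mean_auc`, `sem_auc` — the stepwise-exclusion table).
#' @export
estimate_threshold <- function(cohort, config = run_config()) {
  grid <- config$threshold_grid
  cutoff <- config$urine_positivity_cutoff

  subj <- purrr::map(cohort, function(rec) {
    if (is.null(rec$urine)) return(NULL)
    p <- .postload(rec$series, config$baseline_time)
    list(is_t2d = identical(rec$subject$tolerance_class, "T2D"),
         urine_pos = rec$urine$glucose_mmol_l > cutoff,
         auc = vapply(grid, function(th)
           above_threshold_auc(p$times, p$glucose, th), numeric(1)))
  })
  subj <- purrr::compact(subj)

  tab <- tidyr::expand_grid(threshold = grid,
                            group = c("non_t2d", "t2d"),
                            urine_status = c("negative", "positive"))
  cells <- purrr::pmap(tab, function(threshold, group, urine_status) {
    i <- match(threshold, grid)
    sel <- purrr::keep(subj, function(s) {
      s$is_t2d == (group == "t2d") &&
        s$urine_pos == (urine_status == "positive") && s$auc[i] > 0
    })
    aucs <- vapply(sel, function(s) s$auc[i], numeric(1))
    n <- length(aucs)
    tibble::tibble(n = n,
                   mean_auc = if (n > 0) mean(aucs) else NA_real_,
                   sem_auc = if (n > 1) stats::sd(aucs) / sqrt(n) else NA_real_)
  })
  tab <- dplyr::bind_cols(tab, dplyr::bind_rows(cells))

  est_one <- function(group) {
    members <- purrr::keep(subj, function(s) s$is_t2d == (group == "t2d"))
    if (length(members) == 0) {
      return(tibble::tibble(group = group, threshold = NA_real_,
                            assessable = FALSE, reason = "empty_subgroup"))
    }
    n_neg <- sum(vapply(members, function(s) !s$urine_pos, logical(1)))
    if (n_neg == 0) {
      return(tibble::tibble(group = group, threshold = NA_real_,
                            assessable = FALSE, reason = "all_excrete"))
    }
    for (i in seq_along(grid)) {
      neg_retained <- tab$n[tab$threshold == grid[i] & tab$group == group &
                              tab$urine_status == "negative"]
      if (neg_retained == 0) {
        return(tibble::tibble(group = group, threshold = grid[i],
                              assessable = TRUE, reason = NA_character_))
      }
    }
    tibble::tibble(group = group, threshold = NA_real_,
                   assessable = FALSE, reason = "not_on_grid")
  }
  estimates <- dplyr::bind_rows(est_one("non_t2d"), est_one("t2d"))
  list(estimates = estimates, table = tab)
}
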