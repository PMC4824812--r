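#' Spearman correlation table of urine markers against plasma indices
#'
#' One rank correlation per (marker, index) pair with pairwise-complete
#' deletion; ranks use the average-tie method and the two-sided p-value comes
#' from the standard large-sample t approximation.  Cells with fewer than
#' `min_pairs` complete pairs are marked missing.
#'
#' @param data Data frame holding all columns (one row per subject).
#' @param markers Character vector of urine-marker column names (rows).
#' @param indices Character vector of plasma-index column names (columns).
#' @param min_pairs Minimum complete pairs per cell (default 5).
#' @return Tibble with `marker`, `index`, `n`, `r`, `p`.
#' @export
spearman_table <- function(data,
                           markers = c("urine_glucose", "urine_glucose_creatinine_ratio",
                                       "urine_cpeptide", "urine_cpeptide_creatinine_ratio"),
                           indices = c("incr_auc_cpeptide", "incr_auc_glucose",
                                       "s_i", "phi_dynamic", "phi_static",
                                       "di_dynamic", "di_static"),
                           min_pairs = 5) {
  grid <- tidyr::expand_grid(marker = markers, index = indices)
  cells <- purrr::pmap(grid, function(marker, index) {
    x <- data[[marker]]; y <- data[[index]]
    if (is.null(x) || is.null(y) || length(x) == 0) {
      return(tibble::tibble(n = 0L, r = NA_real_, p = NA_real_))
    }
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < min_pairs) {
      return(tibble::tibble(n = n, r = NA_real_, p = NA_real_))
    }
    r <- stats::cor(rank(x[ok]), rank(y[ok]))
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    tibble::tibble(n = n, r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(cells))
}

# Concordance of a score with a binary status: P(score_case > score_control),
# ties counted 1/2 — the Mann-Whitney AUC via average ranks.
.concordance <- function(score, status) {
  n1 <- sum(status); n0 <- sum(!status)
  r <- rank(score)
  (sum(r[status]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Family-adjusted ROC c-index of a urine marker
#'
#' Point estimate: a single-predictor binary logistic model of status on the
#' marker is fitted to the pooled data and the c-index is the concordance of
#' the fitted probabilities with status (for a monotone predictor this equals
#' the Mann-Whitney AUC of the raw marker).  Family ties are handled in the
#' uncertainty: the confidence interval is a percentile cluster bootstrap
#' resampling whole families.  A family-level random-intercept logistic model
#' (lme4) is exposed as an alternative point estimate.
#'
#' @param marker Numeric marker values.
#' @param status Logical (or 0/1) case status.
#' @param family_id Family identifier per subject.
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @param method `"bootstrap"` (pooled fit + cluster bootstrap, default) or
#'   `"random_intercept"` (lme4 point estimate, same bootstrap CI).
#' @return List `cindex`, `ci` (length 2), `n_case`, `n_control`, `n_boot`,
#'   `reason` (`NA` on success; `"one_class_absent"` or
#'   `"marker_missing"` with `cindex = NA` otherwise).
#' @export
family_adjusted_cindex <- function(marker, status, family_id, n_boot = 1000,
                                   seed = 1L, conf_level = 0.95,
                                   method = c("bootstrap", "random_intercept")) {
  method <- match.arg(method)
  status <- as.logical(status)
  ok <- stats::complete.cases(marker, status, family_id)
  marker <- marker[ok]; status <- status[ok]; family_id <- family_id[ok]
  fail <- function(reason) list(cindex = NA_real_, ci = c(NA_real_, NA_real_),
                                n_case = sum(status), n_control = sum(!status),
                                n_boot = 0L, reason = reason)
  if (length(marker) == 0) return(fail("marker_missing"))
  if (sum(status) == 0 || sum(!status) == 0) return(fail("one_class_absent"))

  point <- function(m, s, f) {
    if (method == "random_intercept" &&
        requireNamespace("lme4", quietly = TRUE)) {
      fit <- suppressWarnings(suppressMessages(
        lme4::glmer(s ~ m + (1 | f), family = stats::binomial,
                    data = data.frame(m = m, s = s, f = f))))
      pr <- stats::predict(fit, re.form = NA, type = "response")
    } else {
      fit <- suppressWarnings(
        stats::glm(s ~ m, family = stats::binomial(),
                   data = data.frame(m = m, s = s)))
      pr <- stats::predict(fit, type = "response")
    }
    .concordance(pr, s)
  }
  c_hat <- point(marker, status, family_id)

  fams <- split(seq_along(marker), family_id)
  boots <- rep(NA_real_, n_boot)
  if (n_boot > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    for (b in seq_len(n_boot)) {
      draw <- unlist(fams[sample(length(fams), replace = TRUE)],
                     use.names = FALSE)
      s <- status[draw]
      if (sum(s) == 0 || sum(!s) == 0) next
      boots[b] <- tryCatch(point(marker[draw], s, family_id[draw]),
                           error = function(e) NA_real_)
    }
  }
  alpha <- (1 - conf_level) / 2
  ci <- if (any(is.finite(boots))) {
    unname(stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  } else {
    c(NA_real_, NA_real_)
  }
  list(cindex = c_hat, ci = ci, n_case = sum(status),
       n_control = sum(!status), n_boot = sum(is.finite(boots)),
       reason = NA_character_)
}
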