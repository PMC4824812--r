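#' Read a cohort from delimited tables
#'
#' The cohort lives in one tidy long-format CSV of plasma samples (subject
#' metadata columns repeated per row, one row per sampling time) plus an
#' optional second CSV of pooled urine collections keyed by `subject_id`.
#' Subjects without urine rows get `urine = NULL` ("missing", never zero).
#'
#' Plasma columns: `subject_id, family_id, ethnicity, sex, age, weight,
#' height, serum_creatinine, tolerance_class, time_min, glucose_mmol_l,
#' insulin_pmol_l, cpeptide_pmol_l`.
#' Urine columns: `subject_id, volume_l, glucose_mmol_l, cpeptide_nmol_l,
#' creatinine_mmol_l`.
#'
#' @param plasma_path Path to the plasma CSV.
#' @param urine_path Path to the urine CSV, or `NULL` if no urine was collected.
#' @param config A [run_config()].
#' @return A list of per-subject records, each a list with elements `subject`
#'   ([subject_record()]), `series` ([ogtt_series()]) and `urine`
#'   ([urine_collection()] or `NULL`).
#' @export
read_cohort <- function(plasma_path, urine_path = NULL, config = run_config()) {
  if (!file.exists(plasma_path)) {
    .stop_schema("read_cohort: file not found: ", plasma_path)
  }
  plasma <- readr::read_csv(plasma_path, show_col_types = FALSE,
                            progress = FALSE)
  required <- c("subject_id", "family_id", "ethnicity", "sex", "age", "weight",
                "height", "serum_creatinine", "tolerance_class", "time_min",
                "glucose_mmol_l", "insulin_pmol_l", "cpeptide_pmol_l")
  missing_cols <- setdiff(required, names(plasma))
  if (length(missing_cols) > 0) {
    .stop_schema("read_cohort: missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", "))
  }

  urine <- NULL
  if (!is.null(urine_path)) {
    if (!file.exists(urine_path)) {
      .stop_schema("read_cohort: file not found: ", urine_path)
    }
    urine <- readr::read_csv(urine_path, show_col_types = FALSE,
                             progress = FALSE)
    u_required <- c("subject_id", "volume_l", "glucose_mmol_l",
                    "cpeptide_nmol_l", "creatinine_mmol_l")
    u_missing <- setdiff(u_required, names(urine))
    if (length(u_missing) > 0) {
      .stop_schema("read_cohort: urine table missing column(s): ",
                   paste(u_missing, collapse = ", "))
    }
  }

  ids <- unique(plasma$subject_id)
  lapply(ids, function(id) {
    rows <- plasma[plasma$subject_id == id, ]
    rows <- rows[order(rows$time_min), ]
    if (anyDuplicated(rows$time_min)) {
      .stop_validation("read_cohort: duplicated sampling time for subject ", id)
    }
    subj <- subject_record(
      subject_id = id, family_id = rows$family_id[1],
      ethnicity = rows$ethnicity[1], sex = rows$sex[1], age = rows$age[1],
      weight = rows$weight[1], height = rows$height[1],
      serum_creatinine = rows$serum_creatinine[1],
      tolerance_class = as.character(rows$tolerance_class[1]))
    series <- ogtt_series(rows$time_min, rows$glucose_mmol_l,
                          rows$insulin_pmol_l, rows$cpeptide_pmol_l)
    u <- NULL
    if (!is.null(urine)) {
      urow <- urine[urine$subject_id == id, ]
      if (nrow(urow) == 1) {
        u <- urine_collection(urow$volume_l, urow$glucose_mmol_l,
                              urow$cpeptide_nmol_l, urow$creatinine_mmol_l)
      }
    }
    list(subject = subj, series = series, urine = u)
  })
}

#' Write a cohort to delimited tables
#'
#' Inverse of [read_cohort()]; numeric fields round-trip to full precision.
#'
#' @param cohort List of per-subject records as returned by [read_cohort()] or
#'   [generate_cohort()]`$cohort`.
#' @param plasma_path,urine_path Output CSV paths.  The urine table is written
#'   only for subjects that have a collection.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, plasma_path, urine_path = NULL) {
  plasma <- dplyr::bind_rows(lapply(cohort, function(rec) {
    s <- rec$subject
    ser <- rec$series
    tibble::tibble(
      subject_id = s$subject_id, family_id = s$family_id,
      ethnicity = s$ethnicity, sex = s$sex, age = s$age, weight = s$weight,
      height = s$height, serum_creatinine = s$serum_creatinine,
      tolerance_class = s$tolerance_class, time_min = ser$times,
      glucose_mmol_l = ser$glucose, insulin_pmol_l = ser$insulin,
      cpeptide_pmol_l = ser$cpeptide)
  }))
  readr::write_csv(plasma, plasma_path, progress = FALSE)
  if (!is.null(urine_path)) {
    urine <- dplyr::bind_rows(lapply(cohort, function(rec) {
      if (is.null(rec$urine)) return(NULL)
      u <- rec$urine
      tibble::tibble(subject_id = rec$subject$subject_id,
                     volume_l = u$volume_l, glucose_mmol_l = u$glucose_mmol_l,
                     cpeptide_nmol_l = u$cpeptide_nmol_l,
                     creatinine_mmol_l = u$creatinine_mmol_l)
    }))
    readr::write_csv(urine, urine_path, progress = FALSE)
  }
  invisible(c(plasma_path, urine_path))
}
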