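#' Cohort table schema
#'
#' A cohort is a data frame with one row per subject-eye. Required columns:
#' `subject_id`, `group` (`control`/`sagittal`), `sex` (`M`/`F`),
#' `age_years`, `re_diopters` (refractive error in diopters, may be `NA`),
#' `eye` (`OD` right / `OS` left), `fundoscopy`
#' (`normal`/`papilledema`/`pseudopapilledema`), `headache` (0/1/`NA`),
#' `fingerprint_r1`, `fingerprint_r2` (rater scores 0/1/2 or `NA`), eight
#' `trt_*` sector thickness columns (um) and eight `trv_*` sector volume
#' columns (mm^3). Missing sectors are empty cells; thickness and volume
#' must be missing for the same sectors of a scan.
#'
#' @return Character vector of the 26 column names in schema order.
#' @export
cohort_columns <- function() {
  c("subject_id", "group", "sex", "age_years", "re_diopters", "eye",
    "fundoscopy", "headache", "fingerprint_r1", "fingerprint_r2",
    sector_columns("trt"), sector_columns("trv"))
}

.val_err <- function(row, msg) {
  stop(sprintf("cohort validation error at row %d: %s", row, msg), call. = FALSE)
}

#' Validate a cohort table
#'
#' Checks the schema and the per-row invariants: group/sex/eye/fundoscopy
#' levels, age in (2, 12) years, sector thickness in (0, 2000) um, sector
#' volume in (0, 2) mm^3, matching thickness/volume availability masks,
#' refractive error present for pseudopapilledema, and at most one row per
#' subject-eye.
#'
#' @param cohort Data frame in the cohort schema.
#' @return The cohort, invisibly, with `headache` and rater scores as
#'   integers and measurements as numerics.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cohort <- cohort[, cohort_columns()]
  for (cc in c(sector_columns("trt"), sector_columns("trv"), "age_years",
               "re_diopters")) {
    cohort[[cc]] <- suppressWarnings(as.numeric(cohort[[cc]]))
  }
  for (cc in c("headache", "fingerprint_r1", "fingerprint_r2")) {
    cohort[[cc]] <- suppressWarnings(as.integer(cohort[[cc]]))
  }
  cohort$subject_id <- as.character(cohort$subject_id)
  lv <- list(group = c("control", "sagittal"), sex = c("M", "F"),
             eye = c("OD", "OS"),
             fundoscopy = c("normal", "papilledema", "pseudopapilledema"))
  for (i in seq_len(nrow(cohort))) {
    r <- cohort[i, ]
    for (cc in names(lv)) {
      if (is.na(r[[cc]]) || !r[[cc]] %in% lv[[cc]])
        .val_err(i, sprintf("%s = '%s' not one of {%s}", cc, r[[cc]],
                            paste(lv[[cc]], collapse = ", ")))
    }
    if (is.na(r$age_years) || r$age_years <= 2 || r$age_years >= 12)
      .val_err(i, sprintf("age_years = %s outside (2, 12)", r$age_years))
    trt <- as.numeric(r[sector_columns("trt")])
    trv <- as.numeric(r[sector_columns("trv")])
    bad_t <- which(!is.na(trt) & (trt <= 0 | trt >= 2000))
    if (length(bad_t) > 0)
      .val_err(i, sprintf("%s = %g outside (0, 2000) um",
                          sector_columns("trt")[bad_t[1]], trt[bad_t[1]]))
    bad_v <- which(!is.na(trv) & (trv <= 0 | trv >= 2))
    if (length(bad_v) > 0)
      .val_err(i, sprintf("%s = %g outside (0, 2) mm^3",
                          sector_columns("trv")[bad_v[1]], trv[bad_v[1]]))
    if (!identical(is.na(trt), is.na(trv)))
      .val_err(i, "thickness and volume availability masks differ")
    if (!is.na(r$headache) && !r$headache %in% c(0L, 1L))
      .val_err(i, "headache must be 0, 1 or empty")
    for (cc in c("fingerprint_r1", "fingerprint_r2"))
      if (!is.na(r[[cc]]) && !r[[cc]] %in% 0:2)
        .val_err(i, paste(cc, "must be 0, 1, 2 or empty"))
    if (r$fundoscopy == "pseudopapilledema" && is.na(r$re_diopters))
      .val_err(i, "pseudopapilledema requires a refractive error")
  }
  if (anyDuplicated(cohort[, c("subject_id", "eye")]) > 0)
    stop("cohort validation error: duplicated subject-eye rows", call. = FALSE)
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads and validates a subject-eye cohort table. Empty cells become `NA`
#' (an absent sector, an unmeasured refractive error, an unscored sign).
#'
#' @param path Path to a CSV file in the cohort schema.
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character"),
                         na.strings = c("", "NA"))
  validate_cohort(raw)
}

#' Write a cohort CSV
#'
#' @param cohort Validated cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort[, cohort_columns()], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Count available sectors per scan
#'
#' @param cohort Cohort data frame (one row per subject-eye).
#' @return Integer vector: number of the 8 sectors with a thickness value.
#' @export
n_sectors_available <- function(cohort) {
  as.integer(rowSums(!is.na(cohort[, sector_columns("trt"), drop = FALSE])))
}

#' Scan quality filter
#'
#' A scan is excluded when less than 75% of the eight sectors are available,
#' i.e. fewer than 6 of 8; exactly 6 (75%) is kept.
#'
#' @param cohort Cohort data frame.
#' @return Logical vector, `TRUE` for scans to keep.
#' @export
#' @examples
#' # a scan with 6 available sectors is kept, 5 is excluded
quality_filter <- function(cohort) {
  n_sectors_available(cohort) >= 6L
}
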