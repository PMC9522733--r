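#' Derived thickness and volume indices
#'
#' Computes, per subject-eye, the summary indices of the eight-sector
#' peripapillary grid: the overall mean (mean of all available sectors),
#' the outer- and inner-ring means, and the four quadrant values (mean of
#' the quadrant's available inner and outer sector). Identical construction
#' for thickness (um) and volume (mm^3). Missing sectors are excluded from
#' every mean; an index whose constituent sectors are all missing is `NA`,
#' never zero.
#'
#' @param cohort Cohort data frame (one row per subject-eye); normally
#'   already restricted to scans passing [quality_filter()].
#' @return Data frame with `subject_id`, `eye` and, for each of
#'   `trt`/`trv`: `mean_*`, `outer_*`, `inner_*`, `superior_*`, `nasal_*`,
#'   `inferior_*`, `temporal_*`, plus `availability_fraction`.
#' @export
derive_indices <- function(cohort) {
  out <- cohort[, c("subject_id", "eye"), drop = FALSE]
  for (measure in c("trt", "trv")) {
    m <- as.matrix(cohort[, sector_columns(measure), drop = FALSE])
    lab <- sector_labels()
    row_mean <- function(cols) {
      sub <- m[, cols, drop = FALSE]
      v <- rowMeans(sub, na.rm = TRUE)
      v[rowSums(!is.na(sub)) == 0] <- NA_real_
      v
    }
    out[[paste0("mean_", measure)]]  <- row_mean(seq_along(lab))
    out[[paste0("outer_", measure)]] <- row_mean(grep("^3_", lab))
    out[[paste0("inner_", measure)]] <- row_mean(grep("^2_", lab))
    for (q in .quadrants) {
      out[[paste0(q, "_", measure)]] <- row_mean(grep(paste0("_", q, "$"), lab))
    }
  }
  out$availability_fraction <- n_sectors_available(cohort) / 8
  out
}

#' Index parameter identifiers
#'
#' The 30 parameters of the normative-range table: for each of thickness and
#' volume, the overall mean, the two ring means, the four quadrant values
#' and the eight sectors.
#'
#' @param measure `"trt"`, `"trv"` or `"both"` (default).
#' @return Character vector of parameter ids, e.g. `"mean_trt"`,
#'   `"trt_3_nasal"`.
#' @export
index_parameters <- function(measure = c("both", "trt", "trv")) {
  measure <- match.arg(measure)
  one <- function(ms) {
    c(paste0(c("mean_", "outer_", "inner_"), ms),
      paste0(.quadrants, "_", ms),
      paste(ms, sector_labels(), sep = "_"))
  }
  switch(measure, trt = one("trt"), trv = one("trv"),
         both = c(one("trt"), one("trv")))
}

#' Per-subject parameter values
#'
#' Binds the derived indices and the raw sector values into one table with
#' a column per parameter id, for reference-interval estimation and
#' classification.
#'
#' @param cohort Cohort data frame (one row per subject-eye).
#' @return Data frame with `subject_id`, `eye` and one column per
#'   [index_parameters()] entry.
#' @export
parameter_values <- function(cohort) {
  idx <- derive_indices(cohort)
  cbind(idx[, setdiff(names(idx), "availability_fraction")],
        cohort[, c(sector_columns("trt"), sector_columns("trv"))])
}

#' Select the analysis eye per subject
#'
#' One eye per subject enters the analyses. Controls contribute the right
#' eye unless its scan is absent or fails the quality filter, in which case
#' the left eye is used. Patients contribute the eye with the highest mean
#' thickness (papilledema can be unilateral). Subjects with no eligible eye
#' are dropped and recorded.
#'
#' @param cohort Cohort data frame (one row per subject-eye).
#' @return Cohort data frame with one row per subject, attribute `"dropped"`
#'   holding a data frame of dropped subjects and reasons.
#' @export
select_analysis_eye <- function(cohort) {
  keep <- quality_filter(cohort)
  mean_trt <- derive_indices(cohort)$mean_trt
  picked <- integer(0)
  dropped <- data.frame(subject_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (sid in unique(cohort$subject_id)) {
    rows <- which(cohort$subject_id == sid)
    ok <- rows[keep[rows]]
    if (length(ok) == 0) {
      dropped <- rbind(dropped, data.frame(
        subject_id = sid, reason = "no scan passing quality filter",
        stringsAsFactors = FALSE))
      next
    }
    grp <- cohort$group[rows[1]]
    if (grp == "control") {
      od <- ok[cohort$eye[ok] == "OD"]
      picked <- c(picked, if (length(od) > 0) od[1] else ok[1])
    } else {
      picked <- c(picked, ok[which.max(mean_trt[ok])])
    }
  }
  out <- cohort[picked, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
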