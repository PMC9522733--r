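#' Cut-off set from a reference-interval table
#'
#' Takes the computed reference-interval endpoints, at full precision, as
#' classification bounds for every parameter.
#'
#' @param ri_table Output of [reference_interval_table()] (or a manual
#'   table with columns `parameter`, `lower_ri`, `upper_ri`).
#' @return Data frame `parameter`, `lower`, `upper` with attribute
#'   `provenance`; parameters without endpoints are dropped.
#' @export
cutoffs_from_reference_intervals <- function(ri_table) {
  stopifnot(all(c("parameter", "lower_ri", "upper_ri") %in% names(ri_table)))
  out <- data.frame(parameter = ri_table$parameter,
                    lower = ri_table$lower_ri,
                    upper = ri_table$upper_ri, stringsAsFactors = FALSE)
  out <- out[!is.na(out$lower) & !is.na(out$upper), , drop = FALSE]
  if (any(out$lower >= out$upper))
    stop("cut-off set invalid: lower >= upper for ",
         out$parameter[out$lower >= out$upper][1], call. = FALSE)
  attr(out, "provenance") <- "reference_interval_table"
  out
}

#' Classify one value against cut-off bounds
#'
#' Strict inequalities: `increased` iff value > upper, `decreased` iff
#' value < lower, `normal` otherwise (a value exactly at an endpoint is
#' normal); missing values get the `missing` flag.
#'
#' @param value Measurement(s).
#' @param lower,upper Cut-off bounds (lower < upper).
#' @return Character vector of flags.
#' @export
#' @examples
#' classify_index(c(403.8, 503.8, 510), 256.0, 503.8)
classify_index <- function(value, lower, upper) {
  stopifnot(lower < upper)
  ifelse(is.na(value), "missing",
         ifelse(value > upper, "increased",
                ifelse(value < lower, "decreased", "normal")))
}

#' Classify a patient cohort against normative cut-offs
#'
#' Flags every cut-off parameter of each subject's analysis eye and derives
#' the overall OCT status. By default the OCT is abnormal when the mean
#' thickness *or* the mean volume is increased (`logic = "or"`); with
#' `logic = "and"` both must be increased. Decreased flags are retained
#' even though thinning (suspected atrophy) is rare in this setting.
#'
#' @param cohort Cohort data frame; `group == "sagittal"` rows are used and
#'   reduced to one analysis eye (highest mean thickness) per subject.
#' @param cutoffs Cut-off table from [cutoffs_from_reference_intervals()].
#' @param logic `"or"` (default) or `"and"` for the overall OCT status.
#' @return Data frame: `subject_id`, one `flag_<parameter>` column per
#'   cut-off parameter, `overall_oct` (`normal`/`abnormal`),
#'   `excluded_pseudopapilledema` (logical). Attribute `"dropped"` lists
#'   subjects without an eligible eye.
#' @export
classify_cohort <- function(cohort, cutoffs, logic = c("or", "and")) {
  logic <- match.arg(logic)
  patients <- cohort[cohort$group == "sagittal", , drop = FALSE]
  if (nrow(patients) == 0) stop("no sagittal rows in cohort", call. = FALSE)
  eye <- select_analysis_eye(patients)
  vals <- parameter_values(eye)
  out <- data.frame(subject_id = eye$subject_id, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cutoffs))) {
    p <- cutoffs$parameter[i]
    v <- if (p %in% names(vals)) vals[[p]] else rep(NA_real_, nrow(vals))
    out[[paste0("flag_", p)]] <- classify_index(v, cutoffs$lower[i],
                                                cutoffs$upper[i])
  }
  pick <- function(p) {
    col <- paste0("flag_", p)
    if (col %in% names(out)) out[[col]] else rep("missing", nrow(out))
  }
  trt_inc <- pick("mean_trt") == "increased"
  trv_inc <- pick("mean_trv") == "increased"
  abn <- if (logic == "or") trt_inc | trv_inc else trt_inc & trv_inc
  out$overall_oct <- ifelse(abn, "abnormal", "normal")
  out$excluded_pseudopapilledema <-
    eye$fundoscopy == "pseudopapilledema"
  attr(out, "dropped") <- attr(eye, "dropped")
  attr(out, "logic") <- logic
  out
}

#' Exclude pseudopapilledema subjects from secondary analyses
#'
#' Pseudopapilledema (hyperopic crowded nerve or drusen) explains an
#' elevated thickness without intracranial hypertension, so those subjects
#' are removed from the clinical-sign association analyses. They stay in
#' the primary fundoscopy cross-tab, which is built from the unfiltered
#' results.
#'
#' @param results Output of [classify_cohort()].
#' @return Filtered results (attribute `"n_excluded"` records the count).
#' @export
apply_pseudopapilledema_exclusion <- function(results) {
  keep <- !results$excluded_pseudopapilledema
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}
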