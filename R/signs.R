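#' @keywords internal
.interp_ref <- function(growth_ref, sex, ages, col) {
  ref <- growth_ref[growth_ref$sex == sex, , drop = FALSE]
  if (nrow(ref) < 2) stop("growth reference has no rows for sex ", sex,
                          call. = FALSE)
  ref <- ref[order(ref$age_years), ]
  if (any(ages < min(ref$age_years) | ages > max(ref$age_years)))
    stop("age outside the growth-reference range [",
         min(ref$age_years), ", ", max(ref$age_years),
         "]; no extrapolation is performed", call. = FALSE)
  stats::approx(ref$age_years, ref[[col]], xout = ages)$y
}

#' Convert head circumference to an SD score
#'
#' SDS = (OFC - mean(age, sex)) / sd(age, sex), with linear interpolation of
#' the reference mean and SD in age. No extrapolation outside the reference
#' age range.
#'
#' @param ofc_cm Occipitofrontal circumference, cm.
#' @param age_years Age in decimal years (same length as `ofc_cm` or scalar).
#' @param sex `"M"` or `"F"`.
#' @param growth_ref Reference table with columns `sex`, `age_years`,
#'   `mean_cm`, `sd_cm` (see [synthetic_growth_reference()]).
#' @return Numeric SD scores.
#' @export
ofc_to_sds <- function(ofc_cm, age_years, sex,
                       growth_ref = synthetic_growth_reference()) {
  sex <- match.arg(sex, c("M", "F"))
  mu <- .interp_ref(growth_ref, sex, age_years, "mean_cm")
  sg <- .interp_ref(growth_ref, sex, age_years, "sd_cm")
  (ofc_cm - mu) / sg
}

#' Detect skull growth arrest from an SDS trajectory
#'
#' Skull growth arrest is a fall of 0.5 SD or more in the OFC SD-score over
#' 2 years. The trajectory (ages in years, values in SD units) is evaluated
#' from its first recorded point onward; when no observation falls exactly
#' 2 years after a window start, the SDS there is linearly interpolated.
#' With `sliding = TRUE` (default) every observation time that leaves at
#' least 2 years of follow-up opens a window, and any qualifying window
#' implies arrest; with `sliding = FALSE` only the window anchored at the
#' first point is tested. A drop of exactly 0.5 counts as arrest.
#'
#' @param age_years Strictly increasing observation ages, years.
#' @param sds OFC SD-scores at those ages.
#' @param sliding Evaluate all 2-year windows (default) or baseline only.
#' @return `TRUE`, `FALSE`, or `NA` (indeterminate: fewer than 2 points or
#'   less than 2 years of follow-up).
#' @export
detect_growth_arrest <- function(age_years, sds, sliding = TRUE) {
  stopifnot(length(age_years) == length(sds))
  ok <- !is.na(age_years) & !is.na(sds)
  age_years <- age_years[ok]; sds <- sds[ok]
  if (length(age_years) < 2) return(NA)
  if (is.unsorted(age_years, strictly = TRUE))
    stop("trajectory ages must be strictly increasing", call. = FALSE)
  span <- max(age_years) - min(age_years)
  if (span < 2) return(NA)
  starts <- if (sliding) age_years[age_years <= max(age_years) - 2]
            else age_years[1]
  for (t0 in starts) {
    s0 <- stats::approx(age_years, sds, xout = t0)$y
    s2 <- stats::approx(age_years, sds, xout = t0 + 2)$y
    if (!is.na(s0) && !is.na(s2) && (s2 - s0) <= -0.5) return(TRUE)
  }
  FALSE
}

#' Growth arrest per subject from a trajectory table
#'
#' Converts each subject's OFC series to SD scores and applies
#' [detect_growth_arrest()].
#'
#' @param trajectories Data frame `subject_id`, `age_years`, `ofc_cm`.
#' @param subjects Data frame with `subject_id` and `sex` (e.g. the cohort
#'   or truth table; first row per subject is used).
#' @param growth_ref Growth reference table.
#' @param sliding Passed to [detect_growth_arrest()].
#' @return Data frame `subject_id`, `growth_arrest` (logical, `NA` when
#'   indeterminate).
#' @export
growth_arrest_table <- function(trajectories, subjects,
                                growth_ref = synthetic_growth_reference(),
                                sliding = TRUE) {
  sex_of <- subjects$sex[!duplicated(subjects$subject_id)]
  names(sex_of) <- subjects$subject_id[!duplicated(subjects$subject_id)]
  ids <- unique(trajectories$subject_id)
  res <- vapply(ids, function(sid) {
    tr <- trajectories[trajectories$subject_id == sid, , drop = FALSE]
    tr <- tr[order(tr$age_years), ]
    sx <- sex_of[[sid]]
    if (is.null(sx) || is.na(sx)) return(NA)
    sds <- ofc_to_sds(tr$ofc_cm, tr$age_years, sx, growth_ref)
    detect_growth_arrest(tr$age_years, sds, sliding = sliding)
  }, logical(1))
  data.frame(subject_id = ids, growth_arrest = unname(res),
             stringsAsFactors = FALSE)
}

#' Collapse the 3-point fingerprinting scale to 2 points
#'
#' Radiograph fingerprinting is scored 0 (none), 1 (minimal), 2 (extensive)
#' by each rater; only extensive fingerprinting counts as abnormal, so
#' scores collapse as 0,1 -> 0 and 2 -> 1. Missing stays missing.
#'
#' @param score Integer scores in \{0, 1, 2\} (or `NA`).
#' @return Integer vector in \{0, 1\} (or `NA`).
#' @export
collapse_fingerprint_scale <- function(score) {
  bad <- !is.na(score) & !score %in% 0:2
  if (any(bad)) stop("fingerprint score must be 0, 1, 2 or missing; got ",
                     score[bad][1], call. = FALSE)
  as.integer(ifelse(is.na(score), NA_integer_, as.integer(score == 2)))
}

#' Combined fingerprinting call per subject
#'
#' Collapses both raters' scores; agreement gives the common value, and
#' disagreement after collapse is flagged for consensus review (returned as
#' `NA` with `needs_consensus = TRUE`, mirroring a joint re-read workflow).
#'
#' @param r1,r2 Rater scores in \{0, 1, 2\} (or `NA`).
#' @return Data frame with `fingerprint` (0/1/`NA`) and `needs_consensus`.
#' @export
fingerprint_call <- function(r1, r2) {
  c1 <- collapse_fingerprint_scale(r1)
  c2 <- collapse_fingerprint_scale(r2)
  agree <- !is.na(c1) & !is.na(c2) & c1 == c2
  out <- ifelse(agree, c1, NA_integer_)
  one <- is.na(c1) != is.na(c2)  # single-rater: use the available score
  out[one] <- ifelse(is.na(c1[one]), c2[one], c1[one])
  data.frame(fingerprint = as.integer(out),
             needs_consensus = !is.na(c1) & !is.na(c2) & c1 != c2)
}

#' Cohen's kappa with asymptotic confidence interval
#'
#' Interrater chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e)
#' with the standard large-sample variance (Fleiss, Cohen & Everitt). The
#' CI is reported untruncated by default (it can exceed \[-1, 1\] in small
#' samples); set `truncate = TRUE` to clip it.
#'
#' @param r1,r2 Paired categorical ratings (equal length; pairs with a
#'   missing value are dropped).
#' @param conf_level Confidence level (default 0.95).
#' @param truncate Clip the CI to \[-1, 1\]?
#' @return List with `kappa`, `se`, `ci` (length 2), `p_value` (test of
#'   kappa = 0), `n`. `kappa` is `NA` when both raters are constant.
#' @export
cohen_kappa <- function(r1, r2, conf_level = 0.95, truncate = FALSE) {
  stopifnot(length(r1) == length(r2))
  ok <- !is.na(r1) & !is.na(r2)
  r1 <- r1[ok]; r2 <- r2[ok]
  n <- length(r1)
  if (n < 1) stop("no complete rating pairs", call. = FALSE)
  lev <- sort(unique(c(r1, r2)))
  if (length(lev) < 2) {
    return(list(kappa = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
                p_value = NA_real_, n = n))
  }
  tab <- table(factor(r1, lev), factor(r2, lev)) / n
  po <- sum(diag(tab))
  pi_ <- rowSums(tab); pj <- colSums(tab)
  pe <- sum(pi_ * pj)
  kap <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt asymptotic variance of kappa-hat
  k_lev <- length(lev)
  a <- sum(vapply(seq_len(k_lev), function(i)
    tab[i, i] * (1 - (pi_[i] + pj[i]) * (1 - kap))^2, numeric(1)))
  b <- 0
  for (i in seq_len(k_lev)) for (j in seq_len(k_lev)) if (i != j)
    b <- b + tab[i, j] * (pj[i] + pi_[j])^2
  b <- b * (1 - kap)^2
  cvar <- (a + b - (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(0, cvar))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- kap + c(-1, 1) * z * se
  if (truncate) ci <- pmin(1, pmax(-1, ci))
  # test of kappa = 0 uses the null-variance form
  v0 <- (pe + pe^2 - sum(pi_ * pj * (pi_ + pj))) / (n * (1 - pe)^2)
  p <- 2 * stats::pnorm(-abs(kap / sqrt(max(v0, .Machine$double.eps))))
  list(kappa = unname(kap), se = unname(se), ci = unname(ci),
       p_value = unname(p), n = n)
}

#' Clinical-sign table per subject
#'
#' Assembles the per-subject binary signs used in the association analyses:
#' growth arrest (from trajectories), collapsed fingerprinting (from the
#' two rater scores in the cohort table) and headache.
#'
#' @param cohort Cohort data frame (subject-eye rows; patient signs are
#'   constant within subject).
#' @param trajectories OFC trajectory table, or `NULL` to skip arrest.
#' @param growth_ref Growth reference table.
#' @param sliding Passed to [detect_growth_arrest()].
#' @return Data frame `subject_id`, `growth_arrest`, `fingerprint`,
#'   `headache` (each 0/1/`NA`).
#' @export
clinical_signs_table <- function(cohort, trajectories = NULL,
                                 growth_ref = synthetic_growth_reference(),
                                 sliding = TRUE) {
  first <- cohort[!duplicated(cohort$subject_id), , drop = FALSE]
  fp <- fingerprint_call(first$fingerprint_r1, first$fingerprint_r2)
  out <- data.frame(subject_id = first$subject_id,
                    growth_arrest = NA_integer_,
                    fingerprint = fp$fingerprint,
                    headache = as.integer(first$headache),
                    stringsAsFactors = FALSE)
  if (!is.null(trajectories)) {
    ga <- growth_arrest_table(trajectories, first, growth_ref, sliding)
    m <- match(out$subject_id, ga$subject_id)
    out$growth_arrest <- as.integer(ga$growth_arrest[m])
  }
  out
}
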