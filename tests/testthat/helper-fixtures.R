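# Build a cohort row (subject-eye) with all 8 sectors set to `trt` unless a
# named trt/trv vector is given; trv defaults to the thickness-implied volume.
make_eye_row <- function(subject_id = "S1", group = "control", sex = "M",
                         age_years = 7, re_diopters = 1, eye = "OD",
                         fundoscopy = "normal", headache = NA,
                         fingerprint_r1 = NA, fingerprint_r2 = NA,
                         trt = 380, trv = NULL) {
  trt_v <- if (length(trt) == 8) trt else rep(trt, 8)
  names(trt_v) <- sector_labels()
  if (is.null(trv)) {
    ring <- rep(c("outer", "inner"), 4)
    trv_v <- ifelse(is.na(trt_v), NA,
                    (trt_v / 1000) *
                      ifelse(ring == "outer", sector_area("outer"),
                             sector_area("inner")))
  } else {
    trv_v <- if (length(trv) == 8) trv else rep(trv, 8)
    trv_v[is.na(trt_v)] <- NA
  }
  row <- data.frame(subject_id = subject_id, group = group, sex = sex,
                    age_years = age_years, re_diopters = re_diopters,
                    eye = eye, fundoscopy = fundoscopy, headache = headache,
                    fingerprint_r1 = fingerprint_r1,
                    fingerprint_r2 = fingerprint_r2,
                    stringsAsFactors = FALSE)
  row[sector_columns("trt")] <- as.list(unname(trt_v))
  row[sector_columns("trv")] <- as.list(unname(trv_v))
  row
}

make_cohort <- function(...) {
  validate_cohort(do.call(rbind, list(...)))
}

# dense two-row-per-age reference with round numbers, for hand oracles
flat_growth_ref <- function(mean_cm = 52, sd_cm = 1.5) {
  expand <- expand.grid(sex = c("M", "F"), age_years = seq(0, 12, 0.5),
                        stringsAsFactors = FALSE)
  expand$mean_cm <- mean_cm
  expand$sd_cm <- sd_cm
  expand
}
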