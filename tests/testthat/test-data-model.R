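test_that("read_cohort parses subjects, eyes and missing cells", {
  rows <- rbind(
    make_eye_row("S1", eye = "OD"),
    make_eye_row("S1", eye = "OS"),
    make_eye_row("S2", eye = "OD", trt = c(360, NA, 370, 380, 390, 400, 410, 420)))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  cohort <- read_cohort(path)
  expect_equal(length(unique(cohort$subject_id)), 2)
  expect_equal(sum(cohort$subject_id == "S1"), 2)
  # empty cell -> sector absent from the availability mask
  s2 <- cohort[cohort$subject_id == "S2", ]
  expect_true(is.na(s2$trt_2_superior))
  expect_true(is.na(s2$trv_2_superior))
  expect_equal(n_sectors_available(s2), 7L)
})

test_that("cohort validation rejects bad headers and out-of-range values", {
  row <- make_eye_row()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(row[, -which(names(row) == "trt_3_nasal")], path,
                   row.names = FALSE)
  expect_error(read_cohort(path), "trt_3_nasal")

  bad <- make_eye_row()
  bad$trt_3_nasal <- -5
  bad$trv_3_nasal <- 0.3
  expect_error(validate_cohort(bad), "row 1.*trt_3_nasal")
  bad2 <- make_eye_row(age_years = 13)
  expect_error(validate_cohort(bad2), "age_years")
  # pseudopapilledema needs a refractive error
  bad3 <- make_eye_row(fundoscopy = "pseudopapilledema", re_diopters = NA)
  expect_error(validate_cohort(bad3), "refractive")
  # thickness/volume masks must agree
  bad4 <- make_eye_row()
  bad4$trt_2_nasal <- NA
  expect_error(validate_cohort(bad4), "availability")
})

test_that("cohort round-trips through write_cohort and read_cohort", {
  cohort <- make_cohort(
    make_eye_row("S1", eye = "OD", headache = 1, fingerprint_r1 = 2,
                 fingerprint_r2 = 1, group = "sagittal", re_diopters = NA),
    make_eye_row("S2", eye = "OS", trt = c(NA, 310, 320, 330, 340, 350, 360, 370)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back, cohort)
})

test_that("quality filter keeps >= 6 of 8 sectors and excludes below", {
  full <- make_eye_row("A", trt = rep(380, 8))
  six <- make_eye_row("B", trt = c(380, 380, 380, 380, 380, 380, NA, NA))
  five <- make_eye_row("C", trt = c(380, 380, 380, 380, 380, NA, NA, NA))
  cohort <- make_cohort(full, six, five)
  expect_equal(quality_filter(cohort), c(TRUE, TRUE, FALSE))
})

test_that("derived indices match direct arithmetic", {
  const <- make_cohort(make_eye_row(trt = rep(300, 8)))
  idx <- derive_indices(const)
  expect_equal(idx$mean_trt, 300)
  expect_equal(idx$outer_trt, 300)
  expect_equal(idx$inner_trt, 300)
  expect_equal(idx$superior_trt, 300)

  # sectors ordered (3_sup, 2_sup, 3_nas, 2_nas, 3_inf, 2_inf, 3_tmp, 2_tmp)
  grid <- make_cohort(make_eye_row(trt = c(400, 300, 410, 310, 420, 320, 430, 330)))
  idx <- derive_indices(grid)
  expect_equal(idx$mean_trt, 365)
  expect_equal(idx$outer_trt, 415)
  expect_equal(idx$inner_trt, 315)
  expect_equal(idx$superior_trt, 350)
  expect_equal(idx$mean_trt, (idx$outer_trt + idx$inner_trt) / 2)
})

test_that("indices equal brute-force means over available sectors", {
  set.seed(11)
  for (rep in 1:25) {
    v <- round(runif(8, 250, 550), 1)
    n_miss <- sample(0:2, 1)
    if (n_miss > 0) v[sample(8, n_miss)] <- NA
    cohort <- make_cohort(make_eye_row(trt = v))
    idx <- derive_indices(cohort)
    brute <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    expect_equal(idx$mean_trt, brute(v))
    expect_equal(idx$outer_trt, brute(v[c(1, 3, 5, 7)]))
    expect_equal(idx$inner_trt, brute(v[c(2, 4, 6, 8)]))
    expect_equal(idx$nasal_trt, brute(v[3:4]))
    expect_equal(idx$availability_fraction, sum(!is.na(v)) / 8)
  }
  # all-missing ring gives a missing index, not zero
  v <- c(400, NA, 410, NA, 420, NA, 430, NA)
  idx <- derive_indices(make_cohort(make_eye_row(trt = v)))
  expect_true(is.na(idx$inner_trt))
  expect_equal(idx$outer_trt, 415)
})

test_that("sector volume follows the annulus-quadrant geometry", {
  expect_equal(sector_area("inner"), pi * (1^2 - 0.5^2) / 4)
  expect_equal(sector_area("outer"), pi * (1.5^2 - 1^2) / 4)
  expect_equal(sector_area("inner"), 0.5890, tolerance = 1e-4)
  expect_equal(sector_area("outer"), 0.9817, tolerance = 1e-4)
  expect_equal(sector_volume_from_thickness(378, "inner"), 0.378 * 0.58905,
               tolerance = 1e-4)
  # a 378 um retina implies ~0.297 mm^3 mean sector volume, consistent with
  # normative medians (thickness ~378 um alongside volume ~0.29 mm^3)
  v <- mean(c(sector_volume_from_thickness(378, "inner"),
              sector_volume_from_thickness(378, "outer")))
  expect_equal(v, 0.297, tolerance = 0.002)
})

test_that("analysis-eye selection applies the group-specific rules", {
  # control: right eye when both are valid
  ctl <- make_cohort(make_eye_row("S1", eye = "OD", trt = 380),
                     make_eye_row("S1", eye = "OS", trt = 420))
  expect_equal(select_analysis_eye(ctl)$eye, "OD")
  # control: left eye when the right scan fails quality
  ctl2 <- make_cohort(
    make_eye_row("S1", eye = "OD", trt = c(380, 380, 380, NA, NA, NA, NA, NA)),
    make_eye_row("S1", eye = "OS", trt = 420))
  expect_equal(select_analysis_eye(ctl2)$eye, "OS")
  # patient: eye with the larger mean thickness
  pat <- make_cohort(
    make_eye_row("P1", group = "sagittal", eye = "OD", trt = 400),
    make_eye_row("P1", group = "sagittal", eye = "OS", trt = 420))
  expect_equal(select_analysis_eye(pat)$eye, "OS")
  # no eligible eye: dropped with a reason
  gone <- make_cohort(
    make_eye_row("S9", eye = "OD", trt = c(380, 380, 380, NA, NA, NA, NA, NA)))
  sel <- select_analysis_eye(gone)
  expect_equal(nrow(sel), 0)
  expect_match(attr(sel, "dropped")$reason, "quality")
})
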