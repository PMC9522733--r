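#' Pipeline run configuration
#'
#' Collects everything one screening run needs: input paths (or generator
#' settings when simulating), bootstrap settings, the overall-OCT logic and
#' the output directory. Round-trips losslessly through YAML/JSON via
#' [read_run_config()] / [write_run_config()].
#'
#' @param cohort_path Cohort CSV, or `NULL` to simulate.
#' @param trajectories_path OFC trajectory CSV, or `NULL`.
#' @param growth_reference_path Growth-reference CSV, or `NULL` for the
#'   packaged synthetic reference.
#' @param cutoffs_path Manual cut-off CSV (`parameter`, `lower`, `upper`),
#'   or `NULL` to derive cut-offs from the control cohort.
#' @param generator Named list of [generator_config()] overrides (used when
#'   `cohort_path` is `NULL`).
#' @param coverage RI central coverage.
#' @param n_bootstrap Bootstrap resamples.
#' @param seed Master seed for every stochastic stage.
#' @param oct_logic `"or"` or `"and"` for the overall OCT status.
#' @param output_dir Directory for rendered tables, or `NULL` to skip
#'   writing.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort_path = NULL, trajectories_path = NULL,
                       growth_reference_path = NULL, cutoffs_path = NULL,
                       generator = list(), coverage = 0.95,
                       n_bootstrap = 2000, seed = 1,
                       oct_logic = c("or", "and"), output_dir = NULL) {
  oct_logic <- match.arg(oct_logic)
  if (is.null(cohort_path) && length(generator) == 0) generator <- list()
  if (!is.null(cohort_path) && !file.exists(cohort_path))
    stop("cohort file not found: ", cohort_path, call. = FALSE)
  if (is.null(seed)) stop("run config requires a seed", call. = FALSE)
  structure(list(cohort_path = cohort_path,
                 trajectories_path = trajectories_path,
                 growth_reference_path = growth_reference_path,
                 cutoffs_path = cutoffs_path, generator = generator,
                 coverage = coverage, n_bootstrap = n_bootstrap,
                 seed = seed, oct_logic = oct_logic,
                 output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML (or JSON) file with run-config fields.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.assoc_row <- function(comparison, t) {
  fr <- fisher_exact(t)
  data.frame(comparison = comparison, a = t$a, b = t$b, c = t$c, d = t$d,
             or_cmle = fr$or_cmle, or_sample = fr$or_sample,
             ci_low = fr$ci[1], ci_high = fr$ci[2], p = fr$p_value,
             stringsAsFactors = FALSE)
}

# cross-tab of one flag column (increased vs not) against papilledema;
# rows: (no papilledema, papilledema), cols: (not increased, increased)
.flag_vs_papilledema <- function(flags, fundo, flag_col) {
  f <- flags[[flag_col]]
  ok <- f != "missing"
  f <- f[ok]; pd <- fundo[ok] == "papilledema"
  inc <- f == "increased"
  table2x2(sum(!pd & !inc), sum(!pd & inc), sum(pd & !inc), sum(pd & inc))
}

#' Run the full screening pipeline
#'
#' Executes the end-to-end analysis: (optional) simulation, quality
#' filtering and eye selection, normative reference intervals and covariate
#' screening on the controls, cut-off classification of the patients,
#' clinical signs, and all association tests. Deterministic given the
#' config. When `config$output_dir` is set the rendered tables and a run
#' log are written there.
#'
#' @param config A [run_config()].
#' @return List: `cohort`, `truth` (simulated runs only), `trajectories`,
#'   `covariate_screen` (Table-1-shaped), `reference_intervals`
#'   (Table-2-shaped), `cutoffs`, `flags`, `fundoscopy_assoc`
#'   (Table-3-shaped), `sign_assoc` (Table-4-shaped), `quadrant_assoc`
#'   (Table-5-shaped), `group_comparison`, `eye_comparison`, `log`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  say("seed: %d", config$seed)

  truth <- NULL
  if (is.null(config$cohort_path)) {
    gcfg <- do.call(generator_config,
                    c(config$generator,
                      if (!"seed" %in% names(config$generator))
                        list(seed = config$seed)))
    sim <- generate_cohort(gcfg)
    cohort <- sim$cohort
    truth <- sim$truth
    say("simulated cohort: %d controls, %d patients",
        gcfg$n_controls, gcfg$n_patients)
  } else {
    cohort <- read_cohort(config$cohort_path)
    say("read cohort: %s (%d rows)", config$cohort_path, nrow(cohort))
  }
  growth_ref <- if (is.null(config$growth_reference_path))
    synthetic_growth_reference()
  else utils::read.csv(config$growth_reference_path,
                       stringsAsFactors = FALSE)
  trajectories <- if (!is.null(config$trajectories_path)) {
    utils::read.csv(config$trajectories_path, stringsAsFactors = FALSE,
                    colClasses = c(subject_id = "character"))
  } else if (!is.null(truth)) {
    gcfg <- do.call(generator_config,
                    c(config$generator,
                      if (!"seed" %in% names(config$generator))
                        list(seed = config$seed)))
    generate_trajectories(gcfg, truth, growth_ref)
  } else NULL

  n_scans <- nrow(cohort)
  keep <- quality_filter(cohort)
  say("quality filter: %d of %d scans kept (<6 of 8 sectors excluded: %d)",
      sum(keep), n_scans, sum(!keep))

  has_controls <- any(cohort$group == "control")
  if (!has_controls && is.null(config$cutoffs_path))
    stop("pipeline aborted at stage 'cutoffs': no control cohort and no ",
         "cut-offs file", call. = FALSE)

  ri <- NULL
  screen <- NULL
  if (has_controls) {
    ri <- reference_interval_table(cohort, coverage = config$coverage,
                                   n_bootstrap = config$n_bootstrap,
                                   seed = config$seed)
    say("reference intervals: %d parameters, control n = %d",
        nrow(ri), max(ri$n))
    screen <- lapply(c(mean_trt = "mean_trt", mean_trv = "mean_trv"),
                     function(oc) covariate_screen(cohort, oc,
                                                   seed = config$seed))
  }
  cutoffs <- if (!is.null(config$cutoffs_path)) {
    cf <- utils::read.csv(config$cutoffs_path, stringsAsFactors = FALSE)
    attr(cf, "provenance") <- "manual"
    cf
  } else {
    cutoffs_from_reference_intervals(ri)
  }

  flags <- classify_cohort(cohort, cutoffs, logic = config$oct_logic)
  dropped <- attr(flags, "dropped")
  if (nrow(dropped) > 0)
    say("eye selection dropped %d patient(s): %s", nrow(dropped),
        paste(dropped$subject_id, collapse = ", "))
  say("classified %d patients (overall OCT abnormal: %d)", nrow(flags),
      sum(flags$overall_oct == "abnormal"))

  patients <- cohort[cohort$group == "sagittal", , drop = FALSE]
  pat_eye <- select_analysis_eye(patients)
  fundo <- pat_eye$fundoscopy[match(flags$subject_id, pat_eye$subject_id)]

  # primary association (pseudopapilledema retained): fundoscopy cross-tabs
  fundoscopy_assoc <- rbind(
    .assoc_row("mean_trt_vs_papilledema",
               .flag_vs_papilledema(flags, fundo, "flag_mean_trt")),
    .assoc_row("mean_trv_vs_papilledema",
               .flag_vs_papilledema(flags, fundo, "flag_mean_trv")))

  # secondary associations exclude pseudopapilledema
  flags2 <- apply_pseudopapilledema_exclusion(flags)
  say("pseudopapilledema exclusion: %d excluded, secondary N = %d",
      attr(flags2, "n_excluded"), nrow(flags2))
  fundo2 <- fundo[match(flags2$subject_id, flags$subject_id)]

  signs <- clinical_signs_table(patients, trajectories, growth_ref)
  signs$papilledema <- as.integer(
    pat_eye$fundoscopy[match(signs$subject_id, pat_eye$subject_id)] ==
      "papilledema")
  sign_assoc <- do.call(rbind, lapply(
    c("growth_arrest", "fingerprint", "papilledema", "headache"),
    function(s) {
      t <- tryCatch(build_2x2(flags2, signs, s), error = function(e) NULL)
      if (is.null(t)) {
        say("sign '%s' skipped: no subjects with both values", s)
        return(NULL)
      }
      .assoc_row(paste0("abnormal_oct_vs_", s), t)
    }))

  ring_quadrant <- c("outer", "inner", .quadrants)
  quadrant_assoc <- do.call(rbind, lapply(c("trt", "trv"), function(ms) {
    do.call(rbind, lapply(ring_quadrant, function(rq) {
      col <- paste0("flag_", rq, "_", ms)
      if (!col %in% names(flags2)) return(NULL)
      .assoc_row(paste0(rq, "_", ms, "_vs_papilledema"),
                 .flag_vs_papilledema(flags2, fundo2, col))
    }))
  }))

  group_comparison <- eye_comparison <- NULL
  if (has_controls) {
    ctl_eye <- select_analysis_eye(cohort[cohort$group == "control", ,
                                          drop = FALSE])
    ctl_idx <- derive_indices(ctl_eye)
    pat_idx <- derive_indices(pat_eye)
    group_comparison <- do.call(rbind, lapply(
      c("mean_trt", "mean_trv"), function(p) {
        w <- wilcoxon_rank_sum(ctl_idx[[p]], pat_idx[[p]])
        data.frame(parameter = p,
                   control_median = stats::median(ctl_idx[[p]], na.rm = TRUE),
                   patient_median = stats::median(pat_idx[[p]], na.rm = TRUE),
                   W = w$statistic, p = w$p_value, stringsAsFactors = FALSE)
      }))
    controls <- cohort[cohort$group == "control", , drop = FALSE]
    controls <- controls[quality_filter(controls), , drop = FALSE]
    ci <- derive_indices(controls)
    wide <- merge(ci[controls$eye == "OD", c("subject_id", "mean_trt", "mean_trv")],
                  ci[controls$eye == "OS", c("subject_id", "mean_trt", "mean_trv")],
                  by = "subject_id", suffixes = c("_od", "_os"))
    eye_comparison <- do.call(rbind, lapply(c("mean_trt", "mean_trv"),
      function(p) {
        pt <- paired_t(wide[[paste0(p, "_od")]], wide[[paste0(p, "_os")]])
        data.frame(parameter = p, t = pt$t, df = pt$df, p = pt$p_value,
                   mean_difference = pt$mean_difference, n = pt$n,
                   stringsAsFactors = FALSE)
      }))
  }

  results <- list(cohort = cohort, truth = truth,
                  trajectories = trajectories,
                  covariate_screen = screen, reference_intervals = ri,
                  cutoffs = cutoffs, flags = flags,
                  fundoscopy_assoc = fundoscopy_assoc,
                  sign_assoc = sign_assoc,
                  quadrant_assoc = quadrant_assoc,
                  group_comparison = group_comparison,
                  eye_comparison = eye_comparison, log = log)
  if (!is.null(config$output_dir)) render_tables(results, config$output_dir)
  results
}

.round_df <- function(df, digits) {
  for (nm in names(digits)) {
    if (nm %in% names(df)) df[[nm]] <- round(df[[nm]], digits[[nm]])
  }
  df
}

#' Render the pipeline results as CSV files
#'
#' Writes the covariate screen, normative reference intervals, the three
#' association tables, the group/eye comparisons and a run log. Odds
#' ratios are printed at 2 decimals; thickness endpoints at 1 decimal and
#' volume endpoints at 2.
#'
#' @param results Output of [run_pipeline()].
#' @param output_dir Directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
render_tables <- function(results, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) {
    utils::write.csv(df, file.path(output_dir, file), row.names = FALSE,
                     na = "")
  }
  if (!is.null(results$covariate_screen)) {
    scr <- do.call(rbind, lapply(names(results$covariate_screen), function(oc) {
      cf <- results$covariate_screen[[oc]]$coefficients
      cf <- cf[cf$term != "(Intercept)", , drop = FALSE]
      cbind(outcome = oc, cf)
    }))
    wr(.round_df(scr, c(estimate = 3, ci_low = 3, ci_high = 3, p_value = 3)),
       "table1_covariate_screen.csv")
  }
  if (!is.null(results$reference_intervals)) {
    ri <- results$reference_intervals
    trv <- grepl("trv", ri$parameter)
    num <- c("lower_ri", "lower_ci_low", "lower_ci_high",
             "upper_ri", "upper_ci_low", "upper_ci_high")
    ri[trv, num] <- round(ri[trv, num], 2)
    ri[!trv, num] <- round(ri[!trv, num], 1)
    wr(ri, "table2_reference_intervals.csv")
  }
  digits_assoc <- c(or_cmle = 2, or_sample = 2, ci_low = 2, ci_high = 2,
                    p = 4)
  empty_assoc <- data.frame(comparison = character(0), a = integer(0),
                            b = integer(0), c = integer(0), d = integer(0),
                            or_cmle = numeric(0), or_sample = numeric(0),
                            ci_low = numeric(0), ci_high = numeric(0),
                            p = numeric(0))
  assoc_or_empty <- function(x) if (is.null(x)) empty_assoc else
    .round_df(x, digits_assoc)
  wr(assoc_or_empty(results$fundoscopy_assoc),
     "table3_fundoscopy_association.csv")
  wr(assoc_or_empty(results$sign_assoc),
     "table4_clinical_sign_association.csv")
  wr(assoc_or_empty(results$quadrant_assoc),
     "table5_quadrant_association.csv")
  if (!is.null(results$group_comparison))
    wr(results$group_comparison, "group_comparison.csv")
  if (!is.null(results$eye_comparison))
    wr(results$eye_comparison, "eye_comparison.csv")
  writeLines(results$log, file.path(output_dir, "run_log.txt"))
  invisible(output_dir)
}
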