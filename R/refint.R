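#' Empirical quantile by linear interpolation of order statistics
#'
#' The quantile at probability `q` is read at rank `1 + (n - 1) q` of the
#' sorted sample, linearly interpolating between adjacent order statistics
#' (the common statistical-software default). Stated explicitly because the
#' reference-interval endpoints depend on this convention.
#'
#' @param values Numeric sample (`NA` removed; must leave at least one).
#' @param q Probabilities in \[0, 1\] (vectorised).
#' @return Quantile value(s).
#' @export
#' @examples
#' empirical_quantile(1:101, 0.025)  # 3.5
empirical_quantile <- function(values, q) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("empty sample", call. = FALSE)
  stopifnot(all(q >= 0 & q <= 1))
  x <- sort(values)
  n <- length(x)
  h <- 1 + (n - 1) * q
  lo <- pmax(1L, floor(h)); hi <- pmin(n, ceiling(h))
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

#' Non-parametric bootstrap reference interval
#'
#' The point reference interval (RI) is the pair of empirical quantiles of
#' the observed sample at `(1 - coverage)/2` and `1 - (1 - coverage)/2`.
#' Each endpoint additionally carries its own 95% confidence interval,
#' obtained from the bootstrap distribution of that endpoint across
#' `n_bootstrap` resamples. By default the resamples are kernel-smoothed
#' (Gaussian noise at the Silverman bandwidth is added to each resampled
#' value) because the plain bootstrap distribution of an extreme order
#' statistic is too discrete for percentile CIs to reach nominal coverage
#' at reference-interval sample sizes; `ci_method = "percentile"` gives the
#' unsmoothed version.
#'
#' @param values Numeric sample; `NA`s are removed and counted.
#' @param coverage Central coverage of the RI (default 0.95).
#' @param n_bootstrap Number of bootstrap resamples (default 2000).
#' @param seed Integer seed; identical seed gives an identical result.
#' @param ci_method `"smoothed"` (default) or `"percentile"`.
#' @param conf_level Confidence level of the endpoint CIs (default 0.95).
#' @param parameter_id Optional label carried into the result.
#' @return Object of class `reference_interval`: list with `parameter_id`,
#'   `lower_ri`, `upper_ri`, `lower_ci`, `upper_ci` (length-2 each), `n`,
#'   `n_missing`, `n_bootstrap`, `coverage`, `seed`.
#' @export
bootstrap_reference_interval <- function(values, coverage = 0.95,
                                         n_bootstrap = 2000, seed = 1,
                                         ci_method = c("smoothed", "percentile"),
                                         conf_level = 0.95,
                                         parameter_id = NA_character_) {
  ci_method <- match.arg(ci_method)
  n_missing <- sum(is.na(values))
  x <- values[!is.na(values)]
  n <- length(x)
  if (n == 0) {
    return(structure(list(parameter_id = parameter_id, lower_ri = NA_real_,
                          upper_ri = NA_real_, lower_ci = c(NA_real_, NA_real_),
                          upper_ci = c(NA_real_, NA_real_), n = 0L,
                          n_missing = n_missing, n_bootstrap = n_bootstrap,
                          coverage = coverage, seed = seed),
                     class = "reference_interval"))
  }
  if (n < 20) stop("reference interval needs n >= 20 (got ", n, ")",
                   call. = FALSE)
  if (n < 40) warning("reference interval from n = ", n,
                      " < 40; endpoints will be imprecise", call. = FALSE)
  ql <- (1 - coverage) / 2
  qu <- 1 - ql
  lower_ri <- empirical_quantile(x, ql)
  upper_ri <- empirical_quantile(x, qu)

  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  bm <- matrix(sample(x, n * n_bootstrap, replace = TRUE), nrow = n)
  if (ci_method == "smoothed" && stats::sd(x) > 0) {
    h <- 0.9 * min(stats::sd(x), stats::IQR(x) / 1.34) * n^(-1 / 5)
    bm <- bm + stats::rnorm(length(bm), 0, h)
  }
  bl <- apply(bm, 2, empirical_quantile, q = ql)
  bu <- apply(bm, 2, empirical_quantile, q = qu)
  al <- (1 - conf_level) / 2
  structure(list(parameter_id = parameter_id,
                 lower_ri = lower_ri, upper_ri = upper_ri,
                 lower_ci = unname(empirical_quantile(bl, c(al, 1 - al))),
                 upper_ci = unname(empirical_quantile(bu, c(al, 1 - al))),
                 n = n, n_missing = n_missing, n_bootstrap = n_bootstrap,
                 coverage = coverage, seed = seed),
            class = "reference_interval")
}

#' @export
print.reference_interval <- function(x, ...) {
  cat(sprintf(
    "Reference interval%s: [%.4g, %.4g] (%.0f%% coverage, n = %d)\n",
    if (is.na(x$parameter_id)) "" else paste0(" for ", x$parameter_id),
    x$lower_ri, x$upper_ri, 100 * x$coverage, x$n))
  cat(sprintf("  lower endpoint 95%% CI: [%.4g, %.4g]\n",
              x$lower_ci[1], x$lower_ci[2]))
  cat(sprintf("  upper endpoint 95%% CI: [%.4g, %.4g]\n",
              x$upper_ci[1], x$upper_ci[2]))
  invisible(x)
}

#' Normative reference-interval table for a control cohort
#'
#' Computes the bootstrap reference interval for every grid parameter
#' (mean, rings, quadrants and sectors, for thickness and volume) of the
#' control analysis eyes. Parameters with fewer than 20 non-missing values
#' are reported with `NA` endpoints and their missing count.
#'
#' @param cohort Cohort data frame; only `group == "control"` rows are used,
#'   quality-filtered and reduced to one analysis eye per subject.
#' @param coverage,n_bootstrap,ci_method,conf_level Passed to
#'   [bootstrap_reference_interval()].
#' @param seed Master seed; parameter k uses seed + k.
#' @return Data frame, one row per parameter: `parameter`, `lower_ri`,
#'   `lower_ci_low`, `lower_ci_high`, `upper_ri`, `upper_ci_low`,
#'   `upper_ci_high`, `n`, `n_missing`.
#' @export
reference_interval_table <- function(cohort, coverage = 0.95,
                                     n_bootstrap = 2000, seed = 1,
                                     ci_method = "smoothed",
                                     conf_level = 0.95) {
  controls <- cohort[cohort$group == "control", , drop = FALSE]
  if (nrow(controls) == 0) stop("no control rows in cohort", call. = FALSE)
  eye <- select_analysis_eye(controls)
  vals <- parameter_values(eye)
  params <- index_parameters()
  rows <- lapply(seq_along(params), function(k) {
    p <- params[k]
    v <- vals[[p]]
    ri <- if (sum(!is.na(v)) >= 20) {
      bootstrap_reference_interval(v, coverage, n_bootstrap,
                                   seed = seed + k, ci_method = ci_method,
                                   conf_level = conf_level, parameter_id = p)
    } else {
      structure(list(parameter_id = p, lower_ri = NA_real_,
                     upper_ri = NA_real_, lower_ci = c(NA_real_, NA_real_),
                     upper_ci = c(NA_real_, NA_real_), n = sum(!is.na(v)),
                     n_missing = sum(is.na(v)), n_bootstrap = n_bootstrap,
                     coverage = coverage, seed = seed + k),
                class = "reference_interval")
    }
    data.frame(parameter = p, lower_ri = ri$lower_ri,
               lower_ci_low = ri$lower_ci[1], lower_ci_high = ri$lower_ci[2],
               upper_ri = ri$upper_ri,
               upper_ci_low = ri$upper_ci[1], upper_ci_high = ri$upper_ci[2],
               n = ri$n, n_missing = ri$n_missing, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Shapiro-Wilk normality assessment
#'
#' Advisory normality check for a parameter's control distribution; it does
#' not gate the non-parametric reference interval. Degenerate (constant)
#' samples are reported as not applicable rather than an error.
#'
#' @param values Numeric sample, 3 <= n <= 5000 after `NA` removal.
#' @return List with `W`, `p_value`, `n`, `applicable`.
#' @export
assess_normality <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(list(W = NA_real_, p_value = NA_real_, n = n, applicable = FALSE))
  }
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p_value = sw$p.value, n = n,
       applicable = TRUE)
}
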