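#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sample rank-sum test (midranks for ties). Uses exact enumeration
#' when both samples are small (n <= 10) and tie-free, otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction.
#'
#' @param x,y Numeric samples (`NA` removed).
#' @return List with `statistic` (W), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) > 0, length(y) > 0)
  exact <- length(x) <= 10 && length(y) <= 10 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Paired t-test between right and left eyes
#'
#' Standard paired t-test on within-subject differences; pairs with a
#' missing member are dropped. Zero-variance differences are reported with
#' p = 1 and a degeneracy flag rather than an error.
#'
#' @param x_right,x_left Paired measurements (equal length).
#' @return List with `t`, `df`, `p_value`, `mean_difference`, `n`,
#'   `degenerate`.
#' @export
paired_t <- function(x_right, x_left) {
  stopifnot(length(x_right) == length(x_left))
  ok <- !is.na(x_right) & !is.na(x_left)
  d <- x_right[ok] - x_left[ok]
  n <- length(d)
  if (n < 3) stop("paired t-test needs at least 3 complete pairs",
                  call. = FALSE)
  if (stats::sd(d) == 0) {
    # identical pairs: no evidence of a difference; constant nonzero shift:
    # certain difference (t degenerates to +/-Inf)
    return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                df = n - 1, p_value = if (mean(d) == 0) 1 else 0,
                mean_difference = mean(d), n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(x_right[ok], x_left[ok], paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = unname(tt$estimate), n = n,
       degenerate = FALSE)
}
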