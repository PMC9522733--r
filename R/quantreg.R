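#' Quantile regression by iteratively reweighted least squares
#'
#' Fits linear quantile regression at level `tau` by minimising the check
#' loss sum rho_tau(y - X beta), rho_tau(u) = u (tau - 1\{u < 0\}), via
#' epsilon-regularised iteratively reweighted least squares. Coefficient
#' confidence intervals and p-values come from a seeded case-resampling
#' bootstrap (percentile CI; p = smallest level at which 0 leaves the
#' interval).
#'
#' @param data Data frame containing the outcome and covariates.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of covariate column names (numeric or
#'   two-level factor/character; rows with missing values are dropped).
#' @param tau Quantile level in (0, 1); default 0.5 (median regression).
#' @param n_bootstrap Bootstrap resamples for inference (default 500; 0
#'   skips inference).
#' @param seed Seed for the bootstrap.
#' @param conf_level CI level (default 0.95).
#' @return Object of class `quantreg_fit`: list with `coefficients` (data
#'   frame: `term`, `estimate`, `ci_low`, `ci_high`, `p_value`), `tau`,
#'   `n`, `loss`.
#' @export
quantile_regression_fit <- function(data, outcome, covariates, tau = 0.5,
                                    n_bootstrap = 500, seed = 1,
                                    conf_level = 0.95) {
  stopifnot(tau > 0, tau < 1)
  cols <- c(outcome, covariates)
  stopifnot(all(cols %in% names(data)))
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  n <- nrow(d)
  if (n < 10 * length(covariates))
    stop("quantile regression needs at least 10 rows per covariate (",
         n, " complete rows for ", length(covariates), " covariates)",
         call. = FALSE)
  X <- cbind(`(Intercept)` = 1)
  for (cv in covariates) {
    v <- d[[cv]]
    if (!is.numeric(v)) {
      lev <- sort(unique(as.character(v)))
      if (length(lev) != 2)
        stop("covariate ", cv, " must be numeric or two-level", call. = FALSE)
      nm <- paste0(cv, "_", lev[2])
      col <- as.numeric(as.character(v) == lev[2])
      X <- cbind(X, stats::setNames(data.frame(col), nm))
    } else {
      X <- cbind(X, stats::setNames(data.frame(v), cv))
    }
  }
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    cors <- suppressWarnings(stats::cor(X[, -1, drop = FALSE]))
    diag(cors) <- 0
    worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
    stop("collinear covariates: ", dep[1], " (strongest dependence between ",
         rownames(cors)[worst[1]], " and ", colnames(cors)[worst[2]], ")",
         call. = FALSE)
  }
  y <- d[[outcome]]
  beta <- .qr_irls(X, y, tau)
  res <- y - drop(X %*% beta)
  loss <- sum(res * (tau - (res < 0)))

  coefs <- data.frame(term = colnames(X), estimate = unname(beta),
                      ci_low = NA_real_, ci_high = NA_real_,
                      p_value = NA_real_, stringsAsFactors = FALSE)
  if (n_bootstrap > 0) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed %% 2147483647))
    B <- matrix(NA_real_, n_bootstrap, ncol(X))
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      if (qr(Xb)$rank < ncol(Xb)) next
      B[b, ] <- .qr_irls(Xb, y[idx], tau)
    }
    al <- (1 - conf_level) / 2
    for (j in seq_len(ncol(X))) {
      bj <- B[, j][!is.na(B[, j])]
      coefs$ci_low[j] <- empirical_quantile(bj, al)
      coefs$ci_high[j] <- empirical_quantile(bj, 1 - al)
      frac <- min(mean(bj <= 0), mean(bj >= 0))
      coefs$p_value[j] <- min(1, 2 * max(frac, 1 / length(bj)))
    }
  }
  structure(list(coefficients = coefs, tau = tau, n = n, loss = loss),
            class = "quantreg_fit")
}

# epsilon-IRLS for the check loss; eps scaled to the response spread
.qr_irls <- function(X, y, tau, max_iter = 200, tol = 1e-8) {
  beta <- qr.solve(X, y)  # LS start
  eps <- 1e-6 * max(stats::sd(y), 1e-12)
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    w <- ifelse(r >= 0, tau, 1 - tau) / pmax(abs(r), eps)
    fit <- stats::lm.wfit(X, y, w)
    new_beta <- fit$coefficients
    if (max(abs(new_beta - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  beta
}

#' @export
print.quantreg_fit <- function(x, ...) {
  cat(sprintf("Quantile regression (tau = %.2f, n = %d)\n", x$tau, x$n))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Covariate screening for the normative cohort
#'
#' Median regression of a control-cohort OCT index on age (years), sex
#' (male vs female) and mild refractive error (diopters): the screen used
#' to justify pooling the normative cohort when none of the covariates
#' shows an effect.
#'
#' @param cohort Cohort data frame; control analysis eyes are used.
#' @param outcome `"mean_trt"` or `"mean_trv"` (or any derived index name).
#' @param tau,n_bootstrap,seed,conf_level Passed to
#'   [quantile_regression_fit()].
#' @return A `quantreg_fit`.
#' @export
covariate_screen <- function(cohort, outcome = "mean_trt", tau = 0.5,
                             n_bootstrap = 500, seed = 1, conf_level = 0.95) {
  controls <- cohort[cohort$group == "control", , drop = FALSE]
  eye <- select_analysis_eye(controls)
  d <- derive_indices(eye)
  d$age_years <- eye$age_years
  d$sex <- eye$sex
  d$re_diopters <- eye$re_diopters
  quantile_regression_fit(d, outcome, c("age_years", "sex", "re_diopters"),
                          tau = tau, n_bootstrap = n_bootstrap, seed = seed,
                          conf_level = conf_level)
}
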