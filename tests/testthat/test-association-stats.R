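test_that("noncentral hypergeometric pmf has the defining properties", {
  # psi = 1 reduces to the central hypergeometric
  for (m in list(c(8, 5, 6), c(10, 10, 7), c(3, 9, 3))) {
    supp <- max(0, m[3] - m[2]):min(m[3], m[1])
    expect_equal(nchg_pmf(supp, m[1], m[2], m[3], 1),
                 dhyper(supp, m[1], m[2], m[3]), tolerance = 1e-12)
  }
  # normalises over the support for random margins and psi
  set.seed(14)
  for (rep in 1:30) {
    m1 <- sample(0:15, 1); m2 <- sample(0:15, 1)
    n1 <- sample(0:(m1 + m2), 1)
    psi <- exp(runif(1, -3, 3))
    supp <- max(0, n1 - m2):min(n1, m1)
    expect_equal(sum(nchg_pmf(supp, m1, m2, n1, psi)), 1, tolerance = 1e-12)
  }
  # mass concentrates at the support maximum as psi grows
  expect_equal(nchg_pmf(5, 5, 5, 5, 1e12), 1, tolerance = 1e-6)
  # outside the support the mass is zero, not an error
  expect_equal(nchg_pmf(c(-1, 99), 5, 5, 5, 2), c(0, 0))
})

test_that("conditional-MLE odds ratio solves the conditional score equation", {
  expect_equal(fisher_cmle_or(table2x2(5, 5, 5, 5)), 1)
  expect_equal(fisher_cmle_or(table2x2(76, 13, 1, 3)), 16.7, tolerance = 0.01)
  # grid-search oracle: maximise the conditional likelihood directly
  cond_loglik <- function(psi, t) {
    supp <- max(0, (t$a + t$c) - (t$c + t$d)):min(t$a + t$c, t$a + t$b)
    lp <- lchoose(t$a + t$b, supp) + lchoose(t$c + t$d, (t$a + t$c) - supp) +
      supp * log(psi)
    (lchoose(t$a + t$b, t$a) + lchoose(t$c + t$d, t$c) + t$a * log(psi)) -
      (max(lp) + log(sum(exp(lp - max(lp)))))
  }
  t <- table2x2(3, 2, 1, 4)
  grid <- exp(seq(log(0.01), log(100), length.out = 20001))
  oracle <- grid[which.max(vapply(grid, cond_loglik, numeric(1), t = t))]
  expect_equal(fisher_cmle_or(t), oracle, tolerance = 5e-3)
  # row swap inverts the odds ratio (tight root tolerance for the identity)
  expect_equal(fisher_cmle_or(table2x2(1, 4, 3, 2), tol = 1e-12),
               1 / fisher_cmle_or(t, tol = 1e-12), tolerance = 1e-8)
  # strictly increasing in the diagonal count within the support interior
  ors <- vapply(1:5, function(a) fisher_cmle_or(table2x2(a, 6 - a, 3, 3)),
                numeric(1))
  expect_true(all(diff(ors) > 0))
  # boundary counts give 0 / infinity
  expect_equal(fisher_cmle_or(table2x2(0, 5, 5, 0)), 0)
  expect_equal(fisher_cmle_or(table2x2(5, 0, 0, 5)), Inf)
  # degenerate margin: not applicable
  expect_true(is.na(fisher_cmle_or(table2x2(0, 0, 3, 4))))
})

test_that("conditional MLE agrees with the reference implementation", {
  set.seed(15)
  for (rep in 1:40) {
    t <- rpois(4, 6)
    if (any(rowSums(matrix(t, 2, byrow = TRUE)) == 0) ||
        any(colSums(matrix(t, 2, byrow = TRUE)) == 0)) next
    tt <- table2x2(t[1], t[2], t[3], t[4])
    ft <- fisher.test(matrix(t, 2, 2, byrow = TRUE))
    mine <- fisher_cmle_or(tt)
    if (is.finite(mine) && ft$estimate > 0 && is.finite(ft$estimate)) {
      expect_equal(unname(log(mine)), unname(log(ft$estimate)),
                   tolerance = 1e-6)
    }
    expect_equal(fisher_two_sided_p(tt), ft$p.value, tolerance = 1e-9)
  }
})

test_that("exact confidence intervals invert their defining tests", {
  t <- table2x2(76, 13, 1, 3)
  ci <- fisher_exact_ci(t)  # two-sided point-probability inversion
  expect_equal(ci[1], 1.71, tolerance = 0.01)
  expect_equal(ci[2], 458.2, tolerance = 0.15)
  # at each bound the two-sided p equals alpha (brute-force check)
  p_at <- function(psi) {
    supp <- 73:77
    lp <- lchoose(89, supp) + lchoose(4, 77 - supp) + supp * log(psi)
    p <- exp(lp - max(lp)); p <- p / sum(p)
    sum(p[p <= p[supp == 76] * (1 + 1e-7)])
  }
  expect_equal(p_at(ci[1]), 0.05, tolerance = 1e-6)
  expect_equal(p_at(ci[2]), 0.05, tolerance = 1e-6)
  # central method: one-sided tails at alpha/2 (summation oracle)
  cic <- fisher_exact_ci(t, method = "central")
  tail_ge <- function(psi) {
    supp <- 73:77
    lp <- lchoose(89, supp) + lchoose(4, 77 - supp) + supp * log(psi)
    p <- exp(lp - max(lp)); p <- p / sum(p)
    sum(p[supp >= 76])
  }
  tail_le <- function(psi) {
    supp <- 73:77
    lp <- lchoose(89, supp) + lchoose(4, 77 - supp) + supp * log(psi)
    p <- exp(lp - max(lp)); p <- p / sum(p)
    sum(p[supp <= 76])
  }
  expect_equal(tail_ge(cic[1]), 0.025, tolerance = 1e-6)
  expect_equal(tail_le(cic[2]), 0.025, tolerance = 1e-6)
  # boundary tables give one-sided intervals
  expect_equal(fisher_exact_ci(table2x2(0, 5, 5, 2))[1], 0)
  expect_equal(fisher_exact_ci(table2x2(5, 0, 2, 5))[2], Inf)
})

test_that("two-sided exact p-value matches enumeration and symmetry", {
  expect_equal(fisher_two_sided_p(table2x2(5, 5, 5, 5)), 1)
  # transpose invariance
  t <- table2x2(7, 2, 3, 9)
  expect_equal(fisher_two_sided_p(t),
               fisher_two_sided_p(table2x2(7, 3, 2, 9)), tolerance = 1e-12)
  # enumeration oracle on small margins
  set.seed(16)
  for (rep in 1:30) {
    m1 <- sample(1:9, 1); m2 <- sample(1:9, 1); n1 <- sample(1:(m1 + m2), 1)
    supp <- max(0, n1 - m2):min(n1, m1)
    if (length(supp) == 1) next  # degenerate margin: p not applicable
    a <- supp[sample.int(length(supp), 1)]
    t <- table2x2(a, m1 - a, n1 - a, m2 - (n1 - a))
    probs <- dhyper(supp, m1, m2, n1)
    oracle <- sum(probs[probs <= probs[supp == a] * (1 + 1e-7)])
    expect_equal(fisher_two_sided_p(t), min(1, oracle), tolerance = 1e-12)
  }
})

test_that("2x2 builder fixes orientation and handles missing signs pairwise", {
  flags <- data.frame(
    subject_id = sprintf("P%02d", 1:88),
    overall_oct = rep(c("normal", "abnormal"), c(74, 14)),
    stringsAsFactors = FALSE)
  signs <- data.frame(
    subject_id = flags$subject_id,
    growth_arrest = c(rep(c(1L, 0L), c(2, 72)), rep(c(1L, 0L), c(4, 10))),
    headache = NA_integer_,
    stringsAsFactors = FALSE)
  t <- build_2x2(flags, signs, "growth_arrest")
  expect_equal(c(t$a, t$b, t$c, t$d), c(72, 2, 10, 4))
  expect_equal(fisher_cmle_or(t), 13.65, tolerance = 0.01)
  # all-missing sign errors
  expect_error(build_2x2(flags, signs, "headache"), "no subjects")
  # pairwise deletion: one subject missing this sign still leaves the rest
  signs$growth_arrest[1] <- NA
  t2 <- build_2x2(flags, signs, "growth_arrest")
  expect_equal(t2$a + t2$b + t2$c + t2$d, 87)
})

test_that("rank-sum comparison uses exact enumeration for small samples", {
  # identical samples carry no evidence
  expect_equal(wilcoxon_rank_sum(c(1, 3, 5), c(1, 3, 5))$p_value, 1,
               tolerance = 1e-9)
  # exact p equals full permutation enumeration
  set.seed(17)
  for (rep in 1:5) {
    x <- round(rnorm(4, 0, 5), 3)
    y <- round(rnorm(5, 1, 5), 3)
    res <- wilcoxon_rank_sum(x, y)
    expect_equal(res$method, "exact")
    pooled <- c(x, y)
    stats_all <- combn(9, 4, function(ix) {
      sum(rank(pooled)[ix]) - 4 * 5 / 2
    })
    obs <- sum(rank(pooled)[1:4]) - 4 * 5 / 2
    oracle <- mean(abs(stats_all - 10) >= abs(obs - 10) - 1e-12)
    expect_equal(res$p_value, oracle, tolerance = 1e-9)
  }
  # control vs patient separation at the default generator settings
  sim <- generate_cohort(generator_config(seed = 18))
  ctl <- derive_indices(select_analysis_eye(
    sim$cohort[sim$cohort$group == "control", ]))
  pat <- derive_indices(select_analysis_eye(
    sim$cohort[sim$cohort$group == "sagittal", ]))
  expect_lt(wilcoxon_rank_sum(ctl$mean_trt, pat$mean_trt)$p_value, 0.001)
  expect_lt(wilcoxon_rank_sum(ctl$mean_trv, pat$mean_trv)$p_value, 0.001)
})

test_that("paired eye comparison matches the textbook t statistic", {
  expect_equal(paired_t(c(1, 2, 3, 4), c(1, 2, 3, 4))$t, 0)
  expect_equal(paired_t(c(1, 2, 3, 4), c(1, 2, 3, 4))$p_value, 1)
  expect_lt(paired_t(seq(1, 30) + 10, seq(1, 30))$p_value, 0.001)
  set.seed(19)
  x <- rnorm(25, 400, 30); y <- x + rnorm(25, 2, 5)
  res <- paired_t(x, y)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(25))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 24), tolerance = 1e-12)
})
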