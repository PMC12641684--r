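test_that("Friedman statistic matches the rank formula and base R", {
  # identical treatments in every block
  X <- matrix(5, 4, 3)
  fr <- friedman_test(X)
  expect_equal(fr$chi2, 0)
  expect_equal(fr$p, 1)

  # fixed rank pattern: two blocks, ranks (1,2,3) in both
  X2 <- matrix(c(1, 2, 3, 1, 2, 3), 2, byrow = TRUE)
  expect_equal(friedman_test(X2)$chi2, 4)

  set.seed(51)
  for (i in 1:10) {
    M <- matrix(rnorm(5 * 4), 5, 4)
    ours <- friedman_test(M)
    ref <- stats::friedman.test(M)
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Friedman p-values agree with the exhaustive permutation null", {
  # n = 3 blocks, k = 3: enumerate all (3!)^3 within-block rank orders
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  stats_null <- c()
  for (a in 1:6) for (b in 1:6) for (cc in 1:6) {
    M <- rbind(perms[a, ], perms[b, ], perms[cc, ])
    stats_null <- c(stats_null, friedman_test(M)$chi2)
  }
  obs <- rbind(c(1, 2, 3), c(1, 2, 3), c(2, 1, 3))
  chi <- friedman_test(obs)$chi2
  exact_p <- mean(stats_null >= chi - 1e-12)
  approx_p <- friedman_test(obs)$p
  expect_lt(abs(exact_p - approx_p), 0.12)   # chi-square approximation
})

test_that("Wilcoxon exact path equals the sign-assignment enumeration", {
  w <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(w$p, 0.25)
  expect_equal(w$W, 6)
  expect_equal(wilcoxon_signed_rank(rep(0, 5), rep(0, 5))$p, 1)

  set.seed(52)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n, 0, 2), 2)
    d <- d[d != 0]
    if (length(d) < 2) next
    ours <- wilcoxon_signed_rank(d, mode = "exact")
    # independent enumeration over all sign subsets
    r <- rank(abs(d))
    subs <- expand.grid(rep(list(c(FALSE, TRUE)), length(d)))
    Wall <- apply(subs, 1, function(s) sum(r[as.logical(s)]))
    pexp <- min(1, 2 * min(mean(Wall <= ours$W), mean(Wall >= ours$W)))
    expect_equal(ours$p, pexp)
    # cross-check against base R when tie-free
    if (!any(duplicated(abs(d)))) {
      ref <- stats::wilcox.test(d, exact = TRUE)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("multiplicity corrections match their step formulas", {
  expect_equal(adjust_p(0.01)$bonferroni, 0.01)
  a <- adjust_p(c(0.01, 0.02, 0.05))
  expect_equal(a$bonferroni, c(0.03, 0.06, 0.15))
  expect_equal(a$holm, c(0.03, 0.04, 0.05))
  expect_equal(adjust_p(c(0.01, 0.02, 0.03))$bh, c(0.03, 0.03, 0.03))
  b <- adjust_p(runif(10, 0.001, 1))
  expect_true(all(b$bonferroni >= b$raw))
  expect_true(all(b$holm >= b$raw))
  expect_true(all(unlist(b) > 0 & unlist(b) <= 1))
  expect_error(adjust_p(numeric(0)), "no p-values")
})

test_that("the normality screen flags skew and is calibrated under the null", {
  set.seed(53)
  hits <- vapply(1:40, function(i)
    shapiro_wilk_screen(exp(rnorm(50)))["p"] < 0.05, logical(1))
  expect_gte(mean(hits), 0.9)
  ps <- vapply(1:100, function(i)
    shapiro_wilk_screen(rnorm(50))["p"], numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_error(shapiro_wilk_screen(c(1, 2)), "n")
  expect_error(shapiro_wilk_screen(rep(3, 10)), "constant")
})

test_that("paired AUC comparison is exact for identical scores and agrees
           with a bootstrap oracle", {
  set.seed(54)
  y <- rbinom(150, 1, 0.4)
  s <- runif(150)
  same <- auc_difference_test(s, s, y)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)

  sa <- y + rnorm(150); sb <- 0.6 * y + rnorm(150)
  dl <- auc_difference_test(sa, sb, y)
  expect_gte(dl$se, 0)
  auc_of <- function(s, y) {
    r <- rank(s); n1 <- sum(y)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * sum(y == 0))
  }
  boots <- vapply(1:2000, function(i) {
    idx <- sample(150, replace = TRUE)
    if (length(unique(y[idx])) < 2) return(NA_real_)
    auc_of(sa[idx], y[idx]) - auc_of(sb[idx], y[idx])
  }, numeric(1))
  boots <- boots[!is.na(boots)]
  z0 <- mean(boots) / sd(boots)
  pboot <- 2 * pnorm(-abs(z0))
  expect_lt(abs(dl$p - pboot), 0.02)
  expect_error(auc_difference_test(sa, sb, rep(1, 150)), "classes")
})

test_that("cohort-table tests reproduce printed two-cohort statistics", {
  sex <- cohort_table_tests(counts = matrix(c(528, 338, 354, 291), 2,
                                            byrow = TRUE))
  expect_equal(round(sex$p, 3), 0.020)
  htn <- cohort_table_tests(counts = matrix(c(690, 176, 548, 97), 2,
                                            byrow = TRUE))
  expect_equal(round(htn$p, 3), 0.010)
  flat <- cohort_table_tests(counts = matrix(c(40, 60, 20, 30), 2,
                                             byrow = TRUE))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  expect_error(cohort_table_tests(counts = matrix(c(0, 0, 5, 5), 2)),
               "marginal")

  # summary t test equals t.test on the raw data
  set.seed(55)
  x <- rnorm(40, 10, 2); z <- rnorm(55, 11, 3)
  s1 <- c(mean(x), sd(x), 40); s2 <- c(mean(z), sd(z), 55)
  pooled <- cohort_table_tests(summaries = list(s1, s2))
  ref <- t.test(x, z, var.equal = TRUE)
  expect_equal(pooled$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(pooled$p, ref$p.value, tolerance = 1e-10)
  welch <- cohort_table_tests(summaries = list(s1, s2), welch = TRUE)
  refw <- t.test(x, z)
  expect_equal(welch$p, refw$p.value, tolerance = 1e-10)
})

test_that("the Friedman-Wilcoxon-Holm cascade controls type-I error", {
  set.seed(56)
  reps <- 400
  false_pos <- 0
  for (i in 1:reps) {
    M <- matrix(rnorm(6 * 7), 6, 7)
    fr <- friedman_test(M)
    if (fr$p >= 0.05) next
    prs <- utils::combn(7, 2)
    ps <- apply(prs, 2, function(pp)
      wilcoxon_signed_rank(M[, pp[1]], M[, pp[2]])$p)
    if (any(adjust_p(ps)$holm < 0.05)) false_pos <- false_pos + 1
  }
  expect_lte(false_pos / reps, 0.06)
})
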