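# Comparison statistics for the classifier grid: Friedman omnibus over
# pipelines, pairwise Wilcoxon signed-rank post hoc with three
# multiplicity corrections, a normality screen gating the nonparametric
# path, paired AUC comparison (DeLong), and the cohort-table tests.

#' Friedman rank test over a blocks x treatments matrix
#'
#' Within-block mid-ranks with the standard tie correction:
#' `chi2 = (k-1) * S / (sum r^2 - n k (k+1)^2 / 4)` where `S` is the sum of
#' squared column-rank-sum deviations. Blocks that are entirely constant
#' across all treatments give statistic 0 and p = 1.
#'
#' @param X numeric matrix, rows = blocks (e.g. classifiers), columns =
#'   treatments (e.g. pipelines).
#' @return List: `chi2`, `df`, `p`.
#' @export
friedman_test <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 2, ncol(X) >= 2)
  n <- nrow(X); k <- ncol(X)
  r <- t(apply(X, 1, rank))
  Rj <- colSums(r)
  S <- sum((Rj - n * (k + 1) / 2)^2)
  denom <- sum(r^2) - n * k * (k + 1)^2 / 4
  chi2 <- if (denom <= 0) 0 else (k - 1) * S / denom
  list(chi2 = chi2, df = k - 1L,
       p = stats::pchisq(chi2, k - 1, lower.tail = FALSE))
}

#' Wilcoxon signed-rank test
#'
#' Zero differences are dropped and absolute differences mid-ranked. The
#' two-sided p-value is exact (enumeration of all `2^n` sign assignments)
#' when `n <= 15` and there are no ties among the absolute differences,
#' otherwise a normal approximation with continuity and tie correction is
#' used. `mode` can force either path.
#'
#' @param a,b paired measurements (or set `b = 0` vector for one-sample).
#' @param mode "auto", "exact" or "normal".
#' @return List: `W` (positive-rank sum), `p`, `n` (nonzero pairs),
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(a, b = rep(0, length(a)),
                                 mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stopifnot(length(a) == length(b), all(is.finite(a)), all(is.finite(b)))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(W = 0, p = 1, n = 0L, method = "degenerate"))
  if (n < 2) stop("need at least 2 nonzero differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  exact <- mode == "exact" || (mode == "auto" && n <= 15 && !ties)
  if (exact) {
    nmask <- 2^n
    bits <- matrix(as.integer(intToBits(0:(nmask - 1))), nrow = 32)[1:n, ,
                                                                    drop = FALSE]
    Wall <- as.vector(r %*% bits)
    p <- min(1, 2 * min(mean(Wall <= W), mean(Wall >= W)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(W = W, p = p, n = as.integer(n), method = method)
}

#' Multiplicity adjustment (Bonferroni, Holm, Benjamini-Hochberg)
#'
#' @param ps numeric p-values in (0, 1].
#' @param methods subset of `c("bonferroni", "holm", "bh")`.
#' @return List with `raw` and one adjusted vector per method.
#' @export
adjust_p <- function(ps, methods = c("bonferroni", "holm", "bh")) {
  if (!length(ps)) stop("no p-values supplied")
  stopifnot(all(ps > 0 & ps <= 1))
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list(raw = ps)
  map <- c(bonferroni = "bonferroni", holm = "holm", bh = "BH")
  for (m in methods) out[[m]] <- stats::p.adjust(ps, method = map[[m]])
  out
}

#' Shapiro-Wilk normality screen
#'
#' Gates the nonparametric comparison path in reports.
#'
#' @param x numeric sample, `3 <= n <= 5000`.
#' @return Named numeric `c(W, p)`.
#' @export
shapiro_wilk_screen <- function(x) {
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop("degenerate (constant) sample")
  sw <- stats::shapiro.test(x)
  c(W = unname(sw$statistic), p = sw$p.value)
}

#' Paired AUC comparison (DeLong)
#'
#' Compares the AUCs of two score vectors on the same cases via the
#' DeLong placement-value covariance estimate.
#'
#' @param scores_a,scores_b numeric scores on identical cases.
#' @param labels binary 0/1, both classes present.
#' @return List: `auc_a`, `auc_b`, `delta`, `se`, `p` (two-sided).
#' @export
auc_difference_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  pos <- labels == 1; neg <- labels == 0
  m <- sum(pos); n <- sum(neg)
  if (m == 0 || n == 0) stop("both classes required")
  placements <- function(s) {
    psi <- outer(s[pos], s[neg], function(x, y)
      (x > y) + 0.5 * (x == y))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), theta = mean(psi))
  }
  A <- placements(scores_a); B <- placements(scores_b)
  delta <- A$theta - B$theta
  s10 <- stats::cov(cbind(A$v10, B$v10))
  s01 <- stats::cov(cbind(A$v01, B$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (v < 1e-14) {
    p <- if (abs(delta) < 1e-12) 1 else 0
    return(list(auc_a = A$theta, auc_b = B$theta, delta = delta,
                se = sqrt(max(v, 0)), p = p))
  }
  z <- delta / sqrt(v)
  list(auc_a = A$theta, auc_b = B$theta, delta = delta, se = sqrt(v),
       p = 2 * stats::pnorm(-abs(z)))
}

#' Cohort-table tests (chi-square counts, t from summaries)
#'
#' Categorical variables: Pearson chi-square on a 2 x c contingency
#' table, with Yates continuity correction for 2 x 2. Continuous
#' variables: two-sample t test from summary statistics (pooled variance
#' by default, Welch optional).
#'
#' @param counts 2 x c matrix of counts (rows = cohorts), or `NULL`.
#' @param summaries list of two `c(mean, sd, n)` vectors, or `NULL`.
#' @param welch use the Welch form for the summary t test.
#' @return List with `statistic`, `df` (t test), `p`.
#' @export
cohort_table_tests <- function(counts = NULL, summaries = NULL,
                               welch = FALSE) {
  if (!is.null(counts)) {
    stopifnot(is.matrix(counts), nrow(counts) == 2)
    if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
      stop("zero marginal in contingency table")
    ct <- stats::chisq.test(counts, correct = ncol(counts) == 2)
    return(list(statistic = unname(ct$statistic), p = ct$p.value))
  }
  if (!is.null(summaries)) {
    s1 <- summaries[[1]]; s2 <- summaries[[2]]
    m1 <- s1[1]; sd1 <- s1[2]; n1 <- s1[3]
    m2 <- s2[1]; sd2 <- s2[2]; n2 <- s2[3]
    if (welch) {
      se2 <- sd1^2 / n1 + sd2^2 / n2
      tt <- (m1 - m2) / sqrt(se2)
      df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
    } else {
      sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
      tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    }
    return(list(statistic = unname(tt), df = unname(df),
                p = unname(2 * stats::pt(-abs(tt), df))))
  }
  stop("supply counts or summaries")
}

#' Compare the seven pipelines across classifiers
#'
#' Builds the blocks x pipelines AUC matrix from a result grid (blocking
#' on classifiers by default, optionally on cross-validation folds),
#' screens the AUC pool for normality, runs the Friedman omnibus, and --
#' when the omnibus is significant -- all pairwise Wilcoxon signed-rank
#' tests with the three corrections.
#'
#' @param grid a `result_grid` from [run_grid()].
#' @param outcome outcome name.
#' @param split "test" or "cv".
#' @param block_on "classifier" (AUCs per classifier) or "fold"
#'   (cv fold-level AUCs pooled over classifiers).
#' @param alpha omnibus significance gate for the post hoc tests.
#' @return List: `auc_matrix`, `normality`, `friedman`, and (when run)
#'   `pairwise` (data.frame with raw and adjusted p-values).
#' @export
compare_pipelines <- function(grid, outcome, split = "test",
                              block_on = c("classifier", "fold"),
                              alpha = 0.05) {
  block_on <- match.arg(block_on)
  g <- grid[grid$outcome == outcome & grid$metric == "auc" &
              grid$split == split, ]
  if (block_on == "classifier") {
    M <- stats::xtabs(value ~ classifier + configuration, data = g)
    M <- matrix(M, nrow(M), ncol(M),
                dimnames = list(rownames(M), colnames(M)))
  } else {
    fa <- attr(grid, "fold_aucs")
    keys <- names(fa)[grepl(paste0("\\|", outcome, "$"), names(fa))]
    cfgs <- unique(vapply(strsplit(keys, "|", fixed = TRUE), `[`, "", 1))
    M <- sapply(cfgs, function(cf) {
      ks <- keys[startsWith(keys, paste0(cf, "|"))]
      rowMeans(do.call(cbind, fa[ks]))   # mean over classifiers per fold
    })
  }
  norm <- tryCatch(shapiro_wilk_screen(as.vector(M)),
                   error = function(e) c(W = NA_real_, p = NA_real_))
  fr <- friedman_test(M)
  out <- list(auc_matrix = M, normality = norm, friedman = fr)
  if (is.finite(fr$p) && fr$p < alpha && ncol(M) >= 2) {
    prs <- utils::combn(colnames(M), 2)
    pw <- data.frame(a = prs[1, ], b = prs[2, ],
                     p_raw = apply(prs, 2, function(pp)
                       wilcoxon_signed_rank(M[, pp[1]], M[, pp[2]])$p))
    adj <- adjust_p(pmin(pmax(pw$p_raw, 1e-300), 1))
    pw$p_bonferroni <- adj$bonferroni
    pw$p_holm <- adj$holm
    pw$p_bh <- adj$bh
    out$pairwise <- pw
  }
  out
}

#' Write the omnibus and pairwise comparison report
#'
#' @param cmp result of [compare_pipelines()].
#' @param dir output directory.
#' @param outcome outcome label used in file names.
#' @return Paths written, invisibly.
#' @export
write_stats_report <- function(cmp, dir, outcome = "outcome") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, sprintf("comparison_%s.csv", outcome))
  md <- file.path(dir, sprintf("comparison_%s.md", outcome))
  utils::write.csv(as.data.frame(cmp$auc_matrix), csv)
  lines <- c(sprintf("# Pipeline comparison (%s)", outcome), "",
             sprintf("Shapiro-Wilk screen: W = %.3f, p = %.4g",
                     cmp$normality["W"], cmp$normality["p"]),
             sprintf("Friedman: chi2 = %.3f, df = %d, p = %.4g",
                     cmp$friedman$chi2, cmp$friedman$df, cmp$friedman$p))
  if (!is.null(cmp$pairwise)) {
    lines <- c(lines, "", "pair | raw p | bonferroni | holm | BH",
               "---|---|---|---|---",
               sprintf("%s vs %s | %.4g | %.4g | %.4g | %.4g",
                       cmp$pairwise$a, cmp$pairwise$b, cmp$pairwise$p_raw,
                       cmp$pairwise$p_bonferroni, cmp$pairwise$p_holm,
                       cmp$pairwise$p_bh))
  }
  writeLines(lines, md)
  invisible(c(csv, md))
}
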