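test_that("stratified folds balance positives and are a seeded partition", {
  y <- rep(c(1, 0), c(20, 80))
  f <- stratified_kfold(y, k = 5, seed = 3)
  expect_equal(sort(unlist(f)), 1:100)
  expect_true(all(vapply(f, function(i) sum(y[i]), numeric(1)) == 4))
  expect_identical(f, stratified_kfold(y, k = 5, seed = 3))
  expect_false(identical(f, stratified_kfold(y, k = 5, seed = 4)))
  expect_error(stratified_kfold(rep(1, 10)), "single class")
  expect_error(stratified_kfold(c(0, 1), k = 5), "fewer")
})

test_that("binary metrics match rank and confusion-table definitions", {
  expect_equal(binary_metrics(c(0.9, 0.8, 0.2, 0.1),
                              c(1, 1, 0, 0))[["auc"]], 1)
  s <- runif(40); y <- rbinom(40, 1, 0.5)
  a1 <- binary_metrics(s, y)[["auc"]]
  expect_equal(binary_metrics(-s, y, rank_scores = -s)[["auc"]], 1 - a1)
  expect_equal(binary_metrics(c(0.9, 0.8, 0.7, 0.6),
                              c(1, 0, 1, 0))[["auc"]], 0.75)
  expect_error(binary_metrics(s, rep(1, 40)), "one-class")

  set.seed(44)
  for (i in 1:20) {
    y <- rbinom(30, 1, 0.5); s <- runif(30)
    if (length(unique(y)) < 2) next
    m <- binary_metrics(s, y, threshold = 0.5)
    pred <- as.integer(s >= 0.5)
    tp <- sum(pred & y); fn <- sum(!pred & y)
    tn <- sum(!pred & !y); fp <- sum(pred & !y)
    expect_equal(m[["sensitivity"]], tp / (tp + fn))
    expect_equal(m[["specificity"]], tn / (tn + fp))
    if (!is.na(m[["ppv"]]) && tp > 0)
      expect_equal(m[["f1"]],
                   2 * m[["ppv"]] * m[["sensitivity"]] /
                     (m[["ppv"]] + m[["sensitivity"]]))
  }
})

test_that("calibration is tight when scores equal generating probabilities", {
  set.seed(45)
  p <- runif(10000)
  y <- rbinom(10000, 1, p)
  cal <- calibration_curve(p, y, bins = 10)
  expect_lt(max(abs(cal$curve$mean_predicted - cal$curve$observed_rate)),
            0.05)
  expect_equal(calibration_curve(rep(0.5, 20),
                                 rep(c(0, 1), 10))$curve$observed_rate, 0.5)
  expect_equal(calibration_curve(c(rep(1, 10), rep(0, 10)),
                                 rep(c(1, 0), c(10, 10)))$brier, 0)
})

test_that("net benefit matches its closed form", {
  scores <- c(rep(0.9, 3), rep(0.8, 2), rep(0.1, 5))
  labels <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  dc <- decision_curve(scores, labels, thresholds = 0.2)
  expect_equal(dc$net_benefit, 0.3 - 0.2 * 0.25)   # 3 TP, 2 FP of n=10
  expect_equal(dc$treat_none, 0)
  tiny <- decision_curve(scores, labels, thresholds = 0.001)
  expect_lt(abs(tiny$treat_all - mean(labels)), 0.01)
})

test_that("grouped permutation importance isolates the signal group", {
  set.seed(46)
  n <- 1600; ntr <- 600
  Xs <- matrix(rnorm(n * 3), n, 3)
  Xn <- matrix(rnorm(n * 3), n, 3)
  X <- cbind(Xs, Xn)
  colnames(X) <- c(paste0("sig", 1:3), paste0("noise", 1:3))
  rownames(X) <- sprintf("c%04d", 1:n)
  y <- rbinom(n, 1, plogis(Xs %*% c(1.5, 1, -1)))
  leakage_clear()
  fit <- fit_classifier(classifier_specs(seed = 2, trees = 150)$RF,
                        X[1:ntr, ], y[1:ntr])
  # importance evaluated out of sample (noise columns must wash out)
  Xe <- X[(ntr + 1):n, ]; ye <- y[(ntr + 1):n]
  groups <- list(signal = colnames(X)[1:3], noise = colnames(X)[4:6])
  imp <- group_attribution(fit, Xe, ye, groups, R = 20, seed = 5)
  expect_lt(imp[["noise"]], 0.02)
  expect_gt(imp[["signal"]], imp[["noise"]])

  # permuting every column destroys essentially all discrimination
  base <- binary_metrics(predict_scores(fit, Xe)$rank, ye)[["auc"]]
  expect_gt(sum(imp), base - 0.5 - 0.1)

  expect_error(group_attribution(fit, Xe, ye,
                                 list(a = colnames(X)[1:2]), R = 2),
               "partition")
})

test_that("the grid covers every configuration, classifier and outcome", {
  set.seed(47)
  n <- 52; ids <- sprintf("c%02d", 1:n)
  sig <- rnorm(n)
  mk <- function(p, pre, with_sig = FALSE) {
    M <- matrix(abs(rnorm(n * p)), n, p,
                dimnames = list(ids, sprintf("%s%03d", pre, 1:p)))
    if (with_sig) M[, 1] <- abs(sig + rnorm(n, 0, 0.3))
    feature_block(M, "latent")
  }
  shape_m <- matrix(abs(rnorm(n * 14)), n, 14,
                    dimnames = list(ids, sprintf("s%03d", 1:14)))
  shape_m[, 1] <- abs(sig + rnorm(n, 0, 0.3))
  blocks <- list(radiomics_all = mk(20, "r", TRUE),
                 shape = feature_block(shape_m, "shape"),
                 seg_full = mk(24, "sf", TRUE),
                 seg_half = mk(12, "sh"),
                 vaegan = mk(16, "v", TRUE))
  labels <- data.frame(case_id = ids,
                       poor_outcome = rbinom(n, 1, plogis(sig)),
                       exp3 = rbinom(n, 1, plogis(sig - 0.5)))
  # guard against degenerate draws
  labels$poor_outcome[1:4] <- c(0, 1, 0, 1)
  labels$exp3[1:4] <- c(0, 1, 0, 1)
  # glmnet grumbles about class counts at this deliberately tiny n
  grid <- suppressWarnings(run_grid(blocks, labels, train_ids = ids[1:36],
                   test_ids = ids[37:52],
                   specs = classifier_specs(seed = 1, trees = 30),
                   outcomes = c("poor_outcome", "exp3"),
                   nmf_k = 4L, folds_k = 2L, seed = 9))
  cells <- unique(grid[grid$split == "test",
                       c("configuration", "classifier", "outcome")])
  expect_equal(nrow(cells), 7 * 6 * 2)
  aucs <- grid$value[grid$metric == "auc"]
  expect_true(all(aucs >= 0 & aucs <= 1))
  fa <- attr(grid, "fold_aucs")
  expect_equal(length(fa), 7 * 6 * 2)
  expect_true(all(vapply(fa, length, integer(1)) == 2))

  expect_error(run_grid(blocks, labels, ids[1:36], ids[30:40]),
               "overlap")
})
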