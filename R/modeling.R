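# Classifier grid over the seven input configurations and four outcomes,
# with stratified cross-validation, final refit on the full training
# cohort, and held-out testing. All feature reductions are re-fit inside
# each training fold; the leakage guard aborts any fit that sees a
# held-out row.

#' The six classifier specifications
#'
#' Random Forest, XGBoost and Extra Trees with 1000 estimators, Gaussian
#' naive Bayes, elastic-net logistic regression (l1 ratio 0.5), and an
#' RBF-kernel SVM, all seeded. `trees` scales the three ensemble sizes
#' down for quick runs.
#'
#' @param seed base seed (each classifier derives its own).
#' @param trees ensemble size for RF / XGBoost / Extra Trees.
#' @return Named list of `classifier_spec`s.
#' @export
classifier_specs <- function(seed = 1L, trees = 1000L) {
  mk <- function(name, hp) structure(list(name = name, hyperparams = hp,
                                          seed = as.integer(seed)),
                                     class = "classifier_spec")
  list(
    RF = mk("RF", list(ntree = trees)),
    XGBoost = mk("XGBoost", list(nrounds = trees, eta = 0.3, max_depth = 6)),
    GaussianNB = mk("GaussianNB", list()),
    ExtraTrees = mk("ExtraTrees", list(num.trees = trees)),
    ElasticNet_LogReg = mk("ElasticNet_LogReg", list(alpha = 0.5)),
    SVM_RBF = mk("SVM_RBF", list(cost = 1)))
}

#' Fit one classifier
#'
#' @param spec a `classifier_spec`.
#' @param X feature matrix with case-id rownames (checked against the
#'   leakage registry).
#' @param y binary 0/1 labels.
#' @return A `fitted_classifier`.
#' @export
fit_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"), nrow(X) == length(y))
  leakage_check(rownames(X), paste0("fit:", spec$name))
  yf <- factor(y, levels = c(0, 1))
  if (length(unique(y)) < 2) stop("single-class labels: cannot fit")
  hp <- spec$hyperparams
  fit <- with_seed(spec$seed, switch(
    spec$name,
    RF = randomForest::randomForest(x = X, y = yf, ntree = hp$ntree),
    XGBoost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eval_metric = "logloss",
                    eta = hp$eta, max_depth = hp$max_depth, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y), nrounds = hp$nrounds),
    GaussianNB = e1071::naiveBayes(x = as.data.frame(X), y = yf),
    ExtraTrees = ranger::ranger(
      x = X, y = yf, num.trees = hp$num.trees, splitrule = "extratrees",
      replace = FALSE, sample.fraction = 1, probability = TRUE,
      num.threads = 1, seed = spec$seed),
    ElasticNet_LogReg = glmnet::glmnet(
      X, yf, family = "binomial", alpha = hp$alpha,
      lambda = 1 / nrow(X), standardize = TRUE),
    SVM_RBF = e1071::svm(x = X, y = yf, kernel = "radial", cost = hp$cost,
                         probability = TRUE, scale = apply(X, 2, stats::sd) > 0),
    stop("unknown classifier: ", spec$name)))
  structure(list(spec = spec, fit = fit, p = ncol(X),
                 feature_names = colnames(X)),
            class = "fitted_classifier")
}

#' Predict scores from a fitted classifier
#'
#' Returns probability-scale scores (`prob`) for threshold metrics and
#' ranking scores (`rank`) for AUC; they differ only for the SVM, where
#' the decision-function value is passed through a monotone logistic link.
#'
#' @param object a `fitted_classifier`.
#' @param X feature matrix.
#' @return List with `prob` and `rank` numeric vectors.
#' @export
predict_scores <- function(object, X) {
  stopifnot(inherits(object, "fitted_classifier"))
  X <- X[, object$feature_names, drop = FALSE]
  sp <- object$spec; fit <- object$fit
  out <- switch(
    sp$name,
    RF = {
      p <- stats::predict(fit, X, type = "prob")[, "1"]
      list(prob = p, rank = p)
    },
    XGBoost = {
      p <- stats::predict(fit, xgboost::xgb.DMatrix(X))
      list(prob = p, rank = p)
    },
    GaussianNB = {
      p <- stats::predict(fit, as.data.frame(X), type = "raw")[, "1"]
      list(prob = p, rank = p)
    },
    ExtraTrees = {
      p <- stats::predict(fit, data = X, num.threads = 1)$predictions[, "1"]
      list(prob = p, rank = p)
    },
    ElasticNet_LogReg = {
      p <- as.vector(stats::predict(fit, X, type = "response"))
      list(prob = p, rank = p)
    },
    SVM_RBF = {
      pr <- stats::predict(fit, X, probability = TRUE,
                           decision.values = TRUE)
      p <- attr(pr, "probabilities")[, "1"]
      dv <- as.vector(attr(pr, "decision.values"))
      if (stats::cor(dv, p) < 0) dv <- -dv   # orient decision values
      list(prob = p, rank = stats::plogis(dv))
    })
  out
}

#' Stratified k-fold split
#'
#' Deals each class round-robin into `k` folds after a seeded shuffle, so
#' per-fold positive counts differ by at most one.
#'
#' @param labels binary 0/1 vector.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return List of `k` integer index vectors (a partition of the cases).
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  if (length(unique(labels)) < 2)
    stop("stratification error: labels contain a single class")
  if (length(labels) < k) stop("fewer cases than folds")
  folds <- vector("list", k)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      for (i in seq_along(idx)) {
        f <- ((i - 1L) %% k) + 1L
        folds[[f]] <- c(folds[[f]], idx[i])
      }
    }
  })
  lapply(folds, sort)
}

#' Threshold and ranking metrics for binary scores
#'
#' AUC is the rank statistic (ties counted 1/2); the remaining metrics
#' come from the confusion table at the probability threshold. PPV / NPV
#' with an undefined denominator are reported as `NA`, not 0.
#'
#' @param scores numeric scores (probability scale for the thresholded
#'   metrics).
#' @param labels binary 0/1.
#' @param threshold probability cutoff.
#' @param rank_scores optional separate scores for AUC (defaults to
#'   `scores`).
#' @return Named numeric: auc, f1, sensitivity, specificity, ppv, npv.
#' @export
binary_metrics <- function(scores, labels, threshold = 0.5,
                           rank_scores = scores) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined for one-class labels")
  r <- rank(rank_scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  c(auc = auc, f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
    else NA_real_,
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = ppv, npv = npv)
}

#' Quantile-binned calibration curve and Brier score
#'
#' @param scores predicted probabilities.
#' @param labels binary 0/1.
#' @param bins number of quantile bins.
#' @return List: `curve` (data.frame bin, mean_predicted, observed_rate,
#'   n) and `brier`.
#' @export
calibration_curve <- function(scores, labels, bins = 10L) {
  stopifnot(length(scores) >= bins)
  br <- unique(stats::quantile(scores, seq(0, 1, length.out = bins + 1)))
  bi <- if (length(br) > 2)
    cut(scores, br, include.lowest = TRUE, labels = FALSE)
  else rep(1L, length(scores))
  curve <- do.call(rbind, lapply(sort(unique(bi)), function(b) {
    s <- bi == b
    data.frame(bin = b, mean_predicted = mean(scores[s]),
               observed_rate = mean(labels[s]), n = sum(s))
  }))
  list(curve = curve, brier = mean((scores - labels)^2))
}

#' Decision-curve net benefit
#'
#' `NB(pt) = TP/n - (FP/n) * pt/(1-pt)`, with treat-all and treat-none
#' reference policies.
#'
#' @param scores predicted probabilities.
#' @param labels binary 0/1.
#' @param thresholds vector in (0, 1).
#' @return data.frame: threshold, net_benefit, treat_all, treat_none.
#' @export
decision_curve <- function(scores, labels,
                           thresholds = seq(0.05, 0.6, by = 0.05)) {
  stopifnot(all(thresholds > 0 & thresholds < 1))
  n <- length(labels); prev <- mean(labels)
  do.call(rbind, lapply(thresholds, function(pt) {
    flag <- scores >= pt
    tp <- sum(flag & labels == 1) / n
    fp <- sum(flag & labels == 0) / n
    data.frame(threshold = pt, net_benefit = tp - fp * pt / (1 - pt),
               treat_all = prev - (1 - prev) * pt / (1 - pt),
               treat_none = 0)
  }))
}

#' Grouped permutation importance
#'
#' Model-agnostic group attribution: each feature group's columns are
#' permuted jointly `R` times and the mean AUC drop (floored at 0) is the
#' group's importance.
#'
#' @param fit a `fitted_classifier`.
#' @param X evaluation feature matrix.
#' @param labels binary 0/1 evaluation labels.
#' @param groups named list of column-name vectors; must partition
#'   `colnames(X)`.
#' @param R permutations per group.
#' @param seed permutation seed.
#' @return Named numeric vector of importances (one per group).
#' @export
group_attribution <- function(fit, X, labels, groups, R = 20L, seed = 1L) {
  allcols <- unlist(groups)
  if (anyDuplicated(allcols) || !setequal(allcols, colnames(X)))
    stop("groups must partition the feature columns")
  base <- binary_metrics(predict_scores(fit, X)$rank, labels)["auc"]
  with_seed(seed, {
    imp <- vapply(groups, function(cols) {
      drops <- vapply(seq_len(R), function(r) {
        Xp <- X
        Xp[, cols] <- Xp[sample(nrow(X)), cols, drop = FALSE]
        base - binary_metrics(predict_scores(fit, Xp)$rank, labels)["auc"]
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
  pmax(imp, 0)
}

#' Run the full classifier grid
#'
#' For every (input configuration, classifier, outcome): stratified
#' k-fold cross-validation on the training cohort with the nonnegative
#' shift and NMF re-fit inside each training fold, then a final refit on
#' the whole training cohort evaluated on the held-out test cohort. The
#' leakage registry is armed with the held-out ids around every fit.
#'
#' @param blocks raw feature blocks covering training and test cases
#'   (see [reduce_and_configure()]).
#' @param labels data.frame with `case_id` and the outcome columns.
#' @param train_ids,test_ids disjoint case-id sets.
#' @param specs classifier specifications ([classifier_specs()]).
#' @param outcomes outcome column names to run.
#' @param nmf_k NMF dimensionality per source.
#' @param folds_k cross-validation folds.
#' @param seed master seed for folds and NMF.
#' @param configurations subset of configuration names (default all 7).
#' @return A `result_grid`: tidy data.frame (configuration, classifier,
#'   outcome, split, metric, value) with attribute `fold_aucs`.
#' @export
run_grid <- function(blocks, labels, train_ids, test_ids,
                     specs = classifier_specs(),
                     outcomes = c("poor_outcome", "exp3", "exp6", "exp9"),
                     nmf_k = 16L, folds_k = 5L, seed = 1L,
                     configurations = INPUT_CONFIG_NAMES) {
  if (length(intersect(train_ids, test_ids)))
    stop("train and test case sets overlap")
  rownames(labels) <- labels$case_id
  rows <- list(); fold_aucs <- list()
  add <- function(cfg, cls, oc, split, metrics) {
    rows[[length(rows) + 1L]] <<- data.frame(
      configuration = cfg, classifier = cls, outcome = oc, split = split,
      metric = names(metrics), value = as.numeric(metrics))
  }
  for (oc in outcomes) {
    ytr <- labels[train_ids, oc]
    folds <- stratified_kfold(ytr, k = folds_k, seed = seed)
    oof <- list()   # out-of-fold scores per (config, classifier)
    for (f in seq_along(folds)) {
      ho_ids <- train_ids[folds[[f]]]
      fit_ids <- setdiff(train_ids, ho_ids)
      leakage_register(c(ho_ids, test_ids))
      red <- reduce_and_configure(blocks, fit_ids, k = nmf_k, seed = seed,
                                  configurations = configurations)
      for (cfg in configurations) {
        M <- red[[cfg]]$matrix
        for (cls in names(specs)) {
          fit <- fit_classifier(specs[[cls]],
                                M[fit_ids, , drop = FALSE],
                                labels[fit_ids, oc])
          sc <- predict_scores(fit, M[ho_ids, , drop = FALSE])
          key <- paste(cfg, cls, sep = "|")
          oof[[key]] <- rbind(oof[[key]],
                              data.frame(id = ho_ids, fold = f,
                                         prob = sc$prob, rank = sc$rank))
        }
      }
      leakage_clear()
    }
    # cv metrics: fold-wise AUC, pooled out-of-fold threshold metrics
    for (key in names(oof)) {
      d <- oof[[key]]
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      fa <- vapply(seq_along(folds), function(f) {
        s <- d[d$fold == f, ]
        y <- labels[s$id, oc]
        if (length(unique(y)) < 2) return(NA_real_)
        binary_metrics(s$prob, y, rank_scores = s$rank)["auc"]
      }, numeric(1))
      fold_aucs[[paste(parts[1], parts[2], oc, sep = "|")]] <- fa
      mets <- binary_metrics(d$prob, labels[d$id, oc], rank_scores = d$rank)
      mets["auc"] <- mean(fa, na.rm = TRUE)
      add(parts[1], parts[2], oc, "cv", mets)
    }
    # final refit on all training cases, evaluate on the test cohort
    if (!length(test_ids)) next
    leakage_register(test_ids)
    red <- reduce_and_configure(blocks, train_ids, k = nmf_k, seed = seed,
                                configurations = configurations)
    for (cfg in configurations) {
      M <- red[[cfg]]$matrix
      for (cls in names(specs)) {
        fit <- fit_classifier(specs[[cls]], M[train_ids, , drop = FALSE],
                              labels[train_ids, oc])
        sc <- predict_scores(fit, M[test_ids, , drop = FALSE])
        add(cfg, cls, oc, "test",
            binary_metrics(sc$prob, labels[test_ids, oc],
                           rank_scores = sc$rank))
      }
    }
    leakage_clear()
  }
  grid <- do.call(rbind, rows)
  attr(grid, "fold_aucs") <- fold_aucs
  class(grid) <- c("result_grid", "data.frame")
  grid
}
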