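#' Stratified holdout split
#'
#' Reserves a fraction of the instances as a test set, sampled
#' proportionally within the redundant and nonredundant classes.
#'
#' @param labels logical class labels (`TRUE` = redundant).
#' @param fraction test fraction (default 0.1).
#' @param seed integer seed; the same seed reproduces the partition.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_holdout <- function(labels, fraction = 0.1, seed = 1) {
  labels <- as.logical_label(labels)
  if (min(table(labels)) < 2) stop("each class needs at least 2 instances to stratify")
  stopifnot(fraction >= 0, fraction < 1)
  test <- integer(0)
  with_seed(seed, {
    for (cl in c(TRUE, FALSE)) {
      idx <- which(labels == cl)
      n_test <- round(length(idx) * fraction)
      if (n_test > 0) test <- c(test, sample(idx, n_test))
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Balanced down-sampling replicates
#'
#' Repeatedly down-samples the majority class (without replacement) to the
#' minority-class size, retaining every minority instance, to remove the
#' class imbalance of the benchmark. Each replicate uses its own sub-seed
#' so replicates differ but the whole set is reproducible.
#'
#' @param labels logical class labels.
#' @param n_replicates number of balanced data sets (default 100).
#' @param seed integer master seed.
#' @return list of sorted integer index vectors, one per replicate, each
#'   of size `2 * min(class sizes)`.
#' @export
balanced_replicates <- function(labels, n_replicates = 100, seed = 1) {
  labels <- as.logical_label(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be non-empty")
  minority <- if (n_pos <= n_neg) which(labels) else which(!labels)
  majority <- if (n_pos <= n_neg) which(!labels) else which(labels)
  seeds <- seed_stream(seed, paste0("replicate", seq_len(n_replicates)))
  lapply(seq_len(n_replicates), function(r) {
    with_seed(seeds[r], sort(c(minority, sample(majority, length(minority)))))
  })
}

# internal: stratified fold assignment
make_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Default hyperparameter grids
#'
#' Candidate values searched per algorithm: the SVM cost parameter C; the
#' number of trees, maximum depth and maximum-features rule for random
#' forest; learning rate plus the depth/feature rules for gradient
#' boosting. Rows are ordered by increasing model complexity so that grid
#' ties resolve toward the simpler model.
#'
#' @param algorithm `"svm"`, `"random_forest"` or `"gradient_boosting"`.
#' @return data.frame of candidate hyperparameter rows.
#' @export
default_grid <- function(algorithm = c("svm", "random_forest", "gradient_boosting")) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "svm") {
    return(data.frame(C = c(1e-3, 1e-2, 1e-1, 1, 10, 100)))
  }
  depth_feat <- expand.grid(
    max_features = c("sqrt", "0.1", "0.5"),
    max_depth = c(3, 5, 10, NA),
    stringsAsFactors = FALSE
  )
  if (algorithm == "random_forest") {
    g <- merge(data.frame(trees = c(100, 500)), depth_feat)
    return(g[order(g$trees, is.na(g$max_depth), g$max_depth, g$max_features), ])
  }
  g <- merge(data.frame(learning_rate = c(0.01, 0.1, 0.3)), depth_feat)
  g$max_depth[is.na(g$max_depth)] <- 6  # boosting needs a finite depth
  g <- unique(g)
  g[order(g$learning_rate, g$max_depth, g$max_features), ]
}

#' Default hyperparameters
#'
#' The conventional single-point defaults used when no grid search is run:
#' SVM cost `C = 1`; random forest with 500 trees, sqrt-p features and
#' unrestricted depth; gradient boosting with learning rate 0.1, depth 6
#' and 100 rounds.
#'
#' @param algorithm classifier name.
#' @return named list of hyperparameters.
#' @export
default_hyper <- function(algorithm = c("svm", "random_forest", "gradient_boosting")) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
         svm = list(C = 1),
         random_forest = list(trees = 500, max_depth = NA, max_features = "sqrt"),
         gradient_boosting = list(trees = 100, learning_rate = 0.1,
                                  max_depth = 6, max_features = "sqrt"))
}

# internal: resolve a max_features rule to an integer column count
resolve_mtry <- function(rule, p) {
  if (is.null(rule) || is.na(rule) || identical(rule, "sqrt")) {
    return(max(1L, floor(sqrt(p))))
  }
  max(1L, floor(as.numeric(rule) * p))
}

# internal: fit one classifier on a scaled matrix
fit_clf <- function(algorithm, x, y, hyper, seed = 1) {
  y <- factor(y, levels = c(FALSE, TRUE))
  if (algorithm == "svm") {
    fit <- e1071::svm(x, y, kernel = "linear", scale = FALSE,
                      cost = if (is.null(hyper$C)) 1 else hyper$C)
  } else if (algorithm == "random_forest") {
    fit <- ranger::ranger(
      x = x, y = y, probability = TRUE,
      num.trees = if (is.null(hyper$trees)) 500 else hyper$trees,
      mtry = resolve_mtry(hyper$max_features, ncol(x)),
      max.depth = if (is.null(hyper$max_depth) || is.na(hyper$max_depth)) 0
                  else hyper$max_depth,
      importance = "impurity", seed = seed, num.threads = 1
    )
  } else if (algorithm == "gradient_boosting") {
    dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y == "TRUE"))
    params <- list(
      objective = "binary:logistic",
      eta = if (is.null(hyper$learning_rate)) 0.1 else hyper$learning_rate,
      max_depth = if (is.null(hyper$max_depth) || is.na(hyper$max_depth)) 6
                  else hyper$max_depth,
      colsample_bytree = if (is.null(hyper$max_features) ||
                             identical(hyper$max_features, "sqrt"))
        max(1 / ncol(x), sqrt(ncol(x)) / ncol(x))
        else as.numeric(hyper$max_features),
      nthread = 1, seed = as.integer(seed)
    )
    fit <- xgboost::xgb.train(
      params = params, data = dtrain,
      nrounds = if (is.null(hyper$trees)) 100 else hyper$trees,
      verbose = 0
    )
  } else {
    stop("unknown algorithm: ", algorithm)
  }
  list(algorithm = algorithm, fit = fit)
}

# internal: raw score oriented so larger = more likely redundant
# (SVM: signed decision value; RF/GB: class probability)
score_clf <- function(clf, x) {
  if (clf$algorithm == "svm") {
    pr <- stats::predict(clf$fit, x, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    flip <- if (startsWith(colnames(dv)[1], "TRUE")) 1 else -1
    return(as.numeric(dv[, 1] * flip))
  }
  if (clf$algorithm == "random_forest") {
    pr <- stats::predict(clf$fit, data = x, num.threads = 1)$predictions
    return(pr[, "TRUE"])
  }
  as.numeric(stats::predict(clf$fit, xgboost::xgb.DMatrix(x)))
}

# internal: Platt-style sigmoid calibration on out-of-fold scores
fit_platt <- function(scores, labels) {
  fit <- suppressWarnings(
    stats::glm(labels ~ scores, family = stats::binomial())
  )
  unname(stats::coef(fit))
}

apply_platt <- function(coefs, scores) {
  if (is.null(coefs)) return(scores)
  stats::plogis(coefs[1] + coefs[2] * scores)
}

#' F1-maximizing decision threshold
#'
#' Scans the sorted unique scores as threshold candidates (an instance is
#' called redundant when its score is greater than or equal to the
#' threshold) and returns the candidate maximizing the F1 score of the
#' redundant class; ties resolve to the lowest threshold.
#'
#' @param scores numeric classifier scores.
#' @param labels logical labels (`TRUE` = redundant).
#' @return list with `threshold` and its `f1`.
#' @export
choose_f1_threshold <- function(scores, labels) {
  labels <- as.logical_label(labels)
  cand <- sort(unique(scores))
  best_f1 <- -1
  best_t <- cand[1]
  for (t in cand) {
    f1 <- f1_score(scores >= t, labels)
    if (f1 > best_f1 + 1e-12) {
      best_f1 <- f1
      best_t <- t
    }
  }
  list(threshold = best_t, f1 = best_f1)
}

# internal: F1 of the positive class (0 when no positive calls/instances)
f1_score <- function(calls, labels) {
  tp <- sum(calls & labels)
  fp <- sum(calls & !labels)
  fn <- sum(!calls & labels)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

# internal: rank-based AUC-ROC (equivalent to the Mann-Whitney statistic)
auc_rank <- function(scores, labels) {
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# internal: out-of-fold scores via stratified k-fold CV on one balanced
# replicate; min-max scaling and (for SVM) the Platt sigmoid are fit on
# the training folds only, so out-of-fold scores carry no information
# about their own fold (in particular no orientation leakage under the
# null)
oof_scores <- function(x, y, algorithm, hyper, folds, seed) {
  fold <- make_folds(y, folds, seed)
  out <- numeric(length(y))
  fit_seeds <- seed_stream(seed, paste0("fold", seq_len(folds)))
  for (f in seq_len(folds)) {
    tr <- fold != f
    scaler <- fit_minmax(x[tr, , drop = FALSE])
    keep <- setdiff(colnames(x), scaler$degenerate)
    xtr <- apply_minmax(scaler, x[tr, , drop = FALSE])[, keep, drop = FALSE]
    xte <- apply_minmax(scaler, x[!tr, , drop = FALSE])[, keep, drop = FALSE]
    clf <- fit_clf(algorithm, xtr, y[tr], hyper, seed = fit_seeds[f])
    if (algorithm == "svm") {
      calib <- fit_platt(score_clf(clf, xtr), y[tr])
      out[!tr] <- apply_platt(calib, score_clf(clf, xte))
    } else {
      out[!tr] <- score_clf(clf, xte)
    }
  }
  out
}

#' Cross-validated hyperparameter grid search
#'
#' Evaluates every grid row by stratified k-fold cross-validation on the
#' first `n_balanced` balanced replicates and returns the row with the
#' highest mean validation AUC-ROC. The grid is scanned in increasing
#' model-complexity order, so exact ties resolve toward the simpler model.
#'
#' @param x numeric feature matrix (training instances).
#' @param y logical labels.
#' @param algorithm classifier name (see [default_grid()]).
#' @param replicates list of balanced index sets from
#'   [balanced_replicates()].
#' @param grid data.frame of candidate hyperparameter rows.
#' @param n_balanced number of replicates used (default 10).
#' @param folds CV folds (default 10).
#' @param seed integer seed.
#' @return list with `best` (named list of hyperparameters) and `results`
#'   (grid with a `mean_auc` column).
#' @export
grid_search_cv <- function(x, y, algorithm, replicates, grid = default_grid(algorithm),
                           n_balanced = 10, folds = 10, seed = 1) {
  if (is.null(grid) || nrow(grid) == 0) stop("empty hyperparameter grid")
  y <- as.logical_label(y)
  reps <- replicates[seq_len(min(n_balanced, length(replicates)))]
  seeds <- seed_stream(seed, paste0("balanced", seq_along(reps)))
  mean_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hyper <- as.list(grid[g, , drop = FALSE])
    aucs <- vapply(seq_along(reps), function(r) {
      idx <- reps[[r]]
      s <- oof_scores(x[idx, , drop = FALSE], y[idx], algorithm, hyper,
                      folds, seeds[r])
      auc_rank(s, y[idx])
    }, numeric(1))
    mean_auc[g] <- mean(aucs)
  }
  best <- which.max(mean_auc)  # first maximum = simplest model on ties
  res <- grid
  res$mean_auc <- mean_auc
  list(best = as.list(grid[best, , drop = FALSE]), results = res)
}

#' Select features for the final model
#'
#' Ranks engineered features by random-forest impurity importance
#' (averaged over balanced replicates) or by absolute elastic-net
#' coefficient at a cross-validated penalty, restricted by the feature
#' scheme: `"NT"` keeps only untransformed variants, `"MT"` allows every
#' transformation, `"BT"` first collapses each base feature to its single
#' highest-importance variant before taking the top k.
#'
#' @param x numeric feature matrix (training instances).
#' @param y logical labels.
#' @param metadata column metadata from [build_pair_matrix()] (columns
#'   `column`, `base`, `transform`).
#' @param method `"random_forest"` or `"elastic_net"`.
#' @param k number of features to return.
#' @param scheme `"NT"`, `"MT"` or `"BT"`.
#' @param replicates optional list of balanced index sets (random-forest
#'   importances are averaged over the first `n_balanced` of them).
#' @param n_balanced replicates used for averaging (default 10).
#' @param seed integer seed.
#' @return character vector of exactly `k` selected column names, in
#'   decreasing importance order.
#' @export
select_features <- function(x, y, metadata, method = c("random_forest", "elastic_net"),
                            k = 200, scheme = c("MT", "NT", "BT"),
                            replicates = NULL, n_balanced = 10, seed = 1) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  y <- as.logical_label(y)
  x <- as.matrix(x)
  meta <- metadata[match(colnames(x), metadata$column), ]
  if (scheme == "NT") {
    keep <- meta$transform == "identity" & meta$base != "(pca)"
    x <- x[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  if (is.null(replicates)) replicates <- list(seq_along(y))
  reps <- replicates[seq_len(min(n_balanced, length(replicates)))]
  seeds <- seed_stream(seed, c(paste0("imp", seq_along(reps)), "en"))

  if (method == "random_forest") {
    imp_mat <- vapply(seq_along(reps), function(r) {
      idx <- reps[[r]]
      # impurity_corrected removes the split-point bias that plain Gini
      # importance has against low-cardinality (binary/count) features
      rf <- ranger::ranger(
        x = x[idx, , drop = FALSE],
        y = factor(y[idx], levels = c(FALSE, TRUE)),
        num.trees = 500, importance = "impurity_corrected", seed = seeds[r],
        num.threads = 1
      )
      rf$variable.importance
    }, numeric(ncol(x)))
    importance <- rowMeans(imp_mat)
  } else {
    scaler <- fit_minmax(x)
    xs <- apply_minmax(scaler, x)
    keep <- setdiff(colnames(xs), scaler$degenerate)
    cvfit <- with_seed(seeds[["en"]], glmnet::cv.glmnet(
      xs[, keep, drop = FALSE], y, family = "binomial", alpha = 0.5, nfolds = 5
    ))
    beta <- as.numeric(stats::coef(cvfit, s = "lambda.min"))[-1]
    importance <- stats::setNames(rep(0, ncol(x)), colnames(x))
    importance[keep] <- abs(beta)
  }
  names(importance) <- colnames(x)

  ord <- order(-importance, names(importance))
  ranked <- names(importance)[ord]
  if (scheme == "BT") {
    key <- meta$base
    key[meta$base == "(pca)"] <- meta$column[meta$base == "(pca)"]
    names(key) <- meta$column
    ranked <- ranked[!duplicated(key[ranked])]
  }
  if (k > length(ranked)) {
    stop(sprintf("k = %d exceeds the %d available feature columns", k, length(ranked)))
  }
  ranked[seq_len(k)]
}

#' Train a balanced-replicate classifier ensemble
#'
#' For each balanced replicate: features are min-max scaled to `[0, 1]`
#' (ranges fit on the replicate's training folds), a classifier is fitted,
#' out-of-fold scores are obtained through stratified k-fold
#' cross-validation, SVM decision values are mapped to `[0, 1]` by
#' Platt-style sigmoid calibration fitted on those out-of-fold scores, and
#' the decision threshold is set to the out-of-fold-score candidate
#' maximizing F1. Zero-variance feature columns within a replicate are
#' dropped for that member. The ensemble decision threshold is the mean of
#' the member thresholds.
#'
#' @param x numeric feature matrix (training instances, engineered
#'   columns).
#' @param y logical labels (`TRUE` = redundant).
#' @param algorithm `"svm"` (linear kernel), `"random_forest"` or
#'   `"gradient_boosting"`.
#' @param hyper named list of hyperparameters (e.g., from
#'   [grid_search_cv()]); `NULL` for package defaults.
#' @param features character vector of columns to use (default: all).
#' @param n_replicates ensemble size (default 100).
#' @param folds CV folds per replicate (default 10).
#' @param seed integer master seed; the full ensemble is reproducible.
#' @return object of class `redundancy_ensemble`.
#' @export
train_ensemble <- function(x, y, algorithm = c("svm", "random_forest", "gradient_boosting"),
                           hyper = NULL, features = NULL, n_replicates = 100,
                           folds = 10, seed = 1) {
  algorithm <- match.arg(algorithm)
  y <- as.logical_label(y)
  x <- as.matrix(x)
  if (is.null(features)) features <- colnames(x)
  missing_f <- setdiff(features, colnames(x))
  if (length(missing_f) > 0) {
    stop("feature column(s) absent from x: ", paste(missing_f, collapse = ", "))
  }
  x <- x[, features, drop = FALSE]
  if (is.null(hyper)) hyper <- default_hyper(algorithm)

  seeds <- seed_stream(seed, c("replicates", "members"))
  reps <- balanced_replicates(y, n_replicates, seeds[["replicates"]])
  member_seeds <- seed_stream(seeds[["members"]], paste0("m", seq_len(n_replicates)))

  members <- lapply(seq_len(n_replicates), function(r) {
    idx <- reps[[r]]
    xr <- x[idx, , drop = FALSE]
    yr <- y[idx]
    sseed <- member_seeds[r]
    prob <- oof_scores(xr, yr, algorithm, hyper, folds, sseed)
    thr <- choose_f1_threshold(prob, yr)
    scaler <- fit_minmax(xr)
    keep <- setdiff(colnames(xr), scaler$degenerate)
    xs <- apply_minmax(scaler, xr)[, keep, drop = FALSE]
    clf <- fit_clf(algorithm, xs, yr, hyper, seed = seed_stream(sseed, "final"))
    calib <- if (algorithm == "svm") fit_platt(score_clf(clf, xs), yr) else NULL
    list(idx = idx, scaler = scaler, features = keep, clf = clf,
         calib = calib, threshold = thr$threshold, oof_f1 = thr$f1,
         oof_score = prob, oof_label = yr, dropped = scaler$degenerate)
  })

  structure(
    list(members = members, algorithm = algorithm, hyper = hyper,
         features = features, folds = folds,
         threshold = mean(vapply(members, `[[`, numeric(1), "threshold")),
         seed = seed),
    class = "redundancy_ensemble"
  )
}

#' @export
print.redundancy_ensemble <- function(x, ...) {
  cat(sprintf("redundancy_ensemble: %d %s members, %d features, threshold %.3f\n",
              length(x$members), x$algorithm, length(x$features), x$threshold))
  invisible(x)
}

# internal: matrix of calibrated member scores for new instances
member_scores <- function(ensemble, x) {
  x <- as.matrix(x)
  missing_f <- setdiff(ensemble$features, colnames(x))
  if (length(missing_f) > 0) {
    stop("missing feature column(s): ", paste(missing_f, collapse = ", "))
  }
  x <- x[, ensemble$features, drop = FALSE]
  vapply(ensemble$members, function(m) {
    xs <- apply_minmax(m$scaler, x)[, m$features, drop = FALSE]
    apply_platt(m$calib, score_clf(m$clf, xs))
  }, numeric(nrow(x)))
}

#' Redundancy scores for new gene pairs
#'
#' The redundancy score of a pair is the ensemble mean of the members'
#' probability-calibrated outputs, on a 0-1 continuum; a pair is called
#' redundant when its score reaches the ensemble's F1-maximizing
#' threshold. Feature scaling, calibration and thresholds are all frozen
#' from training.
#'
#' @param ensemble a `redundancy_ensemble`.
#' @param x feature matrix covering the ensemble's selected columns.
#' @return data.frame with `pair_id` (rownames of `x`), `score`, `call`,
#'   `threshold`.
#' @export
predict_scores <- function(ensemble, x) {
  sc <- member_scores(ensemble, x)
  score <- rowMeans(sc)
  data.frame(
    pair_id = if (is.null(rownames(x))) seq_len(nrow(sc)) else rownames(x),
    score = score,
    call = score >= ensemble$threshold,
    threshold = ensemble$threshold,
    row.names = NULL
  )
}

# internal: ROC step-curve points (fpr, tpr), one row per distinct score
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  data.frame(fpr = c(0, fp / sum(!labels)), tpr = c(0, tp / sum(labels)))
}

# internal: precision-recall points
pr_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  data.frame(recall = c(0, tp / sum(labels)),
             precision = c(1, tp / (tp + fp)))
}

# internal: vertical curve averaging on a fixed grid
average_curves <- function(curves, xname, yname, grid = seq(0, 1, length.out = 101)) {
  ys <- vapply(curves, function(cv) {
    stats::approx(cv[[xname]], cv[[yname]], xout = grid, rule = 2,
                  ties = max)$y
  }, numeric(length(grid)))
  ys <- matrix(ys, nrow = length(grid))
  data.frame(
    x = grid,
    mean = rowMeans(ys),
    sd = apply(ys, 1, stats::sd)
  )
}

# internal: trapezoid area under (x, y)
trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# internal: evaluation summary from per-member (scores, labels) pairs
summarize_members <- function(score_list, label_list, calls, labels) {
  roc <- average_curves(mapply(roc_points, score_list, label_list,
                               SIMPLIFY = FALSE), "fpr", "tpr")
  pr <- average_curves(mapply(pr_points, score_list, label_list,
                              SIMPLIFY = FALSE), "recall", "precision")
  names(roc) <- c("fpr", "tpr_mean", "tpr_sd")
  names(pr) <- c("recall", "precision_mean", "precision_sd")
  tp <- sum(calls & labels); fp <- sum(calls & !labels)
  fn <- sum(!calls & labels); tn <- sum(!calls & !labels)
  structure(
    list(
      roc = roc, pr = pr,
      auc_roc = trapezoid(roc$fpr, roc$tpr_mean),
      au_prc = trapezoid(pr$recall, pr$precision_mean),
      confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                         dimnames = list(predicted = c("redundant", "nonredundant"),
                                         actual = c("redundant", "nonredundant"))),
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      f1 = f1_score(calls, labels)
    ),
    class = "evaluation_summary"
  )
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("AUC-ROC %.3f | AU-PRC %.3f | precision %.3f | recall %.3f | F1 %.3f\n",
              x$auc_roc, x$au_prc, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Cross-validation performance of an ensemble
#'
#' Summarizes the out-of-fold scores collected while training: each
#' member's ROC and precision-recall curves are interpolated onto a fixed
#' 101-point grid and vertically averaged (mean and SD); areas under the
#' curves are computed on the averaged curves by the trapezoid rule.
#'
#' @param ensemble a `redundancy_ensemble`.
#' @return an `evaluation_summary`.
#' @export
cv_performance <- function(ensemble) {
  score_list <- lapply(ensemble$members, `[[`, "oof_score")
  label_list <- lapply(ensemble$members, `[[`, "oof_label")
  calls <- unlist(score_list) >= ensemble$threshold
  labels <- unlist(label_list)
  summarize_members(score_list, label_list, calls, labels)
}

#' Evaluate an ensemble on labeled data
#'
#' Computes each member's ROC and precision-recall curves on the supplied
#' instances, averages them on a fixed 101-point grid, and derives binary
#' calls by comparing the ensemble-mean score with the ensemble threshold.
#'
#' @param ensemble a `redundancy_ensemble`.
#' @param x feature matrix.
#' @param labels logical labels (both classes must be present).
#' @return an `evaluation_summary`.
#' @export
evaluate_ensemble <- function(ensemble, x, labels) {
  labels <- as.logical_label(labels)
  if (length(unique(labels)) < 2) {
    stop("evaluation requires both classes; ROC is undefined on single-class data")
  }
  sc <- member_scores(ensemble, x)
  score_list <- lapply(seq_len(ncol(sc)), function(j) sc[, j])
  label_list <- rep(list(labels), ncol(sc))
  calls <- rowMeans(sc) >= ensemble$threshold
  summarize_members(score_list, label_list, calls, labels)
}

#' Ensemble feature importances
#'
#' For a linear-kernel SVM ensemble the importance of a feature is the
#' mean across members of the absolute weight the model learned for it
#' (weights are meaningful because features are min-max normalized);
#' random-forest and gradient-boosting ensembles use mean impurity
#' importance/gain. Features dropped in a member (zero variance there)
#' contribute zero for that member. Ranks are a permutation of
#' `1..n_features`, ties broken by feature name for determinism.
#'
#' @param ensemble a `redundancy_ensemble`.
#' @return data.frame with `feature`, `importance`, `rank`.
#' @export
feature_importance <- function(ensemble) {
  p <- length(ensemble$features)
  acc <- stats::setNames(numeric(p), ensemble$features)
  for (m in ensemble$members) {
    if (ensemble$algorithm == "svm") {
      w <- crossprod(m$clf$fit$coefs, m$clf$fit$SV)[1, ]
      acc[m$features] <- acc[m$features] + abs(w)
    } else if (ensemble$algorithm == "random_forest") {
      imp <- m$clf$fit$variable.importance
      acc[names(imp)] <- acc[names(imp)] + imp
    } else {
      it <- xgboost::xgb.importance(model = m$clf$fit)
      imp <- stats::setNames(it$Gain, it$Feature)
      acc[names(imp)] <- acc[names(imp)] + imp
    }
  }
  imp <- acc / length(ensemble$members)
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord], importance = unname(imp)[ord],
             rank = seq_len(p), row.names = NULL)
}

#' Cross-definition train/test protocol
#'
#' Trains on the pairs redundant under one definition plus a random half
#' of the nonredundant pool, and tests on the other half of the
#' nonredundant pool plus the pairs redundant under the test definition
#' but not under the training definition. Training and test instance sets
#' are verified disjoint.
#'
#' @param x feature matrix, rows aligned with `labeled`.
#' @param labeled a `labeled_trios` table from [label_trios()].
#' @param train_def,test_def definition names (e.g., `"RD4"`, `"RD9"`).
#' @param algorithm,hyper,n_replicates,folds passed to [train_ensemble()].
#' @param seed integer master seed.
#' @return list with `ensemble`, `evaluation` (an `evaluation_summary` on
#'   the test composition), `train_idx`, `test_idx`.
#' @export
cross_definition_protocol <- function(x, labeled, train_def, test_def,
                                      algorithm = "svm", hyper = NULL,
                                      n_replicates = 100, folds = 10, seed = 1) {
  stopifnot(all(c(train_def, test_def, "NR") %in% names(labeled)))
  x <- as.matrix(x)
  stopifnot(nrow(x) == nrow(labeled))
  train_red <- which(labeled[[train_def]])
  test_red <- which(labeled[[test_def]] & !labeled[[train_def]])
  if (length(test_red) == 0) {
    stop(sprintf("no pairs are redundant under %s but not %s; cross-definition test set is empty",
                 test_def, train_def))
  }
  nr <- which(labeled$NR)
  seeds <- seed_stream(seed, c("nr_split", "train"))
  half <- with_seed(seeds[["nr_split"]], sample(nr, floor(length(nr) / 2)))
  train_idx <- sort(c(train_red, half))
  test_idx <- sort(c(test_red, setdiff(nr, half)))
  if (length(intersect(train_idx, test_idx)) > 0) {
    stop("internal error: cross-definition train and test sets overlap")
  }
  y_train <- labeled[[train_def]][train_idx]
  ens <- train_ensemble(x[train_idx, , drop = FALSE], y_train,
                        algorithm = algorithm, hyper = hyper,
                        n_replicates = n_replicates, folds = folds,
                        seed = seeds[["train"]])
  y_test <- labeled[[test_def]][test_idx]
  list(
    ensemble = ens,
    evaluation = evaluate_ensemble(ens, x[test_idx, , drop = FALSE], y_test),
    train_idx = train_idx, test_idx = test_idx
  )
}

#' End-to-end redundancy prediction pipeline
#'
#' Convenience wrapper: labels the trios, restricts to the pairs that are
#' redundant under `definition` or nonredundant, splits a stratified
#' holdout, builds the pair feature matrix on the training pairs (its
#' recipe is frozen and re-applied to the holdout), optionally runs the
#' hyperparameter grid search and feature selection, trains the balanced
#' ensemble, and evaluates both in cross-validation and on the holdout.
#'
#' @param trios mutant-trio table (see [read_trios()]).
#' @param genes,schema gene attribute table and schema (see
#'   [read_gene_table()]).
#' @param definition redundancy definition to model (default `"RD9"`).
#' @param scheme feature scheme passed to [build_pair_matrix()] /
#'   [select_features()].
#' @param algorithm classifier (default linear SVM).
#' @param hyper hyperparameters; `NULL` with `grid = TRUE` runs
#'   [grid_search_cv()], otherwise package defaults are used.
#' @param grid run the grid search? (default FALSE).
#' @param k number of features to select (`NULL` = use all columns).
#' @param selection_method feature-selection algorithm.
#' @param n_pcs principal-component features to append.
#' @param holdout_fraction stratified holdout fraction.
#' @param n_replicates,folds ensemble size and CV folds.
#' @param seed master seed; every stochastic step derives a named sub-seed
#'   from it.
#' @return list with `labeled`, `counts`, `pf` (training `pair_features`),
#'   `ensemble`, `cv` and `holdout` (`evaluation_summary`), `importance`,
#'   `holdout_pairs` (pair ids held out), `selected`.
#' @export
redundancy_pipeline <- function(trios, genes, schema, definition = "RD9",
                                scheme = "NT", algorithm = "svm", hyper = NULL,
                                grid = FALSE, k = NULL,
                                selection_method = "random_forest",
                                n_pcs = 0, holdout_fraction = 0.1,
                                n_replicates = 100, folds = 10, seed = 1) {
  labeled <- label_trios(trios)
  counts <- count_by_definition(labeled)
  use <- labeled[[definition]] | labeled$NR
  sub <- labeled[use, , drop = FALSE]
  y <- sub[[definition]]
  seeds <- seed_stream(seed, c("holdout", "grid", "select", "train"))
  sp <- split_holdout(y, holdout_fraction, seeds[["holdout"]])

  pairs_df <- function(d) data.frame(pair_id = d$pair_id, gene_a = d$gene_a,
                                     gene_b = d$gene_b)
  build_scheme <- if (scheme == "NT") "NT" else "MT"
  pf <- build_pair_matrix(genes, schema, pairs_df(sub[sp$train, ]),
                          scheme = build_scheme, n_pcs = n_pcs)
  x_train <- as.matrix(pf$features)
  y_train <- y[sp$train]

  reps10 <- balanced_replicates(y_train, 10, seeds[["train"]])
  if (is.null(hyper) && grid) {
    hyper <- grid_search_cv(x_train, y_train, algorithm, reps10,
                            folds = folds, seed = seeds[["grid"]])$best
  }
  selected <- colnames(x_train)
  if (!is.null(k)) {
    selected <- select_features(x_train, y_train, pf$metadata,
                                method = selection_method, k = k,
                                scheme = scheme, replicates = reps10,
                                seed = seeds[["select"]])
  } else if (scheme == "NT") {
    selected <- pf$metadata$column[pf$metadata$transform == "identity" &
                                     pf$metadata$base != "(pca)"]
  }
  ens <- train_ensemble(x_train, y_train, algorithm = algorithm, hyper = hyper,
                        features = selected, n_replicates = n_replicates,
                        folds = folds, seed = seeds[["train"]])
  cv <- cv_performance(ens)

  holdout <- NULL
  if (length(sp$test) > 0 && length(unique(y[sp$test])) == 2) {
    pf_test <- build_pair_matrix(genes, schema, pairs_df(sub[sp$test, ]),
                                 recipe = pf)
    holdout <- evaluate_ensemble(ens, as.matrix(pf_test$features), y[sp$test])
  }

  list(labeled = labeled, counts = counts, pf = pf, ensemble = ens,
       cv = cv, holdout = holdout, importance = feature_importance(ens),
       holdout_pairs = sub$pair_id[sp$test], selected = selected)
}
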