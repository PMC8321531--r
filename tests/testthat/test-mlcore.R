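test_that("holdout split is stratified, disjoint and reproducible", {
  labels <- rep(c(TRUE, FALSE), c(190, 110))
  sp <- split_holdout(labels, 0.1, seed = 3)
  expect_equal(sum(labels[sp$test]), 19)
  expect_equal(sum(!labels[sp$test]), 11)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_identical(sp, split_holdout(labels, 0.1, seed = 3))
  expect_false(identical(sp$test, split_holdout(labels, 0.1, seed = 4)$test))
  expect_length(split_holdout(labels, 0, seed = 1)$test, 0)
  expect_error(split_holdout(c(TRUE, FALSE, FALSE), 0.1), "2 instances")
})

test_that("balanced replicates down-sample the majority class without replacement", {
  labels <- rep(c(TRUE, FALSE), c(50, 100))
  reps <- balanced_replicates(labels, n_replicates = 20, seed = 5)
  expect_length(reps, 20)
  for (r in reps) {
    expect_length(r, 100)
    expect_equal(sum(labels[r]), 50)       # all minority retained
    expect_equal(sum(!labels[r]), 50)      # majority down-sampled
    expect_false(anyDuplicated(r) > 0)     # without replacement
  }
  expect_gt(length(unique(sapply(reps, paste, collapse = ","))), 1)
  # already balanced: every replicate is the full set
  reps2 <- balanced_replicates(rep(c(TRUE, FALSE), 10), 5, seed = 1)
  for (r in reps2) expect_identical(r, 1:20)
  expect_identical(reps, balanced_replicates(labels, 20, seed = 5))
})

test_that("the F1-maximizing threshold beats every candidate threshold", {
  sel <- choose_f1_threshold(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sel$threshold, 0.8)
  expect_equal(sel$f1, 1)
  # single candidate: that score, all-positive call
  one <- choose_f1_threshold(rep(0.4, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(one$threshold, 0.4)
  expect_equal(one$f1, 2 * 0.5 * 1 / 1.5)
  # brute-force optimality and lowest-threshold tie-break on random sets
  set.seed(51)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    s <- round(runif(n), 2)
    l <- runif(n) < 0.5
    if (!any(l)) l[1] <- TRUE
    sel <- choose_f1_threshold(s, l)
    f1s <- vapply(sort(unique(s)), function(t) {
      tp <- sum(s >= t & l); fp <- sum(s >= t & !l); fn <- sum(s < t & l)
      if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }, numeric(1))
    expect_equal(sel$f1, max(f1s), tolerance = 1e-12)
    expect_equal(sel$threshold, sort(unique(s))[which.max(f1s > max(f1s) - 1e-12)])
  }
})

test_that("grid search returns the candidate with the best mean CV AUC", {
  d <- separable_data(n_per_class = 30, p = 4, gap = 4, seed = 52)
  reps <- balanced_replicates(d$y, 3, seed = 1)
  single <- grid_search_cv(d$x, d$y, "svm", reps, grid = data.frame(C = 0.5),
                           n_balanced = 2, folds = 5, seed = 2)
  expect_equal(single$best$C, 0.5)
  gs <- grid_search_cv(d$x, d$y, "svm", reps, grid = data.frame(C = c(0.01, 1)),
                       n_balanced = 2, folds = 5, seed = 2)
  best_row <- which(gs$results$C == gs$best$C)
  expect_gte(gs$results$mean_auc[best_row], max(gs$results$mean_auc) - 1e-12)
  expect_identical(
    gs$best,
    grid_search_cv(d$x, d$y, "svm", reps, grid = data.frame(C = c(0.01, 1)),
                   n_balanced = 2, folds = 5, seed = 2)$best
  )
  expect_error(grid_search_cv(d$x, d$y, "svm", reps, grid = data.frame()),
               "empty")
})

test_that("feature selection honors k, the scheme and planted signal", {
  b <- generate_benchmark(syn_config(n_pairs = 100, emission_noise = 0), seed = 53)
  lab <- label_trios(b$trios)
  pf <- build_pair_matrix(b$genes, b$schema, b$pairs, scheme = "MT")
  x <- as.matrix(pf$features)
  y <- lab$RD9
  reps <- balanced_replicates(y, 3, seed = 1)
  sel <- select_features(x, y, pf$metadata, method = "random_forest", k = 10,
                         scheme = "BT", replicates = reps, n_balanced = 3,
                         seed = 2)
  expect_length(sel, 10)
  # BT: at most one variant per base feature
  expect_false(anyDuplicated(base_of(sel)) > 0)
  # strong planted features dominate the selection
  planted <- c(names(b$config$continuous_effects), names(b$config$binary_effects))
  expect_gte(length(intersect(base_of(sel), planted)), 4)
  # NT restricts to untransformed variants
  sel_nt <- select_features(x, y, pf$metadata, method = "random_forest", k = 10,
                            scheme = "NT", replicates = reps, n_balanced = 2,
                            seed = 2)
  meta_nt <- pf$metadata[match(sel_nt, pf$metadata$column), ]
  expect_true(all(meta_nt$transform == "identity"))
  # elastic net route returns exactly k names from the matrix
  sel_en <- select_features(x, y, pf$metadata, method = "elastic_net", k = 15,
                            scheme = "MT", seed = 3)
  expect_length(sel_en, 15)
  expect_true(all(sel_en %in% colnames(x)))
  expect_error(select_features(x, y, pf$metadata, k = 10000), "exceeds")
})

test_that("the ensemble separates separable data and is reproducible bit for bit", {
  d <- separable_data(n_per_class = 30, p = 4, gap = 6, seed = 54)
  ens <- train_ensemble(d$x, d$y, algorithm = "svm", n_replicates = 5,
                        folds = 5, seed = 7)
  expect_length(ens$members, 5)
  expect_true(ens$threshold > 0 && ens$threshold < 1)
  ev <- evaluate_ensemble(ens, d$x, d$y)
  expect_equal(ev$auc_roc, 1, tolerance = 1e-6)
  expect_equal(ev$au_prc, 1, tolerance = 1e-6)
  expect_equal(ev$f1, 1)
  expect_equal(sum(ev$confusion), length(d$y))
  cv <- cv_performance(ens)
  expect_gte(cv$auc_roc, 0.99)
  # member F1 at the chosen threshold is optimal by construction
  for (m in ens$members) {
    expect_equal(m$oof_f1, choose_f1_threshold(m$oof_score, m$oof_label)$f1)
  }
  # bit-reproducible under the master seed
  ens2 <- train_ensemble(d$x, d$y, algorithm = "svm", n_replicates = 5,
                         folds = 5, seed = 7)
  expect_identical(predict_scores(ens, d$x), predict_scores(ens2, d$x))
  # single-class evaluation is rejected
  expect_error(evaluate_ensemble(ens, d$x, rep(TRUE, nrow(d$x))), "single-class")
})

test_that("degenerate features are dropped per member and scores stay bounded", {
  d <- separable_data(n_per_class = 20, p = 3, gap = 5, seed = 55)
  x <- cbind(d$x, constant = 1)
  ens <- train_ensemble(x, d$y, n_replicates = 3, folds = 4, seed = 8)
  for (m in ens$members) expect_false("constant" %in% m$features)
  # importance table still covers every requested feature, ranks 1..p
  imp <- feature_importance(ens)
  expect_setequal(imp$feature, colnames(x))
  expect_identical(sort(imp$rank), seq_len(ncol(x)))
  expect_equal(imp$importance[imp$feature == "constant"], 0)
  # ensemble mean score lies within the member score range
  sc <- predict_scores(ens, x)
  member_range <- t(apply(redpair:::member_scores(ens, x), 1, range))
  expect_true(all(sc$score >= member_range[, 1] - 1e-12))
  expect_true(all(sc$score <= member_range[, 2] + 1e-12))
  # redundant training instances score above threshold on separable data
  expect_true(all(sc$call[d$y]))
  # missing feature columns are reported by name
  expect_error(predict_scores(ens, x[, 1:2]), "f3")
})

test_that("per-member weight importances concentrate on informative features", {
  set.seed(56)
  n <- 60
  x <- cbind(signal = c(rnorm(n / 2), rnorm(n / 2, 4)),
             matrix(rnorm(n * 10), ncol = 10,
                    dimnames = list(NULL, paste0("noise", 1:10))))
  y <- rep(c(FALSE, TRUE), each = n / 2)
  ens <- train_ensemble(x, y, n_replicates = 5, folds = 5, seed = 9)
  imp <- feature_importance(ens)
  expect_identical(imp$feature[1], "signal")
  # duplicated column: the two copies share the single-copy weight
  x2 <- cbind(x, signal_copy = x[, "signal"])
  ens2 <- train_ensemble(x2, y, n_replicates = 5, folds = 5, seed = 9)
  imp2 <- feature_importance(ens2)
  w_single <- imp$importance[imp$feature == "signal"]
  w_split <- sum(imp2$importance[imp2$feature %in% c("signal", "signal_copy")])
  expect_equal(w_split, w_single, tolerance = 0.15 * w_single)
})

test_that("label shuffling destroys the signal (no leakage through the pipeline)", {
  d <- separable_data(n_per_class = 40, p = 5, gap = 3, seed = 57)
  set.seed(58)
  y_perm <- sample(d$y)
  ens <- train_ensemble(d$x, y_perm, n_replicates = 5, folds = 5, seed = 10)
  cv <- cv_performance(ens)
  expect_lt(cv$auc_roc, 0.65)
  expect_gt(cv$auc_roc, 0.35)
})

test_that("the cross-definition protocol keeps train and test disjoint", {
  b <- generate_benchmark(syn_config(n_pairs = 120), seed = 59)
  lab <- label_trios(b$trios)
  pf <- build_pair_matrix(b$genes, b$schema, b$pairs, scheme = "NT")
  x <- as.matrix(pf$features)
  cd <- cross_definition_protocol(x, lab, "RD4", "RD9", n_replicates = 3,
                                  folds = 5, seed = 11)
  expect_length(intersect(cd$train_idx, cd$test_idx), 0)
  # test redundant set excludes every training-definition pair
  expect_false(any(lab$RD4[cd$test_idx]))
  expect_true(all(lab$RD9[cd$test_idx] | lab$NR[cd$test_idx]))
  expect_true(cd$evaluation$auc_roc >= 0 && cd$evaluation$auc_roc <= 1)
  # same definition on both sides: empty test redundant set
  expect_error(
    cross_definition_protocol(x, lab, "RD9", "RD9", n_replicates = 2, seed = 1),
    "empty"
  )
})

test_that("the end-to-end pipeline is reproducible and leak-free in its outputs", {
  b <- generate_benchmark(syn_config(n_pairs = 120), seed = 60)
  res <- redundancy_pipeline(b$trios, b$genes, b$schema, scheme = "NT",
                             n_replicates = 4, folds = 5, seed = 12)
  res2 <- redundancy_pipeline(b$trios, b$genes, b$schema, scheme = "NT",
                              n_replicates = 4, folds = 5, seed = 12)
  expect_identical(res$cv$auc_roc, res2$cv$auc_roc)
  expect_identical(res$importance, res2$importance)
  expect_gte(res$cv$auc_roc, 0.8)  # planted defaults are strong
  # holdout pairs never enter the training feature recipe
  expect_length(intersect(rownames(res$pf$features), res$holdout_pairs), 0)
})
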