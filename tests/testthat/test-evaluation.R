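test_that("perfect predictions score 1 on every index", {
  y <- rep(1:3, each = 5)
  probs <- matrix(0.05, 15, 3)
  probs[cbind(1:15, y)] <- 0.9
  m <- compute_metrics(y, y, probs)
  expect_equal(m$oa, 1)
  expect_equal(m$f1_macro, 1)
  expect_equal(m$mcc, 1)
  expect_equal(m$per_class_auc, rep(1, 3))
  expect_equal(m$mean_auc, 1)
  expect_equal(m$std_auc, 0)
})

test_that("uniform probabilities and a constant prediction sit at chance", {
  y <- rep(1:2, each = 10)
  probs <- matrix(0.5, 20, 2)
  m <- compute_metrics(y, rep(1L, 20), probs)
  expect_equal(m$mcc, 0)
  expect_equal(m$per_class_auc, c(0.5, 0.5))
})

test_that("metrics match the from-definition oracle on random instances", {
  set.seed(81)
  for (i in 1:50) {
    C <- sample(2:4, 1)
    N <- 60
    y <- sample(1:C, N, replace = TRUE)
    while (length(unique(y)) < C) y <- sample(1:C, N, replace = TRUE)
    probs <- random_simplex(N, C)
    pred <- max.col(probs, ties.method = "first")
    m <- compute_metrics(y, pred, probs, n_classes = C)
    o <- oracle_metrics(y, pred, probs, C)
    expect_equal(m$oa, o$oa, tolerance = 1e-10)
    expect_equal(m$prec_macro, o$prec_macro, tolerance = 1e-10)
    expect_equal(m$rec_macro, o$rec_macro, tolerance = 1e-10)
    expect_equal(m$f1_macro, o$f1_macro, tolerance = 1e-10)
    expect_equal(m$mcc, o$mcc, tolerance = 1e-10)
    expect_equal(m$per_class_auc, o$auc, tolerance = 1e-10)
    expect_equal(m$per_class_aupr, o$aupr, tolerance = 1e-10)
    expect_equal(m$mean_auc, o$mean_auc, tolerance = 1e-10)
    expect_equal(m$std_auc, o$std_auc, tolerance = 1e-10)
    expect_equal(m$mean_aupr, o$mean_aupr, tolerance = 1e-10)
    expect_equal(m$std_aupr, o$std_aupr, tolerance = 1e-10)
  }
})

test_that("mean and std of the AUC block are those of the per-class values", {
  set.seed(82)
  y <- sample(1:3, 40, replace = TRUE)
  probs <- random_simplex(40, 3)
  m <- compute_metrics(y, max.col(probs), probs, n_classes = 3)
  expect_equal(m$mean_auc, mean(m$per_class_auc))
  expect_equal(m$std_auc, sqrt(mean((m$per_class_auc - mean(m$per_class_auc))^2)))
})

test_that("a class absent from y_true is excluded from the AUC block with a warning", {
  y <- rep(1:2, each = 10)
  probs <- random_simplex(20, 3)
  expect_warning(m <- compute_metrics(y, rep(1L, 20), probs, n_classes = 3),
                 "absent")
  expect_true(is.na(m$per_class_auc[3]))
  expect_equal(m$mean_auc, mean(m$per_class_auc[1:2]))
})

test_that("the confusion matrix accounts for every sample", {
  set.seed(83)
  y <- sample(1:3, 30, replace = TRUE)
  p <- sample(1:3, 30, replace = TRUE)
  m <- compute_metrics(y, p, n_classes = 3)
  expect_equal(sum(m$confusion), 30)
  expect_equal(m$oa, sum(diag(m$confusion)) / 30)
})

test_that("stratified folds partition samples with balanced class counts", {
  set.seed(84)
  y <- rep(1:3, times = c(23, 17, 30))
  fold <- subloc2l:::stratified_folds(y, 5, seed = 99)
  expect_length(fold, 70)
  expect_setequal(unique(fold), 1:5)
  for (cl in 1:3) {
    cnt <- table(factor(fold[y == cl], levels = 1:5))
    expect_lte(diff(range(cnt)), 1)
  }
  expect_error(subloc2l:::stratified_folds(rep(1:2, c(3, 40)), 5, 1),
               "stratification error")
})

test_that("single-set cross-validation recovers a separable fixture", {
  set.seed(85)
  y <- rep(1:3, each = 15)
  X <- matrix(rnorm(45 * 6), 45, 6)
  for (j in 1:3) X[, j] <- X[, j] + 5 * as.numeric(y == j)
  rownames(X) <- sprintf("r%d", 1:45)
  fs <- feature_set("sep", X, y)
  cfg <- two_level_config(
    sae_first = sae_config(pretrain_epochs = 30, finetune_epochs = 150, seed = 7),
    stacking_folds = 3, seed = 25)
  res <- stratified_kfold_cv(list(fs), k = 5, cfg = cfg, model = "single")
  expect_gte(res$pooled$oa, 0.95)
  # fold assignment contract
  expect_equal(sort(unique(res$fold)), 1:5)
  expect_equal(length(res$fold), 45)
  # pooled metrics recompute from the prediction table
  expect_equal(res$pooled$oa,
               mean(res$predictions$true == res$predictions$pred))
})

test_that("label permutation drops cross-validation to chance", {
  set.seed(86)
  y <- rep(1:3, each = 15)
  X <- matrix(rnorm(45 * 6), 45, 6)
  for (j in 1:3) X[, j] <- X[, j] + 5 * as.numeric(y == j)
  rownames(X) <- sprintf("r%d", 1:45)
  yp <- sample(y)
  fs <- feature_set("perm", X, yp)
  cfg <- two_level_config(
    sae_first = sae_config(pretrain_epochs = 20, finetune_epochs = 80, seed = 7),
    stacking_folds = 3, seed = 26)
  res <- stratified_kfold_cv(list(fs), k = 5, cfg = cfg, model = "single")
  expect_lt(abs(res$pooled$oa - 1 / 3), 0.15)
})

test_that("per-fold fitting never touches held-out rows (leakage audit)", {
  set.seed(87)
  y <- rep(1:3, each = 12)
  X <- matrix(rnorm(36 * 5), 36, 5)
  X[, 1] <- X[, 1] + 4 * (y - 2)
  rownames(X) <- sprintf("r%d", 1:36)
  fs <- feature_set("aud", X, y)
  audit_enable()
  on.exit(audit_disable())
  cfg <- two_level_config(
    sae_first = sae_config(pretrain_epochs = 5, finetune_epochs = 10, seed = 7),
    stacking_folds = 3, seed = 27)
  res <- stratified_kfold_cv(list(fs), k = 3, cfg = cfg)
  log <- audit_log()
  for (f in 1:3) {
    test_ids <- fs$source_ids[res$fold == f]
    entries <- log[[sprintf("fold_%d", f)]]
    expect_gt(length(entries), 0)
    for (e in entries) {
      expect_true(e$stage %in% c("sda", "sae_fit"))
      expect_length(intersect(e$ids, test_ids), 0)
    }
  }
})
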