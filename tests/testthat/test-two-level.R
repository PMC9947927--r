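test_that("mean ensemble averages element-wise and keeps the simplex", {
  p1 <- matrix(c(1, 0, 0), 1, 3)
  p2 <- matrix(c(0, 1, 0), 1, 3)
  expect_equal(mean_ensemble(list(p1)), p1)
  expect_equal(mean_ensemble(list(p1, p2)), matrix(c(0.5, 0.5, 0), 1, 3))
  set.seed(71)
  mats <- lapply(1:5, function(i) random_simplex(8, 4))
  fme <- mean_ensemble(mats)
  expect_equal(fme, oracle_mean_ensemble(mats), tolerance = 1e-12)
  expect_equal(rowSums(fme), rep(1, 8), tolerance = 1e-12)
  # permutation invariance in the T arguments
  expect_equal(mean_ensemble(mats[c(3, 1, 5, 2, 4)]), fme, tolerance = 1e-12)
  expect_error(mean_ensemble(list()), "argument error")
  expect_error(mean_ensemble(list(p1, matrix(0.25, 2, 4))), "shape error")
})

test_that("training validates class counts against the stacking folds", {
  set.seed(72)
  y <- c(rep(1L, 3), rep(2L, 12))
  fs <- feature_set("A", matrix(rnorm(15 * 4), 15, 4), y)
  expect_error(train_two_level(list(fs), two_level_config(stacking_folds = 5)),
               "stratification error")
})

test_that("the same seed reproduces an identical two-level model", {
  sets <- get_complementary_fixture()
  cfg <- two_level_config(
    sae_first = sae_config(pretrain_epochs = 10, finetune_epochs = 30, seed = 7),
    stacking_folds = 3, seed = 21)
  m1 <- train_two_level(unname(sets), cfg)
  m2 <- train_two_level(unname(sets), cfg)
  expect_equal(m1$first_level, m2$first_level, tolerance = 1e-15)
  expect_equal(m1$second_level$softmax, m2$second_level$softmax, tolerance = 1e-15)
  p1 <- predict_two_level(m1, lapply(sets, `[[`, "matrix"))
  p2 <- predict_two_level(m2, lapply(sets, `[[`, "matrix"))
  expect_identical(p1$labels, p2$labels)
  expect_equal(p1$probs, p2$probs, tolerance = 1e-15)
})

test_that("with one separable set the two-level model matches a direct fit", {
  set.seed(73)
  y <- rep(1:3, each = 12)
  X <- matrix(rnorm(36 * 6), 36, 6)
  for (j in 1:3) X[, j] <- X[, j] + 5 * as.numeric(y == j)
  rownames(X) <- sprintf("r%d", 1:36)
  fs <- feature_set("solo", X, y)
  sae_cfg <- sae_config(pretrain_epochs = 30, finetune_epochs = 150, seed = 7)
  tl <- train_two_level(list(fs), two_level_config(
    sae_first = sae_cfg, stacking_folds = 3, seed = 22))
  pr <- predict_two_level(tl, list(solo = X))
  sel <- sda_select(fs)
  single <- sae_fit(project_selection(sel, X), y, sae_cfg, n_classes = 3)
  acc_single <- mean(max.col(predict_proba(single, project_selection(sel, X))) == y)
  acc_two <- mean(pr$labels == y)
  expect_gte(acc_two, acc_single - 0.02)
})

test_that("complementary views are fused above the best single set", {
  sets <- get_complementary_fixture()
  sae_cfg <- sae_config(pretrain_epochs = 50, finetune_epochs = 300, seed = 7)
  tl <- train_two_level(unname(sets), two_level_config(
    sae_first = sae_cfg, stacking_folds = 3, seed = 11))
  pr <- predict_two_level(tl, lapply(sets, `[[`, "matrix"))
  y <- sets$A$labels
  acc_two <- mean(pr$labels == y)
  singles <- vapply(sets, function(fs) {
    sel <- sda_select(fs)
    m <- sae_fit(project_selection(sel, fs$matrix), y, sae_cfg, n_classes = 7)
    mean(max.col(predict_proba(m, project_selection(sel, fs$matrix))) == y)
  }, numeric(1))
  expect_gt(acc_two, max(singles))
})

test_that("uniform first-level stubs propagate exact uniform decisions", {
  C <- 4
  stub_sae <- function(d) structure(list(
    enc1 = list(W = matrix(0, 2, d), b = c(0, 0)),
    enc2 = list(W = matrix(0, 2, 2), b = c(0, 0)),
    softmax = list(W = matrix(0, C, 2), b = rep(0, C)),
    scaler = list(min = rep(0, d), range = rep(1, d)),
    input_dim = d, n_classes = C, fitted = TRUE), class = "sae_sm")
  stub_sel <- structure(list(selected = 1:2, center = rep(0, 5),
                             scale = rep(1, 5), feature_ids = c("a", "b")),
                        class = "sda_selection")
  model <- structure(list(
    first_level = list(S1 = list(name = "S1", selection = stub_sel, model = stub_sae(2)),
                       S2 = list(name = "S2", selection = stub_sel, model = stub_sae(2))),
    second_level = stub_sae(C),
    n_classes = C, classes = 1:C, stacking_folds = 3, seed = 1),
    class = "two_level_sae")
  X <- matrix(runif(15), 3, 5)
  pr <- predict_two_level(model, list(S1 = X, S2 = X))
  expect_equal(pr$fme, matrix(1 / C, 3, C), tolerance = 1e-12)
  expect_equal(rowSums(pr$probs), rep(1, 3), tolerance = 1e-9)
  expect_identical(pr$labels, rep(1L, 3))   # argmax ties break to lowest class
})

test_that("out-of-fold stacking never scores a row with a model that saw it", {
  sets <- get_complementary_fixture()
  audit_enable()
  on.exit(audit_disable())
  audit_context("stacking_audit")
  cfg <- two_level_config(
    sae_first = sae_config(pretrain_epochs = 5, finetune_epochs = 10, seed = 7),
    stacking_folds = 3, seed = 23)
  tl <- train_two_level(unname(sets), cfg)
  # structural bookkeeping: per stacking fold, train and test ids are disjoint
  for (f in seq_along(tl$stack_fold_rows)) {
    fr <- tl$stack_fold_rows[[f]]
    expect_length(intersect(fr$train, fr$test), 0)
  }
  # every row received an out-of-fold decision
  expect_false(anyNA(tl$oof_decisions[[1]]))
  all_test <- unlist(lapply(tl$stack_fold_rows, `[[`, "test"))
  expect_setequal(all_test, sets$A$source_ids)
})

test_that("prediction rejects unknown or misshaped feature sets", {
  sets <- get_complementary_fixture()
  cfg <- two_level_config(
    sae_first = sae_config(pretrain_epochs = 5, finetune_epochs = 10, seed = 7),
    stacking_folds = 3, seed = 24)
  tl <- train_two_level(unname(sets), cfg)
  expect_error(predict_two_level(tl, list(A = sets$A$matrix)),
               "missing feature set")
  expect_error(predict_two_level(tl, list(A = sets$A$matrix[, 1:3],
                                          B = sets$B$matrix)),
               "keyed shape error")
})
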