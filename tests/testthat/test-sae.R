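test_that("autoencoder training reduces reconstruction error", {
  set.seed(51)
  X <- matrix(runif(20 * 5), 20, 5)
  cfg <- sae_config(sparsity_weight = 0, l2_weight = 0,
                    pretrain_epochs = 80, seed = 3)
  enc <- train_autoencoder(X, 5, 5, cfg)
  expect_lt(tail(enc$loss_trace, 1), enc$loss_trace[1])
})

test_that("the KL sparsity penalty vanishes at its target", {
  expect_equal(subloc2l:::kl_sparsity(0.05, rep(0.05, 7)), 0)
  expect_gt(subloc2l:::kl_sparsity(0.05, rep(0.3, 7)), 0)
})

test_that("autoencoder gradients match central finite differences", {
  set.seed(52)
  X <- matrix(runif(2 * 3), 2, 3)
  cfg <- sae_config(sparsity_target = 0.1, sparsity_weight = 2,
                    l2_weight = 1e-3, seed = 4)
  set.seed(5)
  par <- list()
  e <- subloc2l:::init_layer(4, 3); par$We <- e$W; par$be <- e$b
  d <- subloc2l:::init_layer(3, 4); par$Wd <- d$W; par$bd <- d$b
  g <- subloc2l:::ae_loss_grad(par, X, cfg)
  eps <- 1e-6
  for (slot in c("We", "be", "Wd", "bd")) {
    num <- par[[slot]] * 0
    for (i in seq_along(par[[slot]])) {
      p2 <- par; p2[[slot]][i] <- p2[[slot]][i] + eps
      lp <- subloc2l:::ae_loss_grad(p2, X, cfg, grad = FALSE)$loss
      p2[[slot]][i] <- p2[[slot]][i] - 2 * eps
      lm <- subloc2l:::ae_loss_grad(p2, X, cfg, grad = FALSE)$loss
      num[i] <- (lp - lm) / (2 * eps)
    }
    ana <- g[[paste0("g", slot)]]
    expect_lt(max(abs(num - ana) / pmax(abs(num), 1e-4)), 1e-5)
  }
})

test_that("fine-tuning gradients match central finite differences", {
  set.seed(53)
  X <- matrix(runif(6 * 4), 6, 4)
  y <- c(1L, 2L, 3L, 1L, 2L, 3L)
  Yind <- matrix(0, 6, 3); Yind[cbind(1:6, y)] <- 1
  cfg <- sae_config(l2_weight = 1e-3, seed = 6)
  set.seed(7)
  model <- list(enc1 = subloc2l:::init_layer(5, 4),
                enc2 = subloc2l:::init_layer(4, 5),
                softmax = subloc2l:::init_layer(3, 4))
  g <- subloc2l:::sm_loss_grad(model, X, Yind, cfg)
  eps <- 1e-6
  slots <- list(c("enc1", "W", "gW1"), c("enc1", "b", "gb1"),
                c("enc2", "W", "gW2"), c("enc2", "b", "gb2"),
                c("softmax", "W", "gWs"), c("softmax", "b", "gbs"))
  for (s in slots) {
    num <- model[[s[1]]][[s[2]]] * 0
    for (i in seq_along(num)) {
      m2 <- model; m2[[s[1]]][[s[2]]][i] <- m2[[s[1]]][[s[2]]][i] + eps
      lp <- subloc2l:::sm_loss_grad(m2, X, Yind, cfg, grad = FALSE)$loss
      m2[[s[1]]][[s[2]]][i] <- m2[[s[1]]][[s[2]]][i] - 2 * eps
      lm <- subloc2l:::sm_loss_grad(m2, X, Yind, cfg, grad = FALSE)$loss
      num[i] <- (lp - lm) / (2 * eps)
    }
    expect_lt(max(abs(num - g[[s[3]]]) / pmax(abs(num), 1e-4)), 1e-5)
  }
})

test_that("layer-wise pretraining is seeded-deterministic and chains h1", {
  set.seed(54)
  X <- matrix(runif(15 * 6), 15, 6)
  cfg <- sae_config(hidden1 = 4, hidden2 = 3, pretrain_epochs = 30, seed = 8)
  a <- pretrain_stack(X, cfg)
  b <- pretrain_stack(X, cfg)
  expect_identical(a, b)
  # encoder 2 trained on externally recomputed h1 equals internal chaining
  H1 <- 1 / (1 + exp(-sweep(X %*% t(a$enc1$W), 2, a$enc1$b, "+")))
  enc2 <- train_autoencoder(H1, 4, 3, cfg,
                            seed = subloc2l:::derive_seed(cfg$seed, "enc2"))
  expect_equal(enc2$W, a$enc2$W, tolerance = 1e-12)
})

test_that("layer-2 reconstruction loss decreases during pretraining", {
  set.seed(55)
  X <- matrix(runif(20 * 4), 20, 4)
  cfg <- sae_config(hidden1 = 4, hidden2 = 4, sparsity_weight = 0,
                    pretrain_epochs = 60, seed = 9)
  st <- pretrain_stack(X, cfg)
  expect_lt(tail(st$enc2$loss_trace, 1), st$enc2$loss_trace[1])
})

test_that("fine-tuning reaches perfect accuracy on a separable 2-class toy", {
  set.seed(56)
  y <- rep(1:2, each = 20)
  X <- cbind(rnorm(40) + 4 * (y == 2), rnorm(40))
  # achievability check with an independent logistic fit
  glm_fit <- suppressWarnings(stats::glm((y == 2) ~ X, family = stats::binomial()))
  expect_gte(mean((stats::fitted(glm_fit) > 0.5) + 1 == y), 1)
  cfg <- sae_config(pretrain_epochs = 30, finetune_epochs = 150, seed = 10)
  m <- sae_fit(X, y, cfg)
  expect_equal(mean(predict(m, X) == y), 1)
  expect_lte(tail(m$finetune_trace, 1), m$finetune_trace[1])
})

test_that("zero fine-tune epochs leaves the pretrained network untouched", {
  set.seed(57)
  X <- matrix(runif(12 * 4), 12, 4)
  y <- rep(1:2, 6)
  cfg <- sae_config(hidden1 = 3, hidden2 = 2, pretrain_epochs = 20,
                    finetune_epochs = 0, seed = 11)
  m <- sae_fit(X, y, cfg)
  X01 <- subloc2l:::apply_minmax(m$scaler, X)
  enc <- pretrain_stack(X01, m$config)
  expect_equal(m$enc1$W, enc$enc1$W, tolerance = 1e-12)
  expect_equal(m$enc2$W, enc$enc2$W, tolerance = 1e-12)
  set.seed(subloc2l:::derive_seed(cfg$seed, "softmax_head"))
  head <- subloc2l:::init_layer(2, 2)
  expect_equal(m$softmax$W, head$W, tolerance = 1e-12)
})

test_that("predicted probability rows live on the simplex", {
  set.seed(58)
  X <- matrix(runif(20 * 5), 20, 5)
  y <- rep(1:2, 10)
  m <- sae_fit(X, y, sae_config(pretrain_epochs = 10, finetune_epochs = 10, seed = 12))
  P <- predict_proba(m, X)
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-9)
  expect_error(predict_proba(m, X[, 1:3]), "shape error")
})

test_that("a zero softmax head yields uniform rows; hand-set weights match a manual pass", {
  m <- structure(list(
    enc1 = list(W = matrix(c(1, -1, 0.5, 0.2, 0.1, -0.3), 2, 3), b = c(0.1, -0.2)),
    enc2 = list(W = matrix(c(0.3, -0.5, 0.7, 0.2), 2, 2), b = c(0, 0.1)),
    softmax = list(W = matrix(0, 3, 2), b = c(0, 0, 0)),
    scaler = list(min = rep(0, 3), range = rep(1, 3)),
    input_dim = 3L, n_classes = 3L, fitted = TRUE), class = "sae_sm")
  x <- matrix(c(0.2, 0.8, 0.5), 1, 3)
  P <- predict_proba(m, x)
  expect_equal(unname(P[1, ]), rep(1 / 3, 3), tolerance = 1e-12)
  # manual forward pass with a non-trivial head
  m$softmax$W <- matrix(c(1, 0, -1, 0.5, -0.5, 0.25), 3, 2)
  m$softmax$b <- c(0.1, 0, -0.1)
  sig <- function(z) 1 / (1 + exp(-z))
  h1 <- sig(m$enc1$W %*% t(x) + m$enc1$b)
  h2 <- sig(m$enc2$W %*% h1 + m$enc2$b)
  lg <- m$softmax$W %*% h2 + m$softmax$b
  expect_equal(unname(predict_proba(m, x)[1, ]),
               as.numeric(exp(lg) / sum(exp(lg))), tolerance = 1e-12)
})

test_that("the sparsity penalty pulls mean activations toward the target", {
  set.seed(59)
  X <- matrix(runif(30 * 6), 30, 6)
  rho <- 0.05
  mean_act <- function(beta) {
    cfg <- sae_config(sparsity_target = rho, sparsity_weight = beta,
                      pretrain_epochs = 120, seed = 13)
    enc <- train_autoencoder(X, 6, 6, cfg)
    H <- 1 / (1 + exp(-sweep(X %*% t(enc$W), 2, enc$b, "+")))
    mean(colMeans(H))
  }
  expect_lt(abs(mean_act(3) - rho), abs(mean_act(0) - rho))
})

test_that("a model archive round-trips through JSON", {
  set.seed(60)
  X <- matrix(runif(16 * 4), 16, 4)
  y <- rep(1:2, 8)
  m <- sae_fit(X, y, sae_config(pretrain_epochs = 15, finetune_epochs = 15, seed = 14))
  p <- file.path(tempdir(), "sae.json")
  save_sae(m, p)
  m2 <- load_sae(p)
  expect_equal(predict_proba(m2, X), predict_proba(m, X), tolerance = 1e-12)
})

test_that("missing classes in fine-tuning labels are rejected", {
  set.seed(61)
  X <- matrix(runif(10 * 3), 10, 3)
  expect_error(sae_fit(X, rep(1L, 10), sae_config(seed = 15), n_classes = 2),
               "label-coverage")
})
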