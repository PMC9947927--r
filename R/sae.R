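# Sparse stacked autoencoder with a softmax head (SAE-SM).
#
# Two sigmoid encoders trained greedily layer-by-layer as sparse autoencoders
# (mean squared reconstruction error + KL sparsity penalty + L2 weight decay),
# then stacked under a softmax classification layer and fine-tuned end to end
# by back-propagation on the categorical cross-entropy. All training is
# full-batch gradient descent, seeded and deterministic.

#' SAE-SM configuration
#'
#' @param hidden1,hidden2 hidden layer sizes; `NULL` defaults to
#'   `ceiling(d/2)` and `max(ceiling(d/4), C)` at fit time.
#' @param sparsity_target target mean activation rho of each hidden unit.
#' @param sparsity_weight KL penalty weight beta.
#' @param l2_weight weight-decay coefficient lambda.
#' @param pretrain_epochs,finetune_epochs full-batch gradient descent epochs.
#' @param learning_rate gradient-descent step size.
#' @param momentum classical momentum coefficient of the batch updates in
#'   \[0, 1); 0 recovers plain gradient descent.
#' @param seed integer seed for weight initialization.
#' @return a list of class `sae_config`.
#' @export
sae_config <- function(hidden1 = NULL, hidden2 = NULL,
                       sparsity_target = 0.05, sparsity_weight = 3,
                       l2_weight = 1e-4,
                       pretrain_epochs = 100L, finetune_epochs = 200L,
                       learning_rate = 1.0, momentum = 0.9, seed = 1L) {
  stopifnot(sparsity_target > 0, sparsity_target < 1,
            sparsity_weight >= 0, l2_weight >= 0,
            pretrain_epochs >= 0, finetune_epochs >= 0, learning_rate > 0,
            momentum >= 0, momentum < 1)
  structure(list(hidden1 = hidden1, hidden2 = hidden2,
                 sparsity_target = sparsity_target,
                 sparsity_weight = sparsity_weight,
                 l2_weight = l2_weight,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed)),
            class = "sae_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Glorot-style uniform init for a sigmoid layer, seeded by the caller.
init_layer <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  list(W = matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in),
       b = numeric(n_out))
}

# KL divergence between Bernoulli(rho) and Bernoulli(rho_hat), summed over
# units; rho_hat clamped away from {0,1} for stability.
kl_sparsity <- function(rho, rho_hat) {
  rho_hat <- pmin(pmax(rho_hat, 1e-8), 1 - 1e-8)
  sum(rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat)))
}

# Loss and analytic gradients of one sparse autoencoder on data X (rows =
# samples, already in [0,1]). Parameters: encoder (We,be), decoder (Wd,bd).
ae_loss_grad <- function(par, X, cfg, grad = TRUE) {
  N <- nrow(X)
  H <- sigmoid(sweep(X %*% t(par$We), 2, par$be, "+"))
  Xh <- sigmoid(sweep(H %*% t(par$Wd), 2, par$bd, "+"))
  rho_hat <- colMeans(H)
  rho <- cfg$sparsity_target
  loss <- sum((Xh - X)^2) / (2 * N) +
    cfg$sparsity_weight * kl_sparsity(rho, rho_hat) +
    cfg$l2_weight / 2 * (sum(par$We^2) + sum(par$Wd^2))
  if (!grad) return(list(loss = loss))
  d_out <- (Xh - X) / N * Xh * (1 - Xh)               # N x d
  gWd <- t(d_out) %*% H + cfg$l2_weight * par$Wd
  gbd <- colSums(d_out)
  rh <- pmin(pmax(rho_hat, 1e-8), 1 - 1e-8)
  kl_term <- cfg$sparsity_weight * (-rho / rh + (1 - rho) / (1 - rh)) / N
  d_hid <- (d_out %*% par$Wd + matrix(kl_term, N, length(rh), byrow = TRUE)) * H * (1 - H)
  gWe <- t(d_hid) %*% X + cfg$l2_weight * par$We
  gbe <- colSums(d_hid)
  list(loss = loss, gWe = gWe, gbe = gbe, gWd = gWd, gbd = gbd)
}

#' Train a single sparse autoencoder
#'
#' Minimizes mean squared reconstruction error plus the KL sparsity penalty
#' `beta * sum_u KL(rho || rho_hat_u)` and L2 weight decay by full-batch
#' gradient descent; returns the encoder weights only.
#'
#' @param X numeric N x in_dim matrix with values in \[0, 1\].
#' @param in_dim,out_dim layer dimensions (`in_dim` must equal `ncol(X)`).
#' @param cfg a [sae_config]; `pretrain_epochs` and `learning_rate` are used.
#' @param seed integer seed for initialization.
#' @return list with elements `W` (out_dim x in_dim), `b` (out_dim), and the
#'   training `loss_trace`.
#' @export
train_autoencoder <- function(X, in_dim, out_dim, cfg = sae_config(), seed = cfg$seed) {
  if (ncol(X) != in_dim) stop("shape error: ncol(X) != in_dim")
  if (nrow(X) < 2) stop("need at least 2 samples")
  set.seed(seed)
  par <- list()
  e <- init_layer(out_dim, in_dim); par$We <- e$W; par$be <- e$b
  d <- init_layer(in_dim, out_dim); par$Wd <- d$W; par$bd <- d$b
  trace <- numeric(cfg$pretrain_epochs)
  vel <- lapply(par, function(p) p * 0)
  mom <- cfg$momentum %||% 0
  lr <- cfg$learning_rate
  prev_loss <- Inf
  prev_par <- par
  for (ep in seq_len(cfg$pretrain_epochs)) {
    g <- ae_loss_grad(par, X, cfg)
    if (!is.finite(g$loss))
      stop("divergence error: non-finite autoencoder loss at epoch ", ep)
    # bold-driver rate adaptation: grow on improvement, on an increase undo
    # the step, halve the rate and reset momentum
    if (g$loss <= prev_loss + 1e-12) {
      lr <- lr * 1.05
      prev_loss <- g$loss
      prev_par <- par
    } else {
      par <- prev_par
      vel <- lapply(vel, function(v) v * 0)
      lr <- lr / 2
      g <- ae_loss_grad(par, X, cfg)
    }
    for (nm in c("We", "be", "Wd", "bd")) {
      vel[[nm]] <- mom * vel[[nm]] - lr * g[[paste0("g", nm)]]
      par[[nm]] <- par[[nm]] + vel[[nm]]
    }
    trace[ep] <- g$loss
  }
  list(W = par$We, b = par$be, loss_trace = trace)
}

#' Greedy layer-wise pretraining of the two encoders
#'
#' Encoder 1 is trained as a sparse autoencoder on X; encoder 2 on the
#' hidden activations `h1 = sigmoid(W1 x + b1)`.
#'
#' @param X numeric N x d matrix in \[0, 1\].
#' @param cfg a [sae_config] with resolved hidden sizes.
#' @return list `(enc1, enc2)` of encoder weights.
#' @export
pretrain_stack <- function(X, cfg) {
  enc1 <- train_autoencoder(X, ncol(X), cfg$hidden1, cfg,
                            seed = derive_seed(cfg$seed, "enc1"))
  H1 <- sigmoid(sweep(X %*% t(enc1$W), 2, enc1$b, "+"))
  enc2 <- train_autoencoder(H1, cfg$hidden1, cfg$hidden2, cfg,
                            seed = derive_seed(cfg$seed, "enc2"))
  list(enc1 = enc1, enc2 = enc2)
}

# Forward pass through the full network. Returns activations and row-wise
# softmax probabilities (numerically stabilized).
sae_forward <- function(model, X01) {
  H1 <- sigmoid(sweep(X01 %*% t(model$enc1$W), 2, model$enc1$b, "+"))
  H2 <- sigmoid(sweep(H1 %*% t(model$enc2$W), 2, model$enc2$b, "+"))
  logits <- sweep(H2 %*% t(model$softmax$W), 2, model$softmax$b, "+")
  z <- logits - apply(logits, 1, max)
  P <- exp(z) / rowSums(exp(z))
  list(H1 = H1, H2 = H2, logits = logits, probs = P)
}

# Cross-entropy loss + L2 and full analytic gradients of the stacked network.
sm_loss_grad <- function(model, X01, Yind, cfg, grad = TRUE) {
  N <- nrow(X01)
  fw <- sae_forward(model, X01)
  eps <- 1e-12
  loss <- -sum(Yind * log(fw$probs + eps)) / N +
    cfg$l2_weight / 2 * (sum(model$enc1$W^2) + sum(model$enc2$W^2) +
                           sum(model$softmax$W^2))
  if (!grad) return(list(loss = loss))
  d_log <- (fw$probs - Yind) / N
  gWs <- t(d_log) %*% fw$H2 + cfg$l2_weight * model$softmax$W
  gbs <- colSums(d_log)
  d2 <- (d_log %*% model$softmax$W) * fw$H2 * (1 - fw$H2)
  gW2 <- t(d2) %*% fw$H1 + cfg$l2_weight * model$enc2$W
  gb2 <- colSums(d2)
  d1 <- (d2 %*% model$enc2$W) * fw$H1 * (1 - fw$H1)
  gW1 <- t(d1) %*% X01 + cfg$l2_weight * model$enc1$W
  gb1 <- colSums(d1)
  list(loss = loss, gWs = gWs, gbs = gbs, gW2 = gW2, gb2 = gb2,
       gW1 = gW1, gb1 = gb1)
}

#' Supervised fine-tuning of the stacked network
#'
#' Initializes the full network from the pretrained encoders plus a randomly
#' initialized softmax head and minimizes the categorical cross-entropy (plus
#' L2 weight decay) by back-propagation through all layers.
#'
#' @param enc1,enc2 encoder weight lists from [pretrain_stack()].
#' @param X numeric N x d matrix in \[0, 1\].
#' @param y integer labels in 1..C; every class must be present.
#' @param cfg a [sae_config].
#' @param n_classes number of classes C.
#' @return list of network weights plus `finetune_trace`.
#' @export
fine_tune <- function(enc1, enc2, X, y, cfg, n_classes = max(y)) {
  y <- as.integer(y)
  if (!all(seq_len(n_classes) %in% y))
    stop("label-coverage error: every class in 1..", n_classes,
         " must appear in y")
  set.seed(derive_seed(cfg$seed, "softmax_head"))
  head <- init_layer(n_classes, cfg$hidden2)
  model <- list(enc1 = enc1, enc2 = enc2,
                softmax = list(W = head$W, b = head$b))
  Yind <- matrix(0, nrow(X), n_classes)
  Yind[cbind(seq_len(nrow(X)), y)] <- 1
  trace <- numeric(cfg$finetune_epochs)
  mom <- cfg$momentum %||% 0
  slots <- list(c("softmax", "W", "gWs"), c("softmax", "b", "gbs"),
                c("enc2", "W", "gW2"), c("enc2", "b", "gb2"),
                c("enc1", "W", "gW1"), c("enc1", "b", "gb1"))
  vel <- lapply(slots, function(s) model[[s[1]]][[s[2]]] * 0)
  lr <- cfg$learning_rate
  prev_loss <- Inf
  prev_model <- model
  for (ep in seq_len(cfg$finetune_epochs)) {
    g <- sm_loss_grad(model, X, Yind, cfg)
    if (!is.finite(g$loss))
      stop("divergence error: non-finite fine-tuning loss at epoch ", ep)
    # bold-driver rate adaptation, as in pretraining
    if (g$loss <= prev_loss + 1e-12) {
      lr <- lr * 1.05
      prev_loss <- g$loss
      prev_model <- model
    } else {
      model <- prev_model
      vel <- lapply(vel, function(v) v * 0)
      lr <- lr / 2
      g <- sm_loss_grad(model, X, Yind, cfg)
    }
    for (k in seq_along(slots)) {
      s <- slots[[k]]
      vel[[k]] <- mom * vel[[k]] - lr * g[[s[3]]]
      model[[s[1]]][[s[2]]] <- model[[s[1]]][[s[2]]] + vel[[k]]
    }
    trace[ep] <- g$loss
  }
  model$finetune_trace <- trace
  model
}

#' Fit an SAE-SM classifier
#'
#' Full training procedure: per-feature min-max scaling to \[0, 1\] (fit on
#' the provided rows), greedy layer-wise pretraining of the two sparse
#' encoders, then supervised fine-tuning under the softmax head.
#'
#' @param X numeric N x d matrix of raw feature values.
#' @param y integer labels in 1..C.
#' @param cfg a [sae_config].
#' @param n_classes number of classes C (default `max(y)`).
#' @param sample_ids optional ids recorded by the leakage audit.
#' @return an object of class `sae_sm`.
#' @export
sae_fit <- function(X, y, cfg = sae_config(), n_classes = max(y),
                    sample_ids = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  audit_record("sae_fit", sample_ids %||% rownames(X) %||% seq_len(nrow(X)))
  cfg$hidden1 <- cfg$hidden1 %||% max(ceiling(ncol(X) / 2), n_classes)
  cfg$hidden2 <- cfg$hidden2 %||% max(ceiling(ncol(X) / 4), n_classes)
  scaler <- fit_minmax(X)
  X01 <- apply_minmax(scaler, X)
  enc <- pretrain_stack(X01, cfg)
  net <- fine_tune(enc$enc1, enc$enc2, X01, y, cfg, n_classes)
  structure(list(enc1 = net$enc1, enc2 = net$enc2, softmax = net$softmax,
                 scaler = scaler, config = cfg,
                 input_dim = ncol(X), n_classes = n_classes,
                 finetune_trace = net$finetune_trace, fitted = TRUE),
            class = "sae_sm")
}

#' Class probabilities from a fitted SAE-SM
#'
#' @param model a fitted `sae_sm`.
#' @param X numeric matrix with `model$input_dim` columns.
#' @return N x C matrix of class probabilities; rows sum to 1.
#' @export
predict_proba <- function(model, X) {
  if (!inherits(model, "sae_sm") || !isTRUE(model$fitted))
    stop("`model` must be a fitted sae_sm")
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim)
    stop("shape error: X has ", ncol(X), " columns; model expects ", model$input_dim)
  sae_forward(model, apply_minmax(model$scaler, X))$probs
}

#' @export
predict.sae_sm <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  P <- predict_proba(object, newdata)
  if (type == "prob") return(P)
  max.col(P, ties.method = "first")
}

#' Serialize an SAE-SM model to a self-describing JSON archive
#'
#' Weights, scaler, configuration and schema version are stored as JSON so
#' archives are portable text.
#'
#' @param model a fitted `sae_sm`.
#' @param path output file path.
#' @export
save_sae <- function(model, path) {
  obj <- list(schema = "subloc2l/sae_sm/1",
              input_dim = model$input_dim, n_classes = model$n_classes,
              config = unclass(model$config),
              scaler = model$scaler,
              enc1 = list(W = model$enc1$W, b = model$enc1$b),
              enc2 = list(W = model$enc2$W, b = model$enc2$b),
              softmax = list(W = model$softmax$W, b = model$softmax$b))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Load an SAE-SM model saved by [save_sae()]
#'
#' @param path archive path.
#' @return a fitted `sae_sm`.
#' @export
load_sae <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "subloc2l/sae_sm/1"))
    stop("unrecognized model archive schema: ", obj$schema)
  cfg <- do.call(sae_config, obj$config[!vapply(obj$config, is.null, logical(1))])
  cfg$hidden1 <- obj$config$hidden1; cfg$hidden2 <- obj$config$hidden2
  structure(list(enc1 = list(W = obj$enc1$W, b = as.numeric(obj$enc1$b)),
                 enc2 = list(W = obj$enc2$W, b = as.numeric(obj$enc2$b)),
                 softmax = list(W = obj$softmax$W, b = as.numeric(obj$softmax$b)),
                 scaler = list(min = as.numeric(obj$scaler$min),
                               range = as.numeric(obj$scaler$range)),
                 config = cfg, input_dim = obj$input_dim,
                 n_classes = obj$n_classes, fitted = TRUE),
            class = "sae_sm")
}
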