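# Multiclass evaluation metrics and the stringent cross-validation harness.
#
# Metrics: overall accuracy, macro-averaged one-vs-rest precision / recall /
# F1, the multiclass Matthews correlation (Gorodkin's R_K on the confusion
# matrix), and per-class one-vs-rest ROC AUC / PR AUPR summarized as
# mean/std over classes (population std). Cross-validation is stratified and
# re-runs feature selection, scaler fitting and model training inside every
# fold.

#' Multiclass metrics report
#'
#' @param y_true integer labels in 1..C.
#' @param y_pred integer predicted labels in 1..C.
#' @param probs optional N x C class-probability matrix (rows on the
#'   simplex); required for the AUC / AUPR block.
#' @param n_classes number of classes C (default `max(y_true, y_pred)`).
#' @return list of class `subloc_metrics`: `oa`, `rec_macro`, `prec_macro`,
#'   `f1_macro`, `mcc`, `confusion`, and with `probs`: `per_class_auc`,
#'   `per_class_aupr`, `mean_auc`, `std_auc`, `mean_aupr`, `std_aupr`.
#' @export
compute_metrics <- function(y_true, y_pred, probs = NULL,
                            n_classes = max(c(y_true, y_pred))) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  N <- length(y_true)
  if (length(y_pred) != N) stop("length mismatch")
  C <- n_classes
  conf <- matrix(0L, C, C, dimnames = list(true = 1:C, pred = 1:C))
  for (i in seq_len(N)) conf[y_true[i], y_pred[i]] <- conf[y_true[i], y_pred[i]] + 1L
  oa <- sum(diag(conf)) / N
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  # Gorodkin's R_K generalized correlation
  cc <- sum(diag(conf)) * N - sum(rowSums(conf) * colSums(conf))
  d1 <- sqrt(N^2 - sum(colSums(conf)^2)) * sqrt(N^2 - sum(rowSums(conf)^2))
  mcc <- if (d1 > 0) cc / d1 else 0
  out <- list(oa = oa, rec_macro = mean(rec), prec_macro = mean(prec),
              f1_macro = mean(f1), mcc = mcc, confusion = conf,
              per_class_precision = prec, per_class_recall = rec,
              per_class_f1 = f1, n = N)
  if (!is.null(probs)) {
    probs <- as.matrix(probs)
    if (nrow(probs) != N || ncol(probs) != C) stop("shape error: probs must be N x C")
    auc <- aupr <- rep(NA_real_, C)
    for (cl in seq_len(C)) {
      pos <- y_true == cl
      if (!any(pos)) {
        warning("class ", cl, " absent from y_true; AUC/AUPR undefined and excluded")
        next
      }
      if (all(pos)) { auc[cl] <- NA; aupr[cl] <- NA; next }
      auc[cl] <- roc_auc(probs[, cl], pos)
      aupr[cl] <- pr_auc(probs[, cl], pos)
    }
    ok <- !is.na(auc)
    pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
    out$per_class_auc <- auc
    out$per_class_aupr <- aupr
    out$mean_auc <- mean(auc[ok]); out$std_auc <- pop_sd(auc[ok])
    out$mean_aupr <- mean(aupr[ok]); out$std_aupr <- pop_sd(aupr[ok])
  }
  structure(out, class = "subloc_metrics")
}

# One-vs-rest ROC AUC by trapezoid over all unique score thresholds
# (equivalently the tie-corrected Mann-Whitney statistic).
roc_auc <- function(score, pos) {
  thr <- sort(unique(score), decreasing = TRUE)
  nP <- sum(pos); nN <- sum(!pos)
  tpr <- c(0, vapply(thr, function(t) sum(score >= t & pos), numeric(1)) / nP)
  fpr <- c(0, vapply(thr, function(t) sum(score >= t & !pos), numeric(1)) / nN)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# One-vs-rest PR area by step-wise interpolation of precision: walking the
# thresholds from high to low, each recall increment contributes the
# precision at that threshold.
pr_auc <- function(score, pos) {
  thr <- sort(unique(score), decreasing = TRUE)
  nP <- sum(pos)
  rec <- 0; area <- 0
  for (t in thr) {
    sel <- score >= t
    r <- sum(sel & pos) / nP
    p <- sum(sel & pos) / sum(sel)
    area <- area + (r - rec) * p
    rec <- r
  }
  area
}

#' Stringent stratified k-fold cross-validation
#'
#' Per fold, the full training procedure — feature selection, scaler fitting
#' and network training — is re-run on the k-1 training folds only, and the
#' held-out fold is predicted. Reports per-fold metrics and metrics pooled
#' over the concatenated held-out predictions.
#'
#' @param raw_sets list of [feature_set] objects sharing sample order; a
#'   single-element list with `model = "single"` evaluates one SDA + SAE-SM
#'   classifier instead of the two-level integrator.
#' @param k number of folds (default 10); every class must have >= k rows.
#' @param cfg a [two_level_config].
#' @param seed seed for the fold split (default `cfg$seed`).
#' @param model `"two_level"` or `"single"`.
#' @return list with `pooled` (a `subloc_metrics`), `per_fold` (list of
#'   `subloc_metrics`), `fold` (fold assignment), `predictions`
#'   (data.frame of source_id, fold, true, pred).
#' @export
stratified_kfold_cv <- function(raw_sets, k = 10L, cfg = two_level_config(),
                                seed = cfg$seed, model = c("two_level", "single")) {
  model <- match.arg(model)
  if (model == "single" && length(raw_sets) != 1)
    stop("model = 'single' requires exactly one feature set")
  y <- raw_sets[[1]]$labels
  cls <- sort(unique(y))
  ymap <- match(y, cls)
  C <- length(cls)
  N <- length(y)
  fold <- stratified_folds(ymap, k, derive_seed(seed, "cv"))
  y_pred <- integer(N)
  probs <- matrix(NA_real_, N, C)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    audit_context(sprintf("fold_%d", f))
    tr <- which(fold != f); te <- which(fold == f)
    train_sets <- lapply(raw_sets, subset_fs, rows = tr)
    if (model == "two_level") {
      fit <- train_two_level(train_sets, cfg)
      te_mats <- lapply(raw_sets, function(fs) fs$matrix[te, , drop = FALSE])
      names(te_mats) <- names(fit$first_level)
      pr <- predict_two_level(fit, te_mats)
      pred_f <- match(pr$labels, cls)
      probs_f <- pr$probs
    } else {
      fs_tr <- train_sets[[1]]
      fs_tr$labels <- ymap[tr]
      one <- fit_one_set(fs_tr, cfg, C, sprintf("cv_single_f%d", f))
      Xte <- project_selection(one$selection, raw_sets[[1]]$matrix[te, , drop = FALSE])
      probs_f <- predict_proba(one$model, Xte)
      pred_f <- max.col(probs_f, ties.method = "first")
    }
    y_pred[te] <- pred_f
    probs[te, ] <- probs_f
    per_fold[[f]] <- compute_metrics(ymap[te], pred_f, probs_f, n_classes = C)
  }
  audit_context("global")
  pooled <- compute_metrics(ymap, y_pred, probs, n_classes = C)
  list(pooled = pooled, per_fold = per_fold, fold = fold,
       predictions = data.frame(source_id = raw_sets[[1]]$source_ids,
                                fold = fold, true = cls[ymap],
                                pred = cls[y_pred]))
}

#' @export
print.subloc_metrics <- function(x, ...) {
  cat(sprintf("multiclass metrics (N = %d):\n", x$n))
  cat(sprintf("  OA      %.4f\n  Prec_M  %.4f\n  Rec_M   %.4f\n  F1_M    %.4f\n  MCC     %.4f\n",
              x$oa, x$prec_macro, x$rec_macro, x$f1_macro, x$mcc))
  if (!is.null(x$mean_auc))
    cat(sprintf("  meanAUC %.4f (std %.4f)   meanAUPR %.4f (std %.4f)\n",
                x$mean_auc, x$std_auc, x$mean_aupr, x$std_aupr))
  invisible(x)
}
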