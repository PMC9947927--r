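# Two-level SAE-SM integrator.
#
# Level one trains an SAE-SM per optimal (SDA-selected) heterogeneous feature
# set. The per-set class-probability matrices ("intermediate decision" sets
# p_t) are fused by the mean ensemble F_ME = (1/T) sum_t p_t, and a
# second-level SAE-SM is trained on F_ME. To keep the second level leak-free,
# its training inputs are built out-of-fold: the training rows are split into
# stratified stacking folds and each row's p_t comes from a first-level model
# (selection + SAE-SM) fitted without that row.

#' Mean ensemble of decision sets
#'
#' Element-wise arithmetic mean of T class-probability matrices; rows remain
#' on the probability simplex.
#'
#' @param decisions non-empty list of N x C matrices.
#' @return N x C matrix.
#' @export
mean_ensemble <- function(decisions) {
  if (!is.list(decisions) || length(decisions) == 0)
    stop("argument error: `decisions` must be a non-empty list")
  d0 <- dim(decisions[[1]])
  for (p in decisions)
    if (!all(dim(p) == d0)) stop("shape error: decision sets differ in shape")
  Reduce(`+`, decisions) / length(decisions)
}

#' Two-level model configuration
#'
#' @param sda list of arguments for [sda_select()] (`f_enter`, `f_remove`,
#'   `max_features`).
#' @param sae_first a [sae_config] template for the first-level networks.
#' @param sae_second a [sae_config] for the second-level network; its hidden
#'   sizes default to (C, C) since its input dimension is the class count.
#' @param stacking_folds stratified folds used to build out-of-fold
#'   intermediate decisions (default 5).
#' @param seed root seed.
#' @return a list of class `two_level_config`.
#' @export
two_level_config <- function(sda = list(), sae_first = sae_config(),
                             sae_second = NULL, stacking_folds = 5L, seed = 1L) {
  structure(list(sda = sda, sae_first = sae_first, sae_second = sae_second,
                 stacking_folds = as.integer(stacking_folds),
                 seed = as.integer(seed)),
            class = "two_level_config")
}

# Fit selection + SAE-SM on one feature set (already subset to training rows).
fit_one_set <- function(fs, cfg, n_classes, seed_tag) {
  sel <- do.call(sda_select, c(list(fs = fs), cfg$sda))
  Xopt <- project_selection(sel, fs$matrix)
  sae_cfg <- cfg$sae_first
  sae_cfg$seed <- derive_seed(cfg$seed, seed_tag)
  model <- sae_fit(Xopt, fs$labels, sae_cfg, n_classes = n_classes,
                   sample_ids = fs$source_ids)
  list(selection = sel, model = model)
}

subset_fs <- function(fs, rows) {
  feature_set(fs$name, fs$matrix[rows, , drop = FALSE], fs$labels[rows],
              feature_ids = fs$feature_ids, source_ids = fs$source_ids[rows])
}

#' Train the two-level SAE-SM integrator
#'
#' Per feature set: SDA selection then a first-level SAE-SM. Out-of-fold
#' intermediate decisions are generated with `stacking_folds` stratified
#' folds (fold-specific selection and SAE-SM trained on the remaining folds
#' only), fused by [mean_ensemble()], and the second-level SAE-SM is trained
#' on the fused matrix. Deployed first-level models are refit on all
#' provided rows.
#'
#' @param raw_sets list of [feature_set] objects sharing sample order and
#'   labels.
#' @param cfg a [two_level_config].
#' @return an object of class `two_level_sae`.
#' @export
train_two_level <- function(raw_sets, cfg = two_level_config()) {
  if (length(raw_sets) < 1) stop("argument error: need at least one feature set")
  y <- raw_sets[[1]]$labels
  ids <- raw_sets[[1]]$source_ids
  for (fs in raw_sets) {
    if (!identical(fs$labels, y))
      stop("all feature sets must share sample order and labels")
  }
  C <- length(unique(y))
  if (C < 2) stop("need at least 2 classes")
  if (any(table(y) < cfg$stacking_folds))
    stop("stratification error: every class needs at least stacking_folds = ",
         cfg$stacking_folds, " rows; reduce stacking_folds or add samples")
  T_ <- length(raw_sets)
  N <- length(y)
  cls <- sort(unique(y))
  ymap <- match(y, cls)

  fold <- stratified_folds(ymap, cfg$stacking_folds, derive_seed(cfg$seed, "stacking"))
  oof <- lapply(seq_len(T_), function(t) matrix(NA_real_, N, C))
  fold_rows <- vector("list", cfg$stacking_folds)
  for (f in seq_len(cfg$stacking_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    fold_rows[[f]] <- list(train = ids[tr], test = ids[te])
    for (t in seq_len(T_)) {
      fs_tr <- subset_fs(raw_sets[[t]], tr)
      fs_tr$labels <- ymap[tr]
      fit <- fit_one_set(fs_tr, cfg, C, sprintf("stack_f%d_t%d", f, t))
      Xte <- project_selection(fit$selection, raw_sets[[t]]$matrix[te, , drop = FALSE])
      oof[[t]][te, ] <- predict_proba(fit$model, Xte)
    }
  }
  fme <- mean_ensemble(oof)

  sec_cfg <- cfg$sae_second %||% {
    sc <- cfg$sae_first
    sc$hidden1 <- C; sc$hidden2 <- C
    sc
  }
  sec_cfg$hidden1 <- sec_cfg$hidden1 %||% C
  sec_cfg$hidden2 <- sec_cfg$hidden2 %||% C
  sec_cfg$seed <- derive_seed(cfg$seed, "second_level")
  second <- sae_fit(fme, ymap, sec_cfg, n_classes = C, sample_ids = ids)

  first_level <- lapply(seq_len(T_), function(t) {
    fs <- raw_sets[[t]]
    fs$labels <- ymap
    fit <- fit_one_set(fs, cfg, C, sprintf("deploy_t%d", t))
    list(name = raw_sets[[t]]$name, selection = fit$selection, model = fit$model)
  })
  names(first_level) <- vapply(raw_sets, `[[`, character(1), "name")

  structure(list(first_level = first_level, second_level = second,
                 n_classes = C, classes = cls,
                 stacking_folds = cfg$stacking_folds, seed = cfg$seed,
                 oof_decisions = oof, fme = fme,
                 stack_fold_rows = fold_rows, config = cfg),
            class = "two_level_sae")
}

#' Predict with a two-level SAE-SM model
#'
#' Each per-set matrix is projected onto its stored selected columns and
#' scored by the deployed first-level model; the decision matrices are fused
#' by [mean_ensemble()] and passed to the second-level network. Predicted
#' labels are the row-wise argmax (ties break to the lowest class index).
#'
#' @param model a `two_level_sae`.
#' @param raw_matrices named list of numeric matrices, one per first-level
#'   feature set, at the raw (pre-selection) dimensionality.
#' @return list with `labels` (length M, on the original label scale) and
#'   `probs` (M x C matrix).
#' @export
predict_two_level <- function(model, raw_matrices) {
  if (!inherits(model, "two_level_sae")) stop("`model` must be a two_level_sae")
  nms <- names(model$first_level)
  missing_sets <- setdiff(nms, names(raw_matrices))
  if (length(missing_sets) > 0)
    stop("keyed shape error: missing feature set(s): ",
         paste(missing_sets, collapse = ", "))
  decisions <- lapply(nms, function(nm) {
    fl <- model$first_level[[nm]]
    X <- as.matrix(raw_matrices[[nm]])
    if (ncol(X) != length(fl$selection$center))
      stop("keyed shape error: set ", nm, " has ", ncol(X),
           " columns; expected ", length(fl$selection$center))
    predict_proba(fl$model, project_selection(fl$selection, X))
  })
  fme <- mean_ensemble(decisions)
  probs <- predict_proba(model$second_level, fme)
  list(labels = model$classes[max.col(probs, ties.method = "first")],
       probs = probs, fme = fme)
}
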