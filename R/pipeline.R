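# End-to-end orchestration: configuration handling and the command dispatcher
# wiring imaging -> features -> selection -> networks -> evaluation. Every
# stochastic component derives its stream from the single root seed, so
# component runs and end-to-end runs agree.

default_pipeline_config <- function() {
  list(
    stain = list(dna_vector = c(0.650, 0.704, 0.286),
                 protein_vector = c(0.269, 0.568, 0.778),
                 background = 255),
    sda = list(f_enter = 3.84, f_remove = 2.71, max_features = 40),
    sae = list(hidden1 = NULL, hidden2 = NULL, sparsity_target = 0.05,
               sparsity_weight = 3, l2_weight = 1e-4,
               pretrain_epochs = 100, finetune_epochs = 200,
               learning_rate = 0.1),
    sae_second = list(),
    stacking_folds = 5,
    cv = list(k = 10),
    fixtures = list(n_classes = 7, images_per_class = 35,
                    image_size = c(256, 256), noise_sd = 1),
    seed = 1,
    paths = list(input_dir = NULL, manifest = NULL, output_dir = "subloc2l_out"))
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, and validates every
#' key; unknown or ill-typed keys are reported together in one error.
#'
#' @param config path to a YAML file, or a named list of overrides, or NULL
#'   for the defaults.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL) {
  base <- default_pipeline_config()
  if (is.character(config)) {
    if (!file.exists(config)) stop("path error: config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  errs <- character(0)
  bad <- setdiff(names(config), names(base))
  if (length(bad) > 0)
    errs <- c(errs, paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  for (blk in intersect(names(config), names(base))) {
    if (is.list(base[[blk]]) && !is.null(config[[blk]])) {
      if (!is.list(config[[blk]])) {
        errs <- c(errs, paste0("config block `", blk, "` must be a mapping"))
        next
      }
      bad2 <- setdiff(names(config[[blk]]), names(base[[blk]]))
      if (length(bad2) > 0 && length(names(base[[blk]])) > 0)
        errs <- c(errs, paste0("unknown key(s) in `", blk, "`: ",
                               paste(bad2, collapse = ", ")))
    }
  }
  cfg <- utils::modifyList(base, config, keep.null = TRUE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    errs <- c(errs, "`seed` must be a single number")
  if (!is.null(cfg$sda$f_enter) && !is.null(cfg$sda$f_remove) &&
      cfg$sda$f_enter < cfg$sda$f_remove)
    errs <- c(errs, "`sda.f_enter` must be >= `sda.f_remove`")
  if (cfg$stacking_folds < 2) errs <- c(errs, "`stacking_folds` must be >= 2")
  if (cfg$cv$k < 2) errs <- c(errs, "`cv.k` must be >= 2")
  if (length(errs) > 0)
    stop("config error:\n  - ", paste(errs, collapse = "\n  - "))
  structure(cfg, class = "pipeline_config")
}

cfg_stain_basis <- function(cfg) {
  stain_basis(cfg$stain$dna_vector, cfg$stain$protein_vector, cfg$stain$background)
}

cfg_two_level <- function(cfg) {
  mk_sae <- function(lst, seed) {
    do.call(sae_config, c(lst[!vapply(lst, is.null, logical(1))], list(seed = seed)))
  }
  two_level_config(
    sda = cfg$sda,
    sae_first = mk_sae(cfg$sae, derive_seed(cfg$seed, "sae_first")),
    sae_second = if (length(cfg$sae_second) > 0)
      mk_sae(cfg$sae_second, derive_seed(cfg$seed, "sae_second")) else NULL,
    stacking_folds = cfg$stacking_folds,
    seed = cfg$seed)
}

read_manifest_images <- function(cfg) {
  manifest_path <- cfg$paths$manifest %||%
    file.path(cfg$paths$input_dir %||% cfg$paths$output_dir, "manifest.tsv")
  if (!file.exists(manifest_path))
    stop("path error: manifest not found: ", manifest_path)
  man <- utils::read.delim(manifest_path)
  if (!all(c("image_path", "label") %in% names(man)))
    stop("manifest must have columns image_path and label")
  images <- lapply(man$image_path, read_rgb_image)
  list(images = images, labels = as.integer(man$label), manifest = man)
}

load_feature_sets <- function(dir) {
  paths <- list.files(dir, pattern = "^features_.*\\.csv$", full.names = TRUE)
  if (length(paths) == 0) stop("path error: no feature CSVs found in ", dir)
  sets <- lapply(paths, function(p)
    read_feature_csv(p, name = sub("^features_", "", tools::file_path_sans_ext(basename(p)))))
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Run a pipeline command
#'
#' Commands: `make-fixtures` (write a synthetic dataset), `extract` (images
#' + manifest -> per-set feature CSVs), `select` (feature CSVs ->
#' selected-index JSON + reduced CSVs), `train` (feature CSVs -> model
#' archive), `predict` (model + feature CSVs -> prediction TSV), `cv`
#' (feature CSVs -> metrics JSON + confusion TSV). Each command writes its
#' artifacts plus a run log recording the config and seed into the output
#' directory.
#'
#' @param config a [pipeline_config], YAML path, list of overrides, or NULL.
#' @param command one of `"make-fixtures"`, `"extract"`, `"select"`,
#'   `"train"`, `"predict"`, `"cv"`.
#' @return invisibly, a list of artifact paths written.
#' @export
run <- function(config = NULL, command = c("cv", "extract", "select", "train",
                                           "predict", "make-fixtures")) {
  command <- match.arg(command)
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  out_dir <- cfg$paths$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)

  if (command == "make-fixtures") {
    spec <- synthetic_spec(
      n_classes = cfg$fixtures$n_classes,
      images_per_class = cfg$fixtures$images_per_class,
      image_size = cfg$fixtures$image_size,
      noise_sd = cfg$fixtures$noise_sd,
      basis = cfg_stain_basis(cfg),
      seed = cfg$seed)
    ds <- generate_dataset(spec, dir = out_dir, keep_truth = FALSE)
    written <- file.path(out_dir, "manifest.tsv")
  } else if (command == "extract") {
    inp <- read_manifest_images(cfg)
    sets <- extract_feature_sets(inp$images, inp$labels, cfg_stain_basis(cfg))
    for (fs in sets) {
      p <- file.path(out_dir, sprintf("features_%s.csv", fs$name))
      write_feature_csv(fs, p)
      written <- c(written, p)
    }
  } else if (command == "select") {
    sets <- load_feature_sets(cfg$paths$input_dir %||% out_dir)
    sel_json <- list()
    for (fs in sets) {
      sel <- do.call(sda_select, c(list(fs = fs), cfg$sda))
      sel_json[[fs$name]] <- list(selected = sel$selected,
                                  feature_ids = sel$feature_ids,
                                  lambda_trace = sel$lambda_trace)
      red <- feature_set(fs$name, project_selection(sel, fs$matrix), fs$labels,
                         feature_ids = sel$feature_ids, source_ids = fs$source_ids)
      p <- file.path(out_dir, sprintf("selected_%s.csv", fs$name))
      write_feature_csv(red, p)
      written <- c(written, p)
    }
    pj <- file.path(out_dir, "selection.json")
    jsonlite::write_json(sel_json, pj, digits = NA, auto_unbox = TRUE)
    written <- c(written, pj)
  } else if (command == "train") {
    sets <- load_feature_sets(cfg$paths$input_dir %||% out_dir)
    model <- train_two_level(unname(sets), cfg_two_level(cfg))
    p <- file.path(out_dir, "model.json")
    save_two_level(model, p)
    written <- c(written, p)
  } else if (command == "predict") {
    sets <- load_feature_sets(cfg$paths$input_dir %||% out_dir)
    model <- load_two_level(file.path(out_dir, "model.json"))
    mats <- lapply(sets, `[[`, "matrix")
    pr <- predict_two_level(model, mats)
    df <- data.frame(source_id = sets[[1]]$source_ids,
                     predicted_label = pr$labels)
    probs <- as.data.frame(pr$probs)
    names(probs) <- sprintf("prob_class_%d", seq_len(ncol(probs)))
    p <- file.path(out_dir, "predictions.tsv")
    utils::write.table(cbind(df, probs), p, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, p)
  } else if (command == "cv") {
    sets <- load_feature_sets(cfg$paths$input_dir %||% out_dir)
    res <- stratified_kfold_cv(unname(sets), k = cfg$cv$k, cfg = cfg_two_level(cfg))
    rep_json <- list(
      pooled = metrics_as_list(res$pooled),
      per_fold = lapply(res$per_fold, metrics_as_list),
      k = cfg$cv$k, seed = cfg$seed)
    pj <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(rep_json, pj, digits = NA, auto_unbox = TRUE)
    pc <- file.path(out_dir, "confusion.tsv")
    utils::write.table(res$pooled$confusion, pc, sep = "\t", quote = FALSE)
    written <- c(written, pj, pc)
  }

  log_path <- file.path(out_dir, "run_log.txt")
  cat(sprintf("command: %s\nseed: %s\nconfig_hash: %s\n",
              command, cfg$seed,
              digest_config(cfg)),
      file = log_path)
  invisible(c(written, log_path))
}

# Cheap deterministic config digest (sum of char codes of the deparsed
# config) for the run log; not cryptographic.
digest_config <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% .Machine$integer.max)
}

metrics_as_list <- function(m) {
  list(oa = m$oa, prec_macro = m$prec_macro, rec_macro = m$rec_macro,
       f1_macro = m$f1_macro, mcc = m$mcc,
       mean_auc = m$mean_auc, std_auc = m$std_auc,
       mean_aupr = m$mean_aupr, std_aupr = m$std_aupr, n = m$n)
}

#' Serialize a two-level model to a JSON archive
#'
#' @param model a `two_level_sae`.
#' @param path output path.
#' @export
save_two_level <- function(model, path) {
  ser_sel <- function(s) list(selected = s$selected, center = s$center,
                              scale = s$scale, feature_ids = s$feature_ids)
  obj <- list(schema = "subloc2l/two_level/1",
              n_classes = model$n_classes, classes = model$classes,
              stacking_folds = model$stacking_folds, seed = model$seed,
              first_level = lapply(model$first_level, function(fl)
                list(name = fl$name, selection = ser_sel(fl$selection),
                     model = sae_as_list(fl$model))),
              second_level = sae_as_list(model$second_level))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

sae_as_list <- function(m) {
  list(input_dim = m$input_dim, n_classes = m$n_classes,
       scaler = m$scaler,
       enc1 = list(W = m$enc1$W, b = m$enc1$b),
       enc2 = list(W = m$enc2$W, b = m$enc2$b),
       softmax = list(W = m$softmax$W, b = m$softmax$b))
}

sae_from_list <- function(o) {
  as_mat <- function(x) if (is.matrix(x)) x else matrix(unlist(x), nrow = length(x), byrow = TRUE)
  structure(list(enc1 = list(W = as_mat(o$enc1$W), b = as.numeric(o$enc1$b)),
                 enc2 = list(W = as_mat(o$enc2$W), b = as.numeric(o$enc2$b)),
                 softmax = list(W = as_mat(o$softmax$W), b = as.numeric(o$softmax$b)),
                 scaler = list(min = as.numeric(o$scaler$min),
                               range = as.numeric(o$scaler$range)),
                 input_dim = o$input_dim, n_classes = o$n_classes,
                 fitted = TRUE),
            class = "sae_sm")
}

#' Load a two-level model saved by [save_two_level()]
#'
#' @param path archive path.
#' @return a `two_level_sae`.
#' @export
load_two_level <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "subloc2l/two_level/1"))
    stop("unrecognized model archive schema")
  first <- lapply(obj$first_level, function(fl) {
    sel <- structure(list(selected = as.integer(fl$selection$selected),
                          center = as.numeric(fl$selection$center),
                          scale = as.numeric(fl$selection$scale),
                          feature_ids = fl$selection$feature_ids),
                     class = "sda_selection")
    list(name = fl$name, selection = sel, model = sae_from_list(fl$model))
  })
  names(first) <- vapply(first, `[[`, character(1), "name")
  structure(list(first_level = first,
                 second_level = sae_from_list(obj$second_level),
                 n_classes = obj$n_classes, classes = obj$classes,
                 stacking_folds = obj$stacking_folds, seed = obj$seed),
            class = "two_level_sae")
}
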