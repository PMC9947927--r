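# Assembly of the five heterogeneous feature sets extracted from each
# separated DNA / protein channel pair:
#   SLFs    840 = 4 DNA-distribution statistics + 836 Haralick values
#   LBP     256
#   CLBP    906
#   RICLBP  408
#   LET     413 (locally encoded transform feature histogram)

feature_set_dims <- c(SLFs = 840L, LBP = 256L, CLBP = 906L, RICLBP = 408L, LET = 413L)

#' DNA distribution statistics
#'
#' Four statistics relating the protein-channel signal to the DNA-channel
#' signal of one separated image:
#' \enumerate{
#'   \item fraction of above-threshold protein pixels that overlap the
#'     above-threshold DNA region (Otsu threshold per channel);
#'   \item ratio of total protein signal inside vs outside the DNA region;
#'   \item distance between the protein and DNA centres of mass, in
#'     image-diagonal units;
#'   \item ratio of total protein to total DNA signal.
#' }
#' Ratio statistics with an empty or zero denominator return 0, never NaN.
#'
#' @param cp a `channel_pair` from [separate_stains()].
#' @return named numeric 4-vector.
#' @export
extract_dna_distribution <- function(cp) {
  if (!inherits(cp, "channel_pair")) stop("`cp` must be a channel_pair")
  dna <- cp$dna; prot <- cp$protein
  if (length(dna) == 0 || !all(dim(dna) == dim(prot)))
    stop("shape error: channels must be non-empty and of equal shape")
  dna_mask <- dna > otsu_threshold(dna)
  prot_mask <- prot > otsu_threshold(prot)
  overlap <- if (sum(prot_mask) > 0) sum(prot_mask & dna_mask) / sum(prot_mask) else 0
  inside <- sum(prot[dna_mask]); outside <- sum(prot[!dna_mask])
  in_out <- if (outside > 0) inside / outside else 0
  com <- function(m) {
    tot <- sum(m)
    if (tot == 0) return(NULL)
    r <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
    c_ <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
    c(sum(r * m), sum(c_ * m)) / tot
  }
  cp_com <- com(prot); cd_com <- com(dna)
  com_dist <- if (is.null(cp_com) || is.null(cd_com)) 0 else
    sqrt(sum((cp_com - cd_com)^2)) / sqrt(sum(dim(dna)^2))
  tot_ratio <- if (sum(dna) > 0) sum(prot) / sum(dna) else 0
  c(dna_overlap_frac = overlap, dna_in_out_ratio = in_out,
    dna_com_distance = com_dist, dna_signal_ratio = tot_ratio)
}

#' Subcellular location features (SLFs)
#'
#' Concatenation of the 4 DNA-distribution statistics and the 836 Haralick
#' co-occurrence statistics of the protein channel; length 840.
#'
#' @param cp a `channel_pair`.
#' @param haralick_cfg a [haralick_config].
#' @return named numeric 840-vector.
#' @export
extract_slfs <- function(cp, haralick_cfg = haralick_config()) {
  c(extract_dna_distribution(cp), extract_haralick(cp$protein, haralick_cfg))
}

#' Extract all five heterogeneous feature sets from one image
#'
#' SLFs use both channels; the four local texture descriptors are computed on
#' the protein channel.
#'
#' @param cp a `channel_pair` from [separate_stains()].
#' @param cfg optional list with elements `haralick`, `clbp`, `riclbp`,
#'   `letrist` overriding the descriptor default configurations.
#' @return named list of five numeric vectors (`SLFs`, `LBP`, `CLBP`,
#'   `RICLBP`, `LET`) with lengths 840, 256, 906, 408, 413.
#' @export
extract_all <- function(cp, cfg = list()) {
  if (!inherits(cp, "channel_pair")) stop("`cp` must be a channel_pair")
  out <- list(
    SLFs = extract_slfs(cp, cfg$haralick %||% haralick_config()),
    LBP = extract_lbp(cp$protein),
    CLBP = extract_clbp(cp$protein, cfg$clbp %||% clbp_config()),
    RICLBP = extract_riclbp(cp$protein, cfg$riclbp %||% riclbp_config()),
    LET = extract_letrist(cp$protein, cfg$letrist %||% letrist_config()))
  for (nm in names(out)) {
    if (any(!is.finite(out[[nm]])))
      stop("non-finite feature value in set ", nm, " for ", cp$source_id)
  }
  out
}

#' Construct a labeled feature set
#'
#' One heterogeneous feature set: an N x d matrix of per-image feature
#' vectors, integer class labels and feature identifiers.
#'
#' @param name set name (e.g. "CLBP").
#' @param matrix numeric N x d matrix.
#' @param labels integer class labels in 1..C, length N.
#' @param feature_ids character vector of length d; defaults to column names.
#' @param source_ids optional per-row image identifiers.
#' @return an object of class `feature_set`.
#' @export
feature_set <- function(name, matrix, labels, feature_ids = colnames(matrix),
                        source_ids = rownames(matrix)) {
  matrix <- as.matrix(matrix)
  labels <- as.integer(labels)
  if (nrow(matrix) != length(labels))
    stop("shape error: row count must equal label count")
  if (is.null(feature_ids)) feature_ids <- sprintf("%s_%d", name, seq_len(ncol(matrix)))
  if (ncol(matrix) != length(feature_ids))
    stop("shape error: column count must equal length(feature_ids)")
  if (any(!is.finite(matrix))) stop("feature matrix contains non-finite values")
  if (is.null(source_ids)) source_ids <- sprintf("sample_%d", seq_len(nrow(matrix)))
  structure(list(name = name, matrix = matrix, labels = labels,
                 feature_ids = feature_ids, source_ids = source_ids),
            class = "feature_set")
}

#' Extract feature sets for a whole image collection
#'
#' Runs stain separation and all five descriptors on each image and stacks
#' the results into five [feature_set] objects sharing sample order and
#' labels.
#'
#' @param images list of [rgb_image] objects.
#' @param labels integer class labels, one per image.
#' @param basis a [stain_basis].
#' @param cfg descriptor configuration overrides, see [extract_all()].
#' @param verbose print progress every 25 images.
#' @return named list of five [feature_set] objects.
#' @export
extract_feature_sets <- function(images, labels, basis = stain_basis(),
                                 cfg = list(), verbose = FALSE) {
  if (length(images) != length(labels)) stop("one label per image required")
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    cp <- separate_stains(images[[i]], basis)
    rows[[i]] <- extract_all(cp, cfg)
    if (verbose && i %% 25 == 0) message("extracted ", i, "/", length(images))
  }
  ids <- vapply(images, function(im) im$source_id, character(1))
  out <- lapply(names(feature_set_dims), function(nm) {
    m <- do.call(rbind, lapply(rows, `[[`, nm))
    rownames(m) <- ids
    feature_set(nm, m, labels)
  })
  stats::setNames(out, names(feature_set_dims))
}

#' Write a feature set to CSV
#'
#' First columns are `source_id` and `label`, then one column per feature id.
#'
#' @param fs a [feature_set].
#' @param path output CSV path.
#' @export
write_feature_csv <- function(fs, path) {
  df <- data.frame(source_id = fs$source_ids, label = fs$labels,
                   fs$matrix, check.names = FALSE)
  colnames(df) <- c("source_id", "label", fs$feature_ids)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature set from CSV written by [write_feature_csv()]
#'
#' @param path CSV path.
#' @param name set name; defaults to the file name without extension.
#' @return a [feature_set].
#' @export
read_feature_csv <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  feature_set(name, m, df$label, feature_ids = colnames(m),
              source_ids = as.character(df$source_id))
}
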