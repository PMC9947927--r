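# Synthetic labeled IHC-like image generator.
#
# Desk-scale stand-in for an IHC image corpus: each image is a two-stain RGB
# rendering (inverse Beer-Lambert with a configurable stain basis) of a DNA
# concentration map (random soft-edged nuclei) plus a class-specific protein
# concentration map. The seven default classes are texture archetypes
# (nuclear-overlapping, diffuse, small spots, large spots, perinuclear rings,
# fine stripes, coarse stripes) chosen to span the micro-pattern families the
# descriptors detect; they make no biological claim beyond sharing the class
# count of a typical subcellular location panel.

default_texture_params <- function() {
  list(
    nuclear    = list(kind = "nuclear"),
    diffuse    = list(kind = "diffuse", blob_sigma = 0.08),
    spots_fine = list(kind = "spots", density = 0.008, radius = 1.2),
    spots_large = list(kind = "spots", density = 0.0005, radius = 6),
    rings      = list(kind = "rings", width = 2.5),
    stripes_fine = list(kind = "stripes", freq = 0.20),
    stripes_coarse = list(kind = "stripes", freq = 0.06))
}

#' Specification of a synthetic IHC-like dataset
#'
#' @param n_classes number of classes (default 7; at most the number of
#'   entries of `texture_params`).
#' @param images_per_class images generated per class.
#' @param image_size c(height, width) in pixels (default 256 x 256).
#' @param texture_params named list of per-class texture parameter lists;
#'   defaults to seven distinct archetypes.
#' @param n_nuclei,nucleus_radius DNA-pattern parameters.
#' @param noise_sd Gaussian pixel noise added after rendering, in 8-bit
#'   intensity units (default 1).
#' @param basis a [stain_basis] used for rendering.
#' @param seed root seed.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 7L, images_per_class = 35L,
                           image_size = c(256L, 256L),
                           texture_params = default_texture_params(),
                           n_nuclei = 6L, nucleus_radius = 0.09,
                           noise_sd = 1, basis = stain_basis(), seed = 1L) {
  if (n_classes < 2 || n_classes > length(texture_params))
    stop("n_classes must be between 2 and length(texture_params)")
  if (images_per_class < 1 || any(image_size < 32))
    stop("counts must be positive and images at least 32 x 32")
  sig <- vapply(texture_params[seq_len(n_classes)],
                function(p) paste(deparse(p), collapse = ""), character(1))
  if (anyDuplicated(sig))
    stop("distinct classes must have distinct texture_params")
  structure(list(n_classes = as.integer(n_classes),
                 images_per_class = as.integer(images_per_class),
                 image_size = as.integer(image_size),
                 texture_params = texture_params[seq_len(n_classes)],
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius = nucleus_radius,
                 noise_sd = noise_sd, basis = basis, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Soft disc: 1 inside, smooth falloff over ~1.5 px at the rim.
soft_disc <- function(h, w, cy, cx, radius) {
  r <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+"))
  pmin(pmax((radius - r) / 1.5 + 1, 0), 1)
}

# DNA concentration map: n soft nuclei discs at random positions.
dna_map <- function(h, w, n_nuclei, radius_frac) {
  rad <- radius_frac * min(h, w)
  m <- matrix(0, h, w)
  for (i in seq_len(n_nuclei)) {
    cy <- runif(1, rad, h - rad); cx <- runif(1, rad, w - rad)
    m <- pmax(m, soft_disc(h, w, cy, cx, rad * runif(1, 0.8, 1.2)))
  }
  m * 0.8
}

# Class-specific protein concentration map. `dna` is the already-drawn DNA
# map of the same image (nuclear / ring classes attach to it).
protein_map <- function(kind_params, h, w, dna) {
  p <- kind_params
  base <- switch(p$kind,
    # nuclear-overlapping with chromatin-like granularity, so the class is
    # micro-textured (not just a smooth disc at nuclear scale)
    nuclear = dna / max(dna, 1e-9) * (0.35 + 0.65 * matrix(runif(h * w), h, w)),
    diffuse = {
      g <- matrix(runif(h * w), h, w)
      k <- gauss_kernel(max(2, p$blob_sigma * min(h, w) / 4))
      sm <- sep_conv_same(g, k)
      (sm - min(sm)) / max(diff(range(sm)), 1e-9)
    },
    spots = {
      m <- matrix(0, h, w)
      if (p$radius > 0 && p$density > 0) {
        n <- max(3, round(p$density * h * w))
        for (i in seq_len(n)) {
          m <- pmax(m, soft_disc(h, w, runif(1, 1, h), runif(1, 1, w),
                                 p$radius * runif(1, 0.8, 1.2)))
        }
      }
      m
    },
    rings = {
      # annuli hugging the nuclei rims
      d <- dna / max(dna, 1e-9)
      inner <- sep_conv_same(d, gauss_kernel(p$width))
      ring <- pmax(inner - d * 0.9, 0)
      ring / max(ring, 1e-9)
    },
    stripes = {
      theta <- runif(1, 0, pi)
      gr <- outer(seq_len(h) * sin(theta), seq_len(w) * cos(theta), "+")
      (sin(2 * pi * p$freq * gr) + 1) / 2
    },
    stop("unknown texture kind: ", p$kind))
  prot <- base * 0.7
  if (max(prot) <= 0)
    stop("degenerate-class error: texture parameters produced an empty protein channel")
  prot
}

# Separable "same"-size convolution with replicated edges.
sep_conv_same <- function(img, k) {
  r <- (length(k) - 1) / 2
  h <- nrow(img); w <- ncol(img)
  pad <- img[c(rep(1, r), seq_len(h), rep(h, r)), c(rep(1, r), seq_len(w), rep(w, r))]
  out <- sep_conv_valid(pad, k, k)
  out
}

#' Generate a synthetic labeled image dataset
#'
#' Draws per-image DNA and class-specific protein concentration maps,
#' renders RGB via the inverse Beer-Lambert map with the spec's stain basis,
#' and adds Gaussian pixel noise. Fully seeded and reproducible; ground
#' truth (class, per-image texture parameters, concentration maps) is
#' retained.
#'
#' @param spec a [synthetic_spec].
#' @param dir optional directory; when given, images are written as PNGs
#'   with a `manifest.tsv` (columns image_path, label).
#' @param keep_truth retain the ground-truth concentration maps in the
#'   result (default TRUE).
#' @return list with `images` (list of [rgb_image]), `labels` (integer),
#'   `manifest` (data.frame with source_id, label, class_name, seed), and
#'   `truth` (per-image list of dna / protein concentration maps).
#' @export
generate_dataset <- function(spec = synthetic_spec(), dir = NULL, keep_truth = TRUE) {
  set.seed(derive_seed(spec$seed, "generate_dataset"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  n_img <- spec$n_classes * spec$images_per_class
  images <- vector("list", n_img)
  truth <- if (keep_truth) vector("list", n_img) else NULL
  labels <- integer(n_img)
  class_names <- names(spec$texture_params)
  i <- 0L
  for (cl in seq_len(spec$n_classes)) {
    for (rep_ in seq_len(spec$images_per_class)) {
      i <- i + 1L
      id <- sprintf("%s_%03d", class_names[cl], rep_)
      dna <- dna_map(h, w, spec$n_nuclei, spec$nucleus_radius)
      prot <- protein_map(spec$texture_params[[cl]], h, w, dna)
      img <- render_stains(dna, prot, spec$basis, quantize = FALSE, source_id = id)
      px <- img$pixels + rnorm(length(img$pixels), 0, spec$noise_sd)
      px <- round(pmin(pmax(px, 0), 255))
      images[[i]] <- rgb_image(px, source_id = id)
      labels[i] <- cl
      if (keep_truth) truth[[i]] <- list(dna = dna, protein = prot)
    }
  }
  manifest <- data.frame(
    source_id = vapply(images, `[[`, character(1), "source_id"),
    label = labels,
    class_name = class_names[labels],
    seed = spec$seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(dir, paste0(manifest$source_id, ".png"))
    for (j in seq_len(n_img))
      png::writePNG(images[[j]]$pixels / 255, paths[j])
    manifest$image_path <- paths
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(images = images, labels = labels, manifest = manifest, truth = truth)
}

#' Generate complementary synthetic feature-set fixtures
#'
#' Two Gaussian feature sets over `n_classes` classes in which each set
#' linearly separates only its own half of the classes (the other classes
#' share a common mean), so neither set alone can resolve all classes but
#' their fused decisions can. Used to exercise the gain of the two-level
#' integrator over any single set.
#'
#' @param n_classes number of classes (default 7).
#' @param n_per_class samples per class.
#' @param dim dimensionality of each set.
#' @param sep class-mean separation in within-class SD units (default 5).
#' @param seed seed.
#' @return list of two [feature_set] objects sharing labels.
#' @export
complementary_feature_sets <- function(n_classes = 7L, n_per_class = 20L,
                                       dim = 10L, sep = 5, seed = 1L) {
  set.seed(derive_seed(seed, "complementary"))
  half <- ceiling(n_classes / 2)
  grp <- list(A = seq_len(half), B = seq(half + 1, n_classes))
  y <- rep(seq_len(n_classes), each = n_per_class)
  N <- length(y)
  ids <- sprintf("s%03d", seq_len(N))
  mk <- function(resolved, name) {
    M <- matrix(rnorm(N * dim), N, dim)
    for (k in seq_along(resolved)) {
      cl <- resolved[k]
      M[y == cl, k] <- M[y == cl, k] + sep
    }
    m <- M
    rownames(m) <- ids
    feature_set(name, m, y)
  }
  list(A = mk(grp$A, "A"), B = mk(grp$B, "B"))
}
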