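# Stain separation of two-stain brightfield IHC images.
#
# IHC images are optical mixtures of a nuclear (hematoxylin-type, "DNA") stain
# and a chromogenic ("protein", DAB-type) stain. Under the Beer-Lambert law the
# optical density at each pixel is linear in the per-stain concentrations, so
# two concentration maps can be recovered per pixel by least squares against
# the two stain absorbance vectors.

#' Construct an RGB image object
#'
#' Wraps an H x W x 3 numeric array of intensities on the 0-255 scale and
#' validates it.
#'
#' @param pixels numeric H x W x 3 array, values in \[0, 255\].
#' @param source_id optional identifier carried through to derived objects.
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, source_id = "image") {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop("shape error: `pixels` must be an H x W x 3 array")
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 255))
    stop("rgb_image: intensities must be finite and within [0, 255]")
  structure(list(pixels = pixels,
                 height = dim(pixels)[1], width = dim(pixels)[2],
                 source_id = source_id),
            class = "rgb_image")
}

#' Stain absorbance basis for linear spectral separation
#'
#' Holds the unit-length optical-density absorbance vectors of the DNA
#' (hematoxylin-type) and protein (DAB-type) stains, plus the background
#' (unstained) intensity I0. Defaults are the canonical hematoxylin / DAB
#' vectors used for IHC colour deconvolution.
#'
#' @param dna_vector,protein_vector non-negative, non-zero length-3 absorbance
#'   vectors; normalized internally to unit Euclidean length.
#' @param background background intensity I0 (> 0), default 255.
#' @return an object of class `stain_basis`.
#' @export
stain_basis <- function(dna_vector = c(0.650, 0.704, 0.286),
                        protein_vector = c(0.269, 0.568, 0.778),
                        background = 255) {
  chk <- function(v, nm) {
    if (length(v) != 3 || any(!is.finite(v)) || any(v < 0) || sum(v) == 0)
      stop(sprintf("stain_basis: `%s` must be a non-negative, non-zero 3-vector", nm))
    v / sqrt(sum(v^2))
  }
  dna_vector <- chk(dna_vector, "dna_vector")
  protein_vector <- chk(protein_vector, "protein_vector")
  if (background <= 0) stop("stain_basis: `background` must be > 0")
  # linear independence: cross product must be non-negligible
  cr <- c(dna_vector[2] * protein_vector[3] - dna_vector[3] * protein_vector[2],
          dna_vector[3] * protein_vector[1] - dna_vector[1] * protein_vector[3],
          dna_vector[1] * protein_vector[2] - dna_vector[2] * protein_vector[1])
  if (sqrt(sum(cr^2)) < 1e-8)
    stop("degenerate-basis error: stain vectors are collinear")
  structure(list(dna_vector = dna_vector, protein_vector = protein_vector,
                 background = background),
            class = "stain_basis")
}

#' Beer-Lambert optical density transform
#'
#' Converts intensities to optical densities, `OD_c = -log((p_c + 1) /
#' (I0 + 1))` per channel, clipped below at zero. The +1 offset avoids
#' `log(0)` at fully absorbed pixels.
#'
#' @param img an [rgb_image].
#' @param background_intensity background intensity I0 (> 0).
#' @return an H x W x 3 non-negative array of optical densities.
#' @export
optical_density <- function(img, background_intensity = 255) {
  if (!inherits(img, "rgb_image")) stop("shape error: `img` must be an rgb_image")
  if (background_intensity <= 0) stop("`background_intensity` must be > 0")
  od <- -log((img$pixels + 1) / (background_intensity + 1))
  od[od < 0] <- 0
  od
}

#' Separate an RGB IHC image into DNA and protein density channels
#'
#' Linear spectral separation: each pixel's optical-density vector is solved
#' in least squares against the 3 x 2 matrix of stain absorbance vectors;
#' negative concentrations are clipped to zero (concentrations are physical).
#'
#' @param img an [rgb_image].
#' @param basis a [stain_basis]; defaults to hematoxylin / DAB.
#' @return an object of class `channel_pair` with matrices `dna` and
#'   `protein` (H x W, non-negative stain-density maps) and `source_id`.
#' @export
separate_stains <- function(img, basis = stain_basis()) {
  if (!inherits(img, "rgb_image")) stop("shape error: `img` must be an rgb_image")
  if (!inherits(basis, "stain_basis")) stop("`basis` must be a stain_basis")
  od <- optical_density(img, basis$background)
  h <- dim(od)[1]; w <- dim(od)[2]
  A <- cbind(basis$dna_vector, basis$protein_vector)   # 3 x 2
  # normal-equations pseudo-inverse; basis guaranteed full rank by constructor
  P <- solve(crossprod(A), t(A))                       # 2 x 3
  odm <- matrix(od, nrow = h * w, ncol = 3)            # pixels x 3
  conc <- odm %*% t(P)                                 # pixels x 2
  conc[conc < 0] <- 0
  structure(list(dna = matrix(conc[, 1], h, w),
                 protein = matrix(conc[, 2], h, w),
                 source_id = img$source_id),
            class = "channel_pair")
}

#' Render an RGB image from stain concentration maps
#'
#' Inverse of the Beer-Lambert separation: `pixel_c = (I0 + 1) *
#' exp(-OD_c) - 1` with `OD = a * v_dna + b * v_protein`. Used by the
#' synthetic image generator and for round-trip checks.
#'
#' @param dna,protein non-negative concentration matrices of equal shape.
#' @param basis a [stain_basis].
#' @param quantize round to integer 8-bit intensities (default TRUE).
#' @param source_id identifier for the resulting image.
#' @return an [rgb_image].
#' @export
render_stains <- function(dna, protein, basis = stain_basis(),
                          quantize = TRUE, source_id = "render") {
  if (!all(dim(dna) == dim(protein))) stop("shape error: channel shapes differ")
  if (any(dna < 0) || any(protein < 0)) stop("concentrations must be >= 0")
  h <- nrow(dna); w <- ncol(dna)
  od <- cbind(as.numeric(dna), as.numeric(protein)) %*%
    t(cbind(basis$dna_vector, basis$protein_vector))  # pixels x 3
  px <- (basis$background + 1) * exp(-od) - 1
  px <- pmin(pmax(px, 0), 255)
  if (quantize) px <- round(px)
  rgb_image(array(px, dim = c(h, w, 3)), source_id = source_id)
}

#' Read an RGB image from PNG or TIFF
#'
#' 8-bit and 16-bit RGB are accepted; intensities are rescaled to the
#' \[0, 255\] scale expected by [separate_stains()]. An alpha channel, if
#' present, is dropped.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return an [rgb_image] with `source_id` set to the file name.
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("path error: unsupported image extension: ", ext))
  if (length(dim(px)) == 2) stop("shape error: grayscale image; RGB required")
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] != 3) stop("shape error: expected 3 colour channels")
  # readPNG/readTIFF return [0,1] doubles regardless of bit depth
  rgb_image(px * 255, source_id = basename(path))
}

#' Write the two separated channels as grayscale PNGs for inspection
#'
#' Each channel is min-max scaled to \[0, 1\] for display.
#'
#' @param cp a `channel_pair`.
#' @param dir output directory (created if missing).
#' @return invisibly, the two file paths written.
#' @export
write_channel_pngs <- function(cp, dir) {
  if (!inherits(cp, "channel_pair")) stop("`cp` must be a channel_pair")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  norm01 <- function(m) if (diff(range(m)) == 0) m * 0 else (m - min(m)) / diff(range(m))
  paths <- file.path(dir, paste0(cp$source_id, c("_dna.png", "_protein.png")))
  png::writePNG(norm01(cp$dna), paths[1])
  png::writePNG(norm01(cp$protein), paths[2])
  invisible(paths)
}
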