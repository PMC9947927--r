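# Locally encoded transform feature histogram.
#
# A multiscale transform descriptor: at each Gaussian scale the image is
# filtered with first-derivative-of-Gaussian kernels in x and y, the gradient
# magnitude is passed through the bounded transform u = m / (m + c) and
# quantized into 7 levels. Codes are histogrammed jointly across the three
# scales (7^3 = 343), jointly for the finest/coarsest pair (7^2 = 49), and
# marginally per scale (3 x 7 = 21), totalling 413.

#' Default configuration for the locally encoded transform histogram
#'
#' @param sigmas Gaussian scales (default 1, 2, 4).
#' @param n_levels quantization levels per transform (default 7).
#' @param c_sat saturation constant of the bounded transform m/(m+c), in
#'   8-bit intensity units (default 16).
#' @return a list of class `letrist_config`.
#' @export
letrist_config <- function(sigmas = c(1, 2, 4), n_levels = 7L, c_sat = 16) {
  if (length(sigmas) != 3) stop("exactly three scales are required")
  structure(list(sigmas = sigmas, n_levels = as.integer(n_levels), c_sat = c_sat),
            class = "letrist_config")
}

# 1-D Gaussian and Gaussian-derivative kernels, half-width 3*sigma.
gauss_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# Derivative-of-Gaussian kernel, normalized so that the correlation response
# to a unit-slope ramp equals 1.
dgauss_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2))
  d <- x * g
  d / sum(x * d)
}

# Separable valid-region convolution: filter rows with `kr`, columns with
# `kc`. Returns the valid interior (margin = half kernel width each side).
sep_conv_valid <- function(img, kr, kc) {
  rr <- (length(kr) - 1L) / 2L
  rc <- (length(kc) - 1L) / 2L
  h <- nrow(img); w <- ncol(img)
  if (h < 2 * rr + 1 || w < 2 * rc + 1)
    stop("size error: image too small for scale")
  # convolve along rows (vertical): for output row i, sum_k kr[k] * img[i+k-rr-1, ]
  out1 <- matrix(0, h - 2 * rr, w)
  for (k in seq_along(kr))
    out1 <- out1 + kr[k] * img[(k):(h - 2 * rr - 1 + k), , drop = FALSE]
  out2 <- matrix(0, h - 2 * rr, w - 2 * rc)
  for (k in seq_along(kc))
    out2 <- out2 + kc[k] * out1[, (k):(w - 2 * rc - 1 + k), drop = FALSE]
  out2
}

# Quantized transform codes at one scale, computed on the common interior of
# all scales (margin = ceiling(3 * max sigma)).
letrist_codes <- function(img, sigma, margin, cfg) {
  g <- gauss_kernel(sigma)
  d <- dgauss_kernel(sigma)
  # sep_conv_valid correlates (no kernel flip), so these are the directional
  # derivative responses along columns (gx) and rows (gy)
  gx <- sep_conv_valid(img, g, d)
  gy <- sep_conv_valid(img, d, g)
  r <- ceiling(3 * sigma)
  # crop to the common margin
  keep_r <- (margin - r + 1):(nrow(gx) - (margin - r))
  keep_c <- (margin - r + 1):(ncol(gx) - (margin - r))
  gx <- gx[keep_r, keep_c, drop = FALSE]
  gy <- gy[keep_r, keep_c, drop = FALSE]
  m <- sqrt(gx^2 + gy^2)
  u <- m / (m + cfg$c_sat)
  code <- floor(u * cfg$n_levels)
  code[code >= cfg$n_levels] <- cfg$n_levels - 1L
  matrix(as.integer(code), nrow(gx), ncol(gx))
}

#' Locally encoded transform feature histogram
#'
#' Multiscale quantized Gaussian-derivative transform codes jointly and
#' marginally histogrammed across scales; 413 values under the default
#' configuration, each constituent histogram L1-normalized.
#'
#' @param img numeric grayscale matrix.
#' @param cfg a [letrist_config].
#' @return named numeric vector (length 413 by default).
#' @export
extract_letrist <- function(img, cfg = letrist_config()) {
  img <- rescale_8bit(img)
  margin <- ceiling(3 * max(cfg$sigmas))
  if (nrow(img) < 2 * margin + 2 || ncol(img) < 2 * margin + 2)
    stop("size error: image too small for the largest configured scale")
  L <- cfg$n_levels
  codes <- lapply(cfg$sigmas, function(s) letrist_codes(img, s, margin, cfg))
  c1 <- as.integer(codes[[1]]); c2 <- as.integer(codes[[2]]); c3 <- as.integer(codes[[3]])
  joint3 <- tabulate(c1 + L * c2 + L * L * c3 + 1L, L^3)
  joint3 <- joint3 / sum(joint3)
  names(joint3) <- sprintf("let_joint3_%03d", seq_len(L^3) - 1L)
  joint2 <- tabulate(c1 + L * c3 + 1L, L^2)
  joint2 <- joint2 / sum(joint2)
  names(joint2) <- sprintf("let_joint13_%02d", seq_len(L^2) - 1L)
  marg <- unlist(lapply(seq_along(codes), function(i) {
    h <- tabulate(as.integer(codes[[i]]) + 1L, L)
    stats::setNames(h / sum(h), sprintf("let_s%d_%d", i, seq_len(L) - 1L))
  }))
  c(joint3, joint2, marg)
}
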