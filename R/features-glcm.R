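# Gray-level co-occurrence (Haralick-type) texture statistics.
#
# The 836-dimensional texture block is 19 co-occurrence statistics (Haralick's
# 13 plus autocorrelation, dissimilarity, cluster shade, cluster prominence,
# maximum probability and inverse difference) computed from symmetric,
# normalized GLCMs at 4 directions (0, 45, 90, 135 degrees) and pixel
# distances 1..11 with 32 gray levels: 19 * 4 * 11 = 836.

haralick_stat_names <- c(
  "asm", "contrast", "correlation", "variance", "idm",
  "sum_average", "sum_variance", "sum_entropy", "entropy",
  "diff_variance", "diff_entropy", "imc1", "imc2",
  "autocorrelation", "dissimilarity", "cluster_shade",
  "cluster_prominence", "max_prob", "inverse_difference")

#' Default Haralick configuration
#'
#' @param n_gray number of gray levels for quantization (default 32).
#' @param distances integer pixel distances (default 1:11).
#' @param angles offset directions in degrees, subset of c(0,45,90,135).
#' @param stats statistic names; see `subloc2l:::haralick_stat_names`.
#' @return a list of class `haralick_config`.
#' @export
haralick_config <- function(n_gray = 32L, distances = 1:11,
                            angles = c(0, 45, 90, 135),
                            stats = haralick_stat_names) {
  if (n_gray < 2) stop("n_gray must be >= 2")
  if (!all(angles %in% c(0, 45, 90, 135))) stop("angles must be in {0,45,90,135}")
  if (!all(stats %in% haralick_stat_names)) stop("unknown statistic name")
  structure(list(n_gray = as.integer(n_gray), distances = as.integer(distances),
                 angles = angles, stats = stats),
            class = "haralick_config")
}

# Quantize a grayscale matrix to integer levels 1..n by min-max scaling.
# Constant images map to level 1 everywhere.
quantize_gray <- function(img, n) {
  rng <- range(img)
  if (diff(rng) == 0) return(matrix(1L, nrow(img), ncol(img)))
  q <- floor((img - rng[1]) / diff(rng) * n) + 1L
  q[q > n] <- n
  matrix(as.integer(q), nrow(img), ncol(img))
}

# Offset (drow, dcol) for an angle in degrees at distance d, in matrix
# (row-down) coordinates: 0 deg = east, 45 = north-east, 90 = north,
# 135 = north-west.
angle_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("unsupported angle"))
}

#' Gray-level co-occurrence matrix
#'
#' Symmetric, normalized GLCM of a quantized image for one (distance, angle)
#' offset.
#'
#' @param q integer matrix of gray levels in 1..n_gray.
#' @param n_gray number of levels.
#' @param distance integer pixel distance.
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @return an n_gray x n_gray matrix summing to 1 (all zeros if the offset
#'   exceeds the image extent).
#' @export
glcm <- function(q, n_gray, distance, angle) {
  off <- angle_offset(angle, distance)
  h <- nrow(q); w <- ncol(q)
  r0 <- max(1L, 1L - off[1]); r1 <- min(h, h - off[1])
  c0 <- max(1L, 1L - off[2]); c1 <- min(w, w - off[2])
  P <- matrix(0, n_gray, n_gray)
  if (r0 > r1 || c0 > c1) return(P)
  a <- q[r0:r1, c0:c1, drop = FALSE]
  b <- q[(r0 + off[1]):(r1 + off[1]), (c0 + off[2]):(c1 + off[2]), drop = FALSE]
  counts <- tabulate((as.integer(a) - 1L) * n_gray + as.integer(b), n_gray * n_gray)
  P <- matrix(counts, n_gray, n_gray, byrow = TRUE)
  P <- P + t(P)
  P / sum(P)
}

# All 19 statistics of one normalized symmetric GLCM. 0/0 forms take their
# defined limits (correlation, imc1 -> 0) so a constant image never yields NaN.
glcm_stats <- function(P, stats = haralick_stat_names) {
  n <- nrow(P)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  px <- rowSums(P)
  mu_x <- sum(seq_len(n) * px)
  sd_x <- sqrt(sum((seq_len(n) - mu_x)^2 * px))
  # symmetric GLCM: marginals equal
  psum <- sapply(2:(2 * n), function(k) sum(P[i + j == k]))      # p_{x+y}
  pdif <- sapply(0:(n - 1), function(k) sum(P[abs(i - j) == k])) # p_{x-y}
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  HXY <- ent(P)
  Q1 <- outer(px, px)
  HXY1 <- { m <- P * log2(Q1); m[Q1 == 0 | P == 0] <- 0; -sum(m) }
  HXY2 <- { m <- Q1 * log2(Q1); m[Q1 == 0] <- 0; -sum(m) }
  HX <- ent(px)
  sa <- sum((2:(2 * n)) * psum)
  out <- c(
    asm = sum(P^2),
    contrast = sum((i - j)^2 * P),
    correlation = if (sd_x > 0) (sum(i * j * P) - mu_x^2) / sd_x^2 else 0,
    variance = sum((i - mu_x)^2 * P),
    idm = sum(P / (1 + (i - j)^2)),
    sum_average = sa,
    sum_variance = sum(((2:(2 * n)) - sa)^2 * psum),
    sum_entropy = ent(psum),
    entropy = HXY,
    diff_variance = sum((0:(n - 1))^2 * pdif) - sum((0:(n - 1)) * pdif)^2,
    diff_entropy = ent(pdif),
    imc1 = if (max(HX, HX) > 0) (HXY - HXY1) / HX else 0,
    imc2 = sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY)))),
    autocorrelation = sum(i * j * P),
    dissimilarity = sum(abs(i - j) * P),
    cluster_shade = sum((i + j - 2 * mu_x)^3 * P),
    cluster_prominence = sum((i + j - 2 * mu_x)^4 * P),
    max_prob = max(P),
    inverse_difference = sum(P / (1 + abs(i - j))))
  out[stats]
}

#' Haralick co-occurrence texture features
#'
#' Concatenated GLCM statistics over all configured distances and directions;
#' 836 values under the default configuration.
#'
#' @param img numeric grayscale matrix (at least 2 x 2).
#' @param cfg a [haralick_config].
#' @return named numeric vector of length
#'   `length(stats) * length(angles) * length(distances)`.
#' @export
extract_haralick <- function(img, cfg = haralick_config()) {
  if (!is.matrix(img) || nrow(img) < 2 || ncol(img) < 2)
    stop("size error: image must be at least 2 x 2")
  q <- quantize_gray(img, cfg$n_gray)
  out <- numeric(0)
  for (d in cfg$distances) {
    for (a in cfg$angles) {
      P <- glcm(q, cfg$n_gray, d, a)
      if (sum(P) == 0) {     # offset exceeds extent: degenerate, defined limits
        s <- stats::setNames(numeric(length(cfg$stats)), cfg$stats)
        s["asm"] <- 1; s["max_prob"] <- 1
        s <- s[cfg$stats]
      } else {
        s <- glcm_stats(P, cfg$stats)
      }
      names(s) <- sprintf("har_d%d_a%d_%s", d, a, cfg$stats)
      out <- c(out, s)
    }
  }
  out
}
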