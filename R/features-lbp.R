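# Local binary pattern family descriptors: raw LBP (256 codes), completed LBP
# (sign / magnitude / center decomposition, 906 values), and rotation-invariant
# co-occurrence among adjacent local binary patterns (3 scales x 136 pair
# classes = 408 values).
#
# Conventions shared by all three: the image is first min-max rescaled to
# 8-bit [0, 255] (constant images map to all zeros); neighbor comparisons use
# >=; codes are computed on interior pixels only (no padding); bit 0 sits at
# the east neighbor and bits proceed counter-clockwise.

# Rescale a grayscale matrix to [0, 255]; constant -> all zeros.
rescale_8bit <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) return(img * 0)
  (img - rng[1]) / diff(rng) * 255
}

# Neighbor offsets (drow, dcol) for P points at radius R, counter-clockwise
# from east. Row axis points down, so "counter-clockwise" on screen means
# decreasing row for the first quadrant.
circle_offsets <- function(P, R) {
  k <- 0:(P - 1)
  ang <- 2 * pi * k / P
  cbind(drow = -R * sin(ang), dcol = R * cos(ang))
}

# Sample neighbor values for every interior pixel. Returns a list with the
# center matrix (interior crop) and an n_interior x P matrix of neighbor
# values, bilinearly interpolated where offsets are non-integer.
sample_neighbors <- function(img, P, R) {
  h <- nrow(img); w <- ncol(img)
  m <- ceiling(R)
  if (h < 2 * m + 1 || w < 2 * m + 1)
    stop("size error: image too small for radius ", R)
  rows <- (m + 1):(h - m); cols <- (m + 1):(w - m)
  ctr <- img[rows, cols, drop = FALSE]
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  offs <- circle_offsets(P, R)
  nb <- matrix(0, length(ctr), P)
  for (p in seq_len(P)) {
    yr <- rr + offs[p, 1]; xc <- cc + offs[p, 2]
    y0 <- floor(yr); x0 <- floor(xc)
    fy <- yr - y0; fx <- xc - x0
    # snap near-integer coordinates to avoid spurious interpolation
    snap <- 1e-9
    fy[abs(fy) < snap] <- 0; fx[abs(fx) < snap] <- 0
    fy[abs(fy - 1) < snap] <- 0; fx[abs(fx - 1) < snap] <- 0
    y0[yr - floor(yr) > 1 - snap] <- y0[yr - floor(yr) > 1 - snap] + 1L
    x0[xc - floor(xc) > 1 - snap] <- x0[xc - floor(xc) > 1 - snap] + 1L
    y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
    v <- (1 - fy) * (1 - fx) * img[cbind(c(y0), c(x0))] +
         (1 - fy) * fx       * img[cbind(c(y0), c(x1))] +
         fy       * (1 - fx) * img[cbind(c(y1), c(x0))] +
         fy       * fx       * img[cbind(c(y1), c(x1))]
    nb[, p] <- v
  }
  list(center = as.numeric(ctr), neighbors = nb,
       shape = c(length(rows), length(cols)))
}

# Pack a logical n x P matrix of bits into integer codes (bit 0 = column 1).
pack_bits <- function(bits) {
  as.integer(bits %*% 2^(0:(ncol(bits) - 1)))
}

#' Local binary pattern histogram (raw 256 codes)
#'
#' 8-neighbor LBP at radius 1 over interior pixels; histogram over all 256
#' codes, L1-normalized.
#'
#' @param img numeric grayscale matrix, at least 3 x 3.
#' @return named numeric 256-vector summing to 1.
#' @export
extract_lbp <- function(img) {
  if (!is.matrix(img) || nrow(img) < 3 || ncol(img) < 3)
    stop("size error: image must be at least 3 x 3 for LBP")
  codes <- lbp_codes(rescale_8bit(img))
  h <- tabulate(codes + 1L, 256L)
  stats::setNames(h / sum(h), sprintf("lbp_%03d", 0:255))
}

# Per-pixel 8-neighbor radius-1 LBP codes (vectorized); exported shape for
# oracle tests via the returned matrix.
lbp_codes <- function(img) {
  s <- sample_neighbors(img, 8L, 1)
  pack_bits(s$neighbors >= s$center)
}

# -- Completed LBP ------------------------------------------------------------

# riu2 mapping for P bits: uniform codes (<= 2 transitions) map to their
# number of ones (0..P), the rest to P+1. Returned as a lookup over 0:(2^P-1).
# Memoized: the P = 16 table has 65536 entries.
.lbp_cache <- new.env(parent = emptyenv())

riu2_table <- function(P) {
  key <- paste0("riu2_", P)
  if (!is.null(.lbp_cache[[key]])) return(.lbp_cache[[key]])
  codes <- 0:(2^P - 1)
  bits <- vapply(0:(P - 1),
                 function(s) bitwAnd(bitwShiftR(codes, s), 1L),
                 integer(length(codes)))
  trans <- rowSums(bits != bits[, c(2:P, 1), drop = FALSE])
  ones <- rowSums(bits)
  tab <- as.integer(ifelse(trans <= 2, ones, P + 1L))
  .lbp_cache[[key]] <- tab
  tab
}

#' Default completed-LBP configuration
#'
#' Two scales; per scale a joint sign/magnitude/center histogram
#' ((P+2) x (P+2) x 2) plus marginal sign and magnitude riu2 histograms; one
#' global 2-bin center histogram (the center operator does not depend on
#' scale). Totals 906 under the defaults.
#'
#' @param scales list of c(P, R) pairs.
#' @return a list of class `clbp_config`.
#' @export
clbp_config <- function(scales = list(c(8, 1), c(16, 3))) {
  structure(list(scales = scales), class = "clbp_config")
}

# Per-scale CLBP operators: riu2-mapped sign and magnitude codes per interior
# pixel, plus the center bit (center >= global image mean).
clbp_codes <- function(img, P, R, m_threshold = NULL) {
  s <- sample_neighbors(img, P, R)
  d <- s$neighbors - s$center
  sign_code <- pack_bits(d >= 0)
  mag <- abs(d)
  if (is.null(m_threshold)) m_threshold <- mean(mag)
  mag_code <- pack_bits(mag >= m_threshold)
  map <- riu2_table(P)
  list(sign = map[sign_code + 1L], mag = map[mag_code + 1L],
       center = as.integer(s$center >= mean(img)),
       m_threshold = m_threshold)
}

#' Completed local binary pattern descriptor
#'
#' Sign/magnitude/center decomposition with riu2 mapping; see [clbp_config()]
#' for the histogram layout. 906 values under the default configuration; each
#' constituent histogram is L1-normalized.
#'
#' @param img numeric grayscale matrix.
#' @param cfg a [clbp_config].
#' @return named numeric vector (length 906 by default).
#' @export
extract_clbp <- function(img, cfg = clbp_config()) {
  img <- rescale_8bit(img)
  out <- numeric(0)
  center_hist <- NULL
  for (sc in cfg$scales) {
    P <- sc[1]; R <- sc[2]
    cc <- clbp_codes(img, P, R)
    nb <- P + 2L
    joint <- tabulate(cc$sign + nb * cc$mag + nb * nb * cc$center + 1L,
                      nb * nb * 2L)
    joint <- joint / sum(joint)
    s_h <- tabulate(cc$sign + 1L, nb); s_h <- s_h / sum(s_h)
    m_h <- tabulate(cc$mag + 1L, nb); m_h <- m_h / sum(m_h)
    names(joint) <- sprintf("clbp_p%d_joint_%03d", P, seq_along(joint) - 1L)
    names(s_h) <- sprintf("clbp_p%d_s_%02d", P, seq_len(nb) - 1L)
    names(m_h) <- sprintf("clbp_p%d_m_%02d", P, seq_len(nb) - 1L)
    out <- c(out, joint, s_h, m_h)
    if (is.null(center_hist)) {
      ch <- tabulate(cc$center + 1L, 2L)
      center_hist <- stats::setNames(ch / sum(ch), c("clbp_c_0", "clbp_c_1"))
    }
  }
  c(out, center_hist)
}

# -- RICLBP -------------------------------------------------------------------

# 4-neighbor LBP codes (E, N, W, S at integer radius r), 16 patterns.
lbp4_codes <- function(img, r) {
  h <- nrow(img); w <- ncol(img)
  if (h < 2 * r + 1 || w < 2 * r + 1)
    stop("size error: image too small for radius ", r)
  rows <- (r + 1):(h - r); cols <- (r + 1):(w - r)
  ctr <- img[rows, cols, drop = FALSE]
  bits <- cbind(
    as.numeric(img[rows, cols + r, drop = FALSE] >= ctr),   # E
    as.numeric(img[rows - r, cols, drop = FALSE] >= ctr),   # N
    as.numeric(img[rows, cols - r, drop = FALSE] >= ctr),   # W
    as.numeric(img[rows + r, cols, drop = FALSE] >= ctr))   # S
  matrix(pack_bits(bits == 1), length(rows), length(cols))
}

# Rotate a 4-bit code by k * 90 degrees counter-clockwise (cyclic bit shift).
rot4 <- function(code, k) {
  k <- k %% 4
  if (k == 0) return(code)
  bitwAnd(bitwOr(bitwShiftL(code, k), bitwShiftR(code, 4 - k)), 15L)
}

# Lookup from 256 ordered (a, b) pair codes to the 136 rotation-invariant
# classes: pairs already direction-normalized are further identified with
# (rot180(b), rot180(a)) (the same pair read from the other end).
riclbp_pair_table <- function() {
  if (!is.null(.lbp_cache$riclbp_pairs)) return(.lbp_cache$riclbp_pairs)
  a <- rep(0:15, each = 16); b <- rep(0:15, times = 16)
  key1 <- a * 16L + b
  key2 <- rot4(b, 2) * 16L + rot4(a, 2)
  canon <- pmin(key1, key2)
  cls <- match(canon, sort(unique(canon)))
  tab <- list(class_of = cls, n_class = length(unique(cls)))
  .lbp_cache$riclbp_pairs <- tab
  tab
}

#' Default RICLBP configuration
#'
#' Three (radius, displacement) scales; each contributes a 136-bin histogram
#' of rotation-invariant adjacent-LBP pair classes: 3 x 136 = 408.
#'
#' @param scales list of c(lbp_radius, pair_displacement) pairs.
#' @return a list of class `riclbp_config`.
#' @export
riclbp_config <- function(scales = list(c(1, 2), c(2, 4), c(4, 8))) {
  structure(list(scales = scales), class = "riclbp_config")
}

#' Rotation-invariant co-occurrence of adjacent LBP descriptor
#'
#' 4-neighbor LBP codes are paired at a fixed displacement along the four
#' axis directions; each pair is rotation-normalized (both codes cyclically
#' shifted so the displacement points east, then identified with its
#' 180-degree reading) giving 136 pattern-pair classes per scale. Histograms
#' are L1-normalized per scale.
#'
#' @param img numeric grayscale matrix.
#' @param cfg a [riclbp_config].
#' @return named numeric vector (length 408 by default).
#' @export
extract_riclbp <- function(img, cfg = riclbp_config()) {
  img <- rescale_8bit(img)
  tab <- riclbp_pair_table()
  out <- numeric(0)
  for (sc in cfg$scales) {
    r <- sc[1]; d <- sc[2]
    codes <- lbp4_codes(img, r)
    h <- nrow(codes); w <- ncol(codes)
    if (h <= d || w <= d)
      stop("size error: displacement ", d, " exceeds code-map extent")
    counts <- numeric(tab$n_class)
    dirs <- list(c(0L, d), c(-d, 0L), c(0L, -d), c(d, 0L))  # E N W S
    for (k in 0:3) {
      off <- dirs[[k + 1]]
      r0 <- max(1L, 1L - off[1]); r1 <- min(h, h - off[1])
      c0 <- max(1L, 1L - off[2]); c1 <- min(w, w - off[2])
      A <- codes[r0:r1, c0:c1, drop = FALSE]
      B <- codes[(r0 + off[1]):(r1 + off[1]), (c0 + off[2]):(c1 + off[2]), drop = FALSE]
      a <- rot4(as.integer(A), -k); b <- rot4(as.integer(B), -k)
      counts <- counts + tabulate(tab$class_of[a * 16L + b + 1L], tab$n_class)
    }
    counts <- counts / sum(counts)
    names(counts) <- sprintf("riclbp_r%d_d%d_%03d", r, d, seq_along(counts) - 1L)
    out <- c(out, counts)
  }
  out
}
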