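test_that("constant image puts all LBP mass in the all-ones code", {
  h <- extract_lbp(matrix(7, 6, 6))
  expect_equal(unname(h[256]), 1)   # code 255
  expect_equal(sum(h), 1)
})

test_that("LBP histogram is a 256-bin probability vector", {
  set.seed(11)
  img <- matrix(runif(25, 0, 255), 5, 5)
  h <- extract_lbp(img)
  expect_length(h, 256)
  expect_true(all(h >= 0))
  expect_equal(sum(h), 1)
  expect_error(extract_lbp(matrix(0, 2, 3)), "size error")
})

test_that("vectorized LBP codes equal the nested-loop oracle", {
  set.seed(12)
  for (i in 1:10) {
    img <- matrix(sample(0:255, 36, replace = TRUE), 6, 6)
    img8 <- subloc2l:::rescale_8bit(img)
    codes <- matrix(subloc2l:::lbp_codes(img8), 4, 4)
    expect_identical(codes, oracle_lbp_codes(img8))
  }
})

test_that("CLBP default configuration yields 906 L1-normalized values", {
  set.seed(13)
  img <- matrix(runif(40 * 40, 0, 255), 40, 40)
  v <- extract_clbp(img)
  expect_length(v, 906)
  expect_true(all(v >= 0))
  # constituent histograms: 2 joints, 4 marginals, 1 center histogram
  expect_equal(unname(sum(v[grep("^clbp_p8_joint", names(v))])), 1)
  expect_equal(unname(sum(v[grep("^clbp_p16_joint", names(v))])), 1)
  expect_equal(unname(sum(v[grep("^clbp_p8_s_", names(v))])), 1)
  expect_equal(unname(sum(v[grep("^clbp_p16_m_", names(v))])), 1)
  expect_equal(unname(sum(v[grep("^clbp_c_", names(v))])), 1)
})

test_that("constant image: CLBP sign is all-ones, magnitudes all zero", {
  cc <- subloc2l:::clbp_codes(matrix(4, 9, 9), 8, 1)
  riu <- subloc2l:::riu2_table(8)
  expect_true(all(cc$sign == riu[255 + 1]))   # all-ones pattern -> 8 ones
  expect_equal(cc$sign[1], 8)
  expect_equal(cc$m_threshold, 0)
})

test_that("CLBP sign/magnitude patterns match the brute-force oracle on a 7x7 image", {
  set.seed(14)
  for (i in 1:5) {
    img <- matrix(sample(0:255, 49, replace = TRUE), 7, 7)
    img8 <- subloc2l:::rescale_8bit(img)
    s <- subloc2l:::sample_neighbors(img8, 8, 1)
    thr <- mean(abs(s$neighbors - s$center))
    cc <- subloc2l:::clbp_codes(img8, 8, 1)
    o <- oracle_clbp_patterns(img8, thr)
    riu <- subloc2l:::riu2_table(8)
    expect_identical(matrix(cc$sign, 5, 5), matrix(riu[o$sign + 1L], 5, 5))
    expect_identical(matrix(cc$mag, 5, 5), matrix(riu[o$mag + 1L], 5, 5))
  }
})

test_that("RICLBP has 136 rotation-invariant pair classes and length 408", {
  tab <- subloc2l:::riclbp_pair_table()
  expect_equal(tab$n_class, 136)
  set.seed(15)
  img <- matrix(runif(48 * 48, 0, 255), 48, 48)
  v <- extract_riclbp(img)
  expect_length(v, 408)
  for (sc in c("r1_d2", "r2_d4", "r4_d8"))
    expect_equal(unname(sum(v[grep(sc, names(v))])), 1)
})

test_that("constant image concentrates RICLBP mass in one bin per scale", {
  v <- extract_riclbp(matrix(3, 40, 40))
  for (sc in c("r1_d2", "r2_d4", "r4_d8")) {
    h <- v[grep(sc, names(v))]
    expect_equal(unname(max(h)), 1)
    expect_equal(unname(sum(h > 0)), 1)
  }
})

test_that("RICLBP pair counts match an explicit pair enumeration at one scale", {
  set.seed(16)
  img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  img8 <- subloc2l:::rescale_8bit(img)
  v <- extract_riclbp(img8, riclbp_config(scales = list(c(1, 2))))
  # oracle: enumerate all pixel pairs at displacement 2 in 4 axis directions,
  # rotation-normalize the 4-bit codes and count canonical classes
  codes <- subloc2l:::lbp4_codes(img8, 1)
  tab <- subloc2l:::riclbp_pair_table()
  counts <- numeric(tab$n_class)
  rot <- function(code, k) subloc2l:::rot4(code, k)
  h <- nrow(codes); w <- ncol(codes)
  dirs <- list(c(0, 2), c(-2, 0), c(0, -2), c(2, 0))
  for (k in 0:3) {
    off <- dirs[[k + 1]]
    for (r in seq_len(h)) for (c in seq_len(w)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
        a <- rot(codes[r, c], -k); b <- rot(codes[r2, c2], -k)
        cls <- tab$class_of[a * 16 + b + 1]
        counts[cls] <- counts[cls] + 1
      }
    }
  }
  expect_equal(unname(v), counts / sum(counts), tolerance = 1e-12)
})

test_that("RICLBP is invariant to 90-degree image rotation", {
  set.seed(17)
  spec <- synthetic_spec(n_classes = 2, images_per_class = 1,
                         image_size = c(48, 48), seed = 9)
  ds <- generate_dataset(spec)
  cp <- separate_stains(ds$images[[1]])
  img <- cp$protein
  rot90 <- t(img)[ncol(img):1, ]
  v1 <- extract_riclbp(img)
  v2 <- extract_riclbp(rot90)
  expect_lt(max(abs(v1 - v2)), 0.02)   # histogram-count tolerance at borders
})
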