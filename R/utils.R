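#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd cor
#' @importFrom utils modifyList write.table read.delim
NULL

# Derive a child seed from a root seed and a component tag, so every stochastic
# component of the pipeline gets its own reproducible stream. Kept below 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Otsu threshold on a continuous-valued matrix. The value range is binned into
# `nbins` equal-width cells; returns the threshold value maximizing
# between-class variance. A constant input returns its single value (so that
# `x > otsu(x)` is empty).
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  mids[which.max(sigma_b)]
}

# Min-max scaler to [0, 1], fit on training rows only.  Constant columns map
# to 0.  Values outside the training range are clipped at transform time so
# sigmoid reconstruction targets stay in [0, 1].
fit_minmax <- function(X) {
  mins <- apply(X, 2, min)
  rngs <- apply(X, 2, max) - mins
  list(min = mins, range = rngs)
}

apply_minmax <- function(scaler, X) {
  X <- sweep(X, 2, scaler$min, "-")
  rng <- ifelse(scaler$range > 0, scaler$range, 1)
  X <- sweep(X, 2, rng, "/")
  X[, scaler$range == 0] <- 0
  pmin(pmax(X, 0), 1)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so per-class test counts differ by at most one across folds.
stratified_folds <- function(y, k, seed) {
  y <- as.integer(y)
  if (k < 2) stop("k must be >= 2")
  cnt <- table(y)
  if (any(cnt < k)) {
    bad <- names(cnt)[cnt < k]
    stop(sprintf(
      "stratification error: class(es) %s have fewer than k = %d samples; reduce k or add samples",
      paste(bad, collapse = ", "), k))
  }
  set.seed(derive_seed(seed, "stratified_folds"))
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
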