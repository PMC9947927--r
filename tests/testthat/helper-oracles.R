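# Independent from-definition oracles, written as plain nested loops against
# the stated conventions. They share no code with the package implementation.

# Beer-Lambert optical density of one pixel channel, scalar form.
oracle_od_scalar <- function(p, I0) {
  v <- -log((p + 1) / (I0 + 1))
  if (v < 0) 0 else v
}

# Two-stain unmixing of one OD 3-vector by explicitly coded normal equations.
oracle_unmix <- function(od, v1, v2) {
  a11 <- sum(v1 * v1); a12 <- sum(v1 * v2); a22 <- sum(v2 * v2)
  b1 <- sum(v1 * od); b2 <- sum(v2 * od)
  det <- a11 * a22 - a12 * a12
  c1 <- (a22 * b1 - a12 * b2) / det
  c2 <- (a11 * b2 - a12 * b1) / det
  c(max(c1, 0), max(c2, 0))
}

# Bilinear sample of img at (continuous) row y, col x.
oracle_bilinear <- function(img, y, x) {
  snap <- 1e-9
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  if (abs(fy) < snap) fy <- 0
  if (abs(fx) < snap) fx <- 0
  if (abs(fy - 1) < snap) { fy <- 0; y0 <- y0 + 1 }
  if (abs(fx - 1) < snap) { fx <- 0; x0 <- x0 + 1 }
  y1 <- min(y0 + 1, nrow(img)); x1 <- min(x0 + 1, ncol(img))
  (1 - fy) * (1 - fx) * img[y0, x0] + (1 - fy) * fx * img[y0, x1] +
    fy * (1 - fx) * img[y1, x0] + fy * fx * img[y1, x1]
}

# Per-pixel 8-neighbor radius-1 LBP codes by nested loops (east first,
# counter-clockwise, >= comparison, bilinear sampling on the unit circle).
oracle_lbp_codes <- function(img) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_integer_, h - 2, w - 2)
  for (r in 2:(h - 1)) {
    for (c in 2:(w - 1)) {
      code <- 0L
      for (k in 0:7) {
        ang <- 2 * pi * k / 8
        nb <- oracle_bilinear(img, r - sin(ang), c + cos(ang))
        if (nb >= img[r, c]) code <- code + as.integer(2^k)
      }
      out[r - 1, c - 1] <- code
    }
  }
  out
}

# CLBP sign and magnitude per-pixel patterns at (P, R) = (8, 1) by nested
# loops; magnitude threshold supplied by the caller.
oracle_clbp_patterns <- function(img, m_threshold) {
  h <- nrow(img); w <- ncol(img)
  s_out <- m_out <- matrix(NA_integer_, h - 2, w - 2)
  for (r in 2:(h - 1)) {
    for (c in 2:(w - 1)) {
      s_code <- m_code <- 0L
      for (k in 0:7) {
        ang <- 2 * pi * k / 8
        nb <- oracle_bilinear(img, r - sin(ang), c + cos(ang))
        d <- nb - img[r, c]
        if (d >= 0) s_code <- s_code + as.integer(2^k)
        if (abs(d) >= m_threshold) m_code <- m_code + as.integer(2^k)
      }
      s_out[r - 1, c - 1] <- s_code
      m_out[r - 1, c - 1] <- m_code
    }
  }
  list(sign = s_out, mag = m_out)
}

# Symmetric normalized GLCM by explicit pair enumeration.
oracle_glcm <- function(q, n, drow, dcol) {
  P <- matrix(0, n, n)
  h <- nrow(q); w <- ncol(q)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + drow; c2 <- c + dcol
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
        P[q[r, c], q[r2, c2]] <- P[q[r, c], q[r2, c2]] + 1
        P[q[r2, c2], q[r, c]] <- P[q[r2, c2], q[r, c]] + 1
      }
    }
  }
  P / sum(P)
}

# The 19 co-occurrence statistics from their definitions, explicit loops.
oracle_glcm_stats <- function(P) {
  n <- nrow(P)
  px <- numeric(n)
  for (i in 1:n) for (j in 1:n) px[i] <- px[i] + P[i, j]
  mu <- sum((1:n) * px)
  sg <- sqrt(sum(((1:n) - mu)^2 * px))
  psum <- numeric(2 * n); pdif <- numeric(n)
  for (i in 1:n) for (j in 1:n) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  asm <- contrast <- idm <- ent <- acorr <- dissim <- shade <- prom <- invdiff <- 0
  var_ <- 0
  for (i in 1:n) for (j in 1:n) {
    p <- P[i, j]
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    if (p > 0) ent <- ent - p * log2(p)
    acorr <- acorr + i * j * p
    dissim <- dissim + abs(i - j) * p
    shade <- shade + (i + j - 2 * mu)^3 * p
    prom <- prom + (i + j - 2 * mu)^4 * p
    invdiff <- invdiff + p / (1 + abs(i - j))
    var_ <- var_ + (i - mu)^2 * p
  }
  correlation <- if (sg > 0) (acorr - mu^2) / sg^2 else 0
  sa <- 0; for (k in 2:(2 * n)) sa <- sa + k * psum[k]
  sv <- 0; for (k in 2:(2 * n)) sv <- sv + (k - sa)^2 * psum[k]
  se <- 0; for (k in 2:(2 * n)) if (psum[k] > 0) se <- se - psum[k] * log2(psum[k])
  dmean <- 0; for (k in 0:(n - 1)) dmean <- dmean + k * pdif[k + 1]
  dv <- 0; for (k in 0:(n - 1)) dv <- dv + k^2 * pdif[k + 1]
  dv <- dv - dmean^2
  de <- 0; for (k in 0:(n - 1)) if (pdif[k + 1] > 0) de <- de - pdif[k + 1] * log2(pdif[k + 1])
  HX <- 0; for (i in 1:n) if (px[i] > 0) HX <- HX - px[i] * log2(px[i])
  HXY1 <- HXY2 <- 0
  for (i in 1:n) for (j in 1:n) {
    q <- px[i] * px[j]
    if (q > 0) {
      if (P[i, j] > 0) HXY1 <- HXY1 - P[i, j] * log2(q)
      HXY2 <- HXY2 - q * log2(q)
    }
  }
  imc1 <- if (HX > 0) (ent - HXY1) / HX else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - ent))))
  c(asm = asm, contrast = contrast, correlation = correlation, variance = var_,
    idm = idm, sum_average = sa, sum_variance = sv, sum_entropy = se,
    entropy = ent, diff_variance = dv, diff_entropy = de, imc1 = imc1,
    imc2 = imc2, autocorrelation = acorr, dissimilarity = dissim,
    cluster_shade = shade, cluster_prominence = prom, max_prob = max(P),
    inverse_difference = invdiff)
}

# Wilks' lambda from explicitly accumulated scatter matrices.
oracle_wilks <- function(X, y, subset) {
  Xs <- X[, subset, drop = FALSE]
  n <- nrow(Xs); d <- ncol(Xs)
  gm <- colSums(Xs) / n
  Tm <- matrix(0, d, d)
  for (i in 1:n) Tm <- Tm + (Xs[i, ] - gm) %*% t(Xs[i, ] - gm)
  Wm <- matrix(0, d, d)
  for (cl in unique(y)) {
    rows <- which(y == cl)
    cm <- colSums(Xs[rows, , drop = FALSE]) / length(rows)
    for (i in rows) Wm <- Wm + (Xs[i, ] - cm) %*% t(Xs[i, ] - cm)
  }
  det(Wm) / det(Tm)
}

# Textbook stepwise selection driven entirely by oracle_wilks; same
# thresholds and tie rule (lowest index) as the implementation, no
# standardization (Wilks' lambda is scale-invariant).
oracle_stepwise <- function(X, y, f_enter = 3.84, f_remove = 2.71,
                            max_features = ncol(X)) {
  N <- nrow(X); C <- length(unique(y))
  s <- integer(0)
  usable <- which(apply(X, 2, sd) > 0)
  lam <- function(sub) if (length(sub) == 0) 1 else oracle_wilks(X, y, sub)
  repeat {
    changed <- FALSE
    if (length(s) < max_features) {
      cand <- setdiff(usable, s)
      if (length(cand) > 0) {
        Fs <- sapply(cand, function(q) {
          l1 <- lam(c(s, q))
          if (!is.finite(l1) || l1 <= 0) return(0)
          (N - C - length(s)) / (C - 1) * (lam(s) / l1 - 1)
        })
        best <- which.max(Fs)
        if (Fs[best] > f_enter) {
          s <- c(s, cand[best]); changed <- TRUE
        } else if (length(s) == 0) {
          return(cand[which.max(Fs)])
        }
      }
    }
    repeat {
      if (length(s) < 2) break
      Fr <- sapply(seq_along(s), function(i) {
        l0 <- lam(s[-i]); l1 <- lam(s)
        if (!is.finite(l1) || l1 <= 0) return(Inf)
        (N - C - (length(s) - 1)) / (C - 1) * (l0 / l1 - 1)
      })
      worst <- which.min(Fr)
      if (Fr[worst] < f_remove) { s <- s[-worst]; changed <- TRUE } else break
    }
    if (!changed || length(s) >= max_features) break
  }
  s
}

# Metrics from their definitions with explicit counting loops.
oracle_metrics <- function(y_true, y_pred, probs, C) {
  N <- length(y_true)
  conf <- matrix(0, C, C)
  for (i in 1:N) conf[y_true[i], y_pred[i]] <- conf[y_true[i], y_pred[i]] + 1
  oa <- sum(diag(conf)) / N
  prec <- rec <- f1 <- numeric(C)
  for (k in 1:C) {
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  num <- N * sum(diag(conf)) - sum(sapply(1:C, function(k) sum(conf[k, ]) * sum(conf[, k])))
  den <- sqrt(N^2 - sum(sapply(1:C, function(k) sum(conf[, k])^2))) *
    sqrt(N^2 - sum(sapply(1:C, function(k) sum(conf[k, ])^2)))
  mcc <- if (den > 0) num / den else 0
  auc <- aupr <- numeric(C)
  for (k in 1:C) {
    pos <- y_true == k
    sc <- probs[, k]
    thr <- sort(unique(sc), decreasing = TRUE)
    tpr <- fpr <- numeric(length(thr) + 1)
    for (t in seq_along(thr)) {
      tp <- fp <- 0
      for (i in 1:N) {
        if (sc[i] >= thr[t]) {
          if (pos[i]) tp <- tp + 1 else fp <- fp + 1
        }
      }
      tpr[t + 1] <- tp / sum(pos); fpr[t + 1] <- fp / sum(!pos)
    }
    a <- 0
    for (t in 2:length(tpr))
      a <- a + (fpr[t] - fpr[t - 1]) * (tpr[t] + tpr[t - 1]) / 2
    auc[k] <- a
    rec_prev <- 0; ap <- 0
    for (t in seq_along(thr)) {
      tp <- fp <- 0
      for (i in 1:N) {
        if (sc[i] >= thr[t]) {
          if (pos[i]) tp <- tp + 1 else fp <- fp + 1
        }
      }
      r <- tp / sum(pos); p <- tp / (tp + fp)
      ap <- ap + (r - rec_prev) * p
      rec_prev <- r
    }
    aupr[k] <- ap
  }
  list(oa = oa, prec_macro = mean(prec), rec_macro = mean(rec),
       f1_macro = mean(f1), mcc = mcc, auc = auc, aupr = aupr,
       mean_auc = mean(auc), std_auc = sqrt(mean((auc - mean(auc))^2)),
       mean_aupr = mean(aupr), std_aupr = sqrt(mean((aupr - mean(aupr))^2)))
}

# Element-wise loop average of decision sets.
oracle_mean_ensemble <- function(mats) {
  out <- matrix(0, nrow(mats[[1]]), ncol(mats[[1]]))
  for (i in seq_len(nrow(out)))
    for (j in seq_len(ncol(out)))
      for (m in mats) out[i, j] <- out[i, j] + m[i, j] / length(mats)
  out
}

# Random row-stochastic matrix.
random_simplex <- function(n, c) {
  m <- matrix(stats::rexp(n * c), n, c)
  m / rowSums(m)
}
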