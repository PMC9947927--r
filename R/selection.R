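# Stepwise discriminant analysis (SDA).
#
# Classical forward selection with backward elimination on Wilks' lambda
# Lambda = det(W)/det(T), where W and T are the within-group and total
# scatter matrices restricted to the candidate subset. The partial F for
# entering feature q given the current subset s is
#   F = (N - C - |s|) / (C - 1) * (Lambda(s) / Lambda(s u {q}) - 1),
# and the lambda ratio is computed for all candidates at once from Schur
# complements of W and T on the selected subset.

#' Wilks' lambda of a feature subset
#'
#' `Lambda = det(W_s) / det(T_s)` with W, T the within-group and total
#' scatter matrices restricted to `subset`. A singular within-group scatter
#' triggers a ridge-stabilized fallback (`eps * I` added to both matrices)
#' with a warning.
#'
#' @param X numeric N x d matrix.
#' @param y integer class labels (>= 2 classes, each with >= 2 samples).
#' @param subset integer feature indices (1-based, non-empty).
#' @return scalar in (0, 1].
#' @export
wilks_lambda <- function(X, y, subset) {
  if (length(subset) == 0) stop("`subset` must be non-empty")
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("at least 2 classes required")
  sc <- scatter_matrices(X[, subset, drop = FALSE], y)
  dW <- det(sc$W); dT <- det(sc$T)
  if (!is.finite(dW) || !is.finite(dT) || dW <= 0 || dT <= 0) {
    warning("singular scatter matrix; applying ridge stabilization")
    eps <- 1e-8 * mean(diag(sc$T))
    if (eps <= 0) eps <- 1e-8
    k <- length(subset)
    dW <- det(sc$W + eps * diag(k)); dT <- det(sc$T + eps * diag(k))
  }
  min(dW / dT, 1)
}

# Within-group (W) and total (T) scatter matrices of the full matrix.
scatter_matrices <- function(X, y) {
  X <- as.matrix(X)
  Tc <- scale(X, center = TRUE, scale = FALSE)
  Tm <- crossprod(Tc)
  Wm <- matrix(0, ncol(X), ncol(X))
  for (cl in unique(y)) {
    Xi <- X[y == cl, , drop = FALSE]
    if (nrow(Xi) < 2) stop("every class needs >= 2 samples")
    Wi <- scale(Xi, center = TRUE, scale = FALSE)
    Wm <- Wm + crossprod(Wi)
  }
  list(W = Wm, T = Tm)
}

# Residual diagonals of W and T for all candidate features given subset s:
# res_q = M[q,q] - M[q,s] M[s,s]^{-1} M[s,q].  Lambda(s u q)/Lambda(s) =
# resW_q / resT_q.
residual_diag <- function(M, s, cand) {
  if (length(s) == 0) return(diag(M)[cand])
  Mss <- M[s, s, drop = FALSE]
  Msq <- M[s, cand, drop = FALSE]
  sol <- tryCatch(solve(Mss, Msq), error = function(e) {
    eps <- max(1e-8 * mean(diag(Mss)), 1e-10)
    solve(Mss + eps * diag(length(s)), Msq)
  })
  diag(M)[cand] - colSums(Msq * sol)
}

#' Stepwise discriminant feature selection
#'
#' Forward selection with backward elimination: at each step the unselected
#' feature with the largest partial F enters if it exceeds `f_enter`; then
#' any selected feature whose partial F falls below `f_remove` is removed.
#' Columns are z-scored on the provided rows before selection; the stored
#' means/SDs transform test rows identically. Ties in partial F break toward
#' the lowest feature index. If no feature passes `f_enter` at the first
#' step, the single best feature is returned with a warning.
#'
#' @param fs a [feature_set] (training rows only).
#' @param f_enter,f_remove partial-F thresholds, `f_enter >= f_remove > 0`
#'   (defaults 3.84 / 2.71).
#' @param max_features cap on the selected subset size; default
#'   `min(d, N - C - 1)`.
#' @return an object of class `sda_selection` with fields `selected`
#'   (ordered indices), `lambda_trace`, `f_enter`, `f_remove`, `steps_log`,
#'   `center`, `scale`, `feature_ids`.
#' @export
sda_select <- function(fs, f_enter = 3.84, f_remove = 2.71, max_features = NULL) {
  if (!inherits(fs, "feature_set")) stop("`fs` must be a feature_set")
  if (!(f_enter >= f_remove && f_remove > 0))
    stop("need f_enter >= f_remove > 0")
  X <- fs$matrix
  y <- as.integer(fs$labels)
  N <- nrow(X); C <- length(unique(y)); d <- ncol(X)
  if (N <= C) stop("need more samples than classes")
  if (is.null(max_features)) max_features <- min(d, N - C - 1)
  # within-group scatter turns singular at N - C selected features, so the
  # cap always binds even when a larger value is requested
  max_features <- max(1L, min(max_features, d, N - C - 1))
  audit_record("sda", fs$source_ids)

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  usable <- scl > 0
  scl[!usable] <- 1
  Z <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")

  sc <- scatter_matrices(Z, y)
  Wm <- sc$W; Tm <- sc$T

  s <- integer(0)
  lambda <- 1
  lambda_trace <- numeric(0)
  log_action <- character(0); log_index <- integer(0); log_f <- numeric(0)
  seen <- character(0)

  repeat {
    changed <- FALSE
    # ---- forward step
    if (length(s) < max_features) {
      cand <- setdiff(which(usable), s)
      if (length(cand) > 0) {
        resW <- residual_diag(Wm, s, cand)
        resT <- residual_diag(Tm, s, cand)
        ok <- is.finite(resW) & is.finite(resT) & resT > 1e-10 * diag(Tm)[cand] & resW >= 0
        ratio <- rep(1, length(cand))         # Lambda(s u q)/Lambda(s)
        ratio[ok] <- pmin(resW[ok] / resT[ok], 1)
        Fin <- (N - C - length(s)) / (C - 1) * (1 / ratio - 1)
        Fin[!ok] <- 0
        best <- which.max(Fin * (1 + 1e-12))  # which.max takes first max: lowest index
        if (Fin[best] > f_enter) {
          q <- cand[best]
          lambda <- lambda * ratio[best]
          s <- c(s, q)
          lambda_trace <- c(lambda_trace, lambda)
          log_action <- c(log_action, "enter"); log_index <- c(log_index, q)
          log_f <- c(log_f, Fin[best])
          changed <- TRUE
        } else if (length(s) == 0) {
          warning("no feature passes f_enter; returning the single best feature")
          q <- cand[best]
          lambda <- lambda * ratio[best]
          s <- q
          lambda_trace <- lambda
          log_action <- "enter_forced"; log_index <- q; log_f <- Fin[best]
          break
        }
      } else if (length(s) == 0) stop("no usable (non-constant) features")
    }
    # ---- backward step(s)
    repeat {
      if (length(s) < 2) break
      Frem <- vapply(seq_along(s), function(i) {
        sj <- s[-i]; j <- s[i]
        resW <- residual_diag(Wm, sj, j)
        resT <- residual_diag(Tm, sj, j)
        if (!is.finite(resW) || !is.finite(resT) || resT <= 0 || resW <= 0) return(Inf)
        ratio <- min(resW / resT, 1)          # Lambda(s)/Lambda(s - j)
        (N - C - (length(s) - 1)) / (C - 1) * (1 / ratio - 1)
      }, numeric(1))
      worst <- which.min(Frem)
      if (Frem[worst] < f_remove) {
        j <- s[worst]
        s <- s[-worst]
        lambda <- wilks_lambda(Z, y, s)
        log_action <- c(log_action, "remove"); log_index <- c(log_index, j)
        log_f <- c(log_f, Frem[worst])
        changed <- TRUE
        sig <- paste(sort(s), collapse = ",")
        if (sig %in% seen) { changed <- FALSE; break }  # cycle guard
        seen <- c(seen, sig)
      } else break
    }
    if (!changed || length(s) >= max_features) break
  }

  structure(list(selected = s,
                 lambda_trace = lambda_trace,
                 f_enter = f_enter, f_remove = f_remove,
                 steps_log = data.frame(action = log_action, index = log_index,
                                        partial_f = log_f),
                 center = ctr, scale = scl,
                 feature_ids = fs$feature_ids[s],
                 n_train = N),
            class = "sda_selection")
}

#' Project a feature matrix onto a selection result
#'
#' Returns the selected raw columns (the optimal subset is a column subset,
#' not a transformation). Set `standardize = TRUE` to apply the stored
#' training z-scoring.
#'
#' @param sel an `sda_selection`.
#' @param X numeric matrix with the original full dimensionality.
#' @param standardize apply stored training means/SDs (default FALSE).
#' @return matrix with `length(sel$selected)` columns.
#' @export
project_selection <- function(sel, X, standardize = FALSE) {
  if (ncol(X) != length(sel$center))
    stop("shape error: X has ", ncol(X), " columns; selection expects ", length(sel$center))
  if (standardize)
    X <- sweep(sweep(X, 2, sel$center, "-"), 2, sel$scale, "/")
  X[, sel$selected, drop = FALSE]
}
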