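# Principal motion analysis (PMA): a partial-least-squares-derived
# deflation regression of per-step minimum MoS on flattened step signals.
#
# With column-centred X and centred y, components l = 1..L are built as
#   w_l = X_l' y_l / |X_l' y_l|          (unit weight vector)
#   c_l = X w_l                          (scores; "as_printed" variant uses
#                                         the UNdeflated centred X)
#   p_l = X_l' c_l / (c_l' c_l)          (loadings)
#   b_l = c_l' y_l / (c_l' c_l)          (regression coefficient)
#   X_{l+1} = X_l - c_l p_l',  y_{l+1} = y_l - b_l c_l
# and a new sample is predicted as  y_hat = (x - x_mean)' sum_l b_l w_l +
# y_mean.  The "nipals" variant instead takes c_l = X_l w_l (standard
# NIPALS PLS1) with the usual combined coefficients W (P'W)^{-1} b; the two
# coincide at L = 1.

#' Fit a principal motion analysis model
#'
#' @param X Numeric n x d predictor matrix (rows: step samples; columns:
#'   flattened 51-point x 6-axis signals, optionally for two sensors).
#' @param y Numeric response vector of length n (per-step minimum MoS,
#'   mm).
#' @param L Number of principal motions (components), >= 1. Capped at
#'   `min(n - 1, d)` with a warning.
#' @param variant `"as_printed"` (default; scores from the undeflated
#'   centred X) or `"nipals"` (standard PLS1 deflated scores).
#' @param tol Zero-norm tolerance for degenerate covariance; if
#'   `|X_l' y_l|` vanishes at component `l`, fitting stops early with
#'   `L_effective = l - 1` (an error if `l = 1`).
#' @return Object of class `pma_model` with elements `x_mean`, `y_mean`,
#'   `W` (d x L unit weight vectors), `P` (loadings), `b` (coefficients),
#'   `beta` (combined coefficient vector), `L`, `L_effective`, `variant`
#'   and `resid_norms` (`|y_l|` for l = 1..L_effective+1, non-increasing).
#' @seealso [predict.pma_model()], [pma_fit_reference()]
#' @export
pma_fit <- function(X, y, L, variant = c("as_printed", "nipals"), tol = 1e-12) {
  variant <- match.arg(variant)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); d <- ncol(X)
  if (n != length(y)) stopf("input error: nrow(X) != length(y)")
  if (n < 2) stopf("input error: need at least 2 samples")
  if (L < 1) stopf("input error: L must be >= 1")
  L_max <- min(n - 1, d)
  if (L > L_max) {
    warnf("L = %d exceeds min(n - 1, d) = %d; capped", L, L_max)
    L <- L_max
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- matrix(0, d, L)
  P <- matrix(0, d, L)
  b <- numeric(L)
  Xl <- Xc
  yl <- yc
  resid_norms <- sqrt(sum(yl^2))
  L_eff <- 0L
  for (l in seq_len(L)) {
    v <- crossprod(Xl, yl)
    nv <- sqrt(sum(v^2))
    if (nv <= tol * max(1, resid_norms[1])) {
      if (l == 1) stopf("degenerate input: X and y are uncorrelated (|X'y| = 0)")
      warnf("covariance vanished at component %d; stopping with L_effective = %d",
            l, l - 1L)
      break
    }
    w <- as.vector(v) / nv
    cl <- if (variant == "as_printed") as.vector(Xc %*% w) else as.vector(Xl %*% w)
    cc <- sum(cl^2)
    if (cc <= tol^2) {
      if (l == 1) stopf("degenerate input: zero score vector at component 1")
      warnf("zero score vector at component %d; stopping with L_effective = %d",
            l, l - 1L)
      break
    }
    p <- as.vector(crossprod(Xl, cl)) / cc
    bl <- sum(cl * yl) / cc
    W[, l] <- w
    P[, l] <- p
    b[l] <- bl
    Xl <- Xl - tcrossprod(cl, p)
    yl <- yl - bl * cl
    resid_norms <- c(resid_norms, sqrt(sum(yl^2)))
    L_eff <- l
  }
  W <- W[, seq_len(L_eff), drop = FALSE]
  P <- P[, seq_len(L_eff), drop = FALSE]
  b <- b[seq_len(L_eff)]
  beta <- if (variant == "as_printed") {
    as.vector(W %*% b)
  } else {
    as.vector(W %*% solve(crossprod(P, W), b))
  }
  structure(list(x_mean = x_mean, y_mean = y_mean, W = W, P = P, b = b,
                 beta = beta, L = L, L_effective = L_eff, variant = variant,
                 resid_norms = resid_norms),
            class = "pma_model")
}

#' Predict minimum MoS for new step samples
#'
#' Applies `y_hat = (x - x_mean)' beta + y_mean` with the training
#' centering statistics.
#'
#' @param object A fitted [pma_fit()] model.
#' @param newdata m x d matrix (or single vector) of predictor rows.
#' @param ... Unused.
#' @return Numeric vector of m predictions (same units as the training
#'   response).
#' @export
predict.pma_model <- function(object, newdata, ...) {
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    stopf("input error: newdata has %d columns, model expects %d",
          ncol(newdata), length(object$x_mean))
  }
  as.vector(sweep(newdata, 2, object$x_mean) %*% object$beta) + object$y_mean
}

#' @export
print.pma_model <- function(x, ...) {
  cat(sprintf("<pma_model> %d principal motions (%s variant), %d predictors\n",
              x$L_effective, x$variant, length(x$x_mean)))
  cat(sprintf("  training residual norms: %s\n",
              paste(signif(x$resid_norms, 4), collapse = " -> ")))
  invisible(x)
}

# Predictions for every component count 1..L_effective in one pass;
# used by select_L so the deflation runs once per fold.
pma_path_predict <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  Xc <- sweep(newdata, 2, model$x_mean)
  L <- model$L_effective
  out <- matrix(0, nrow(newdata), L)
  if (model$variant == "as_printed") {
    S <- Xc %*% model$W                       # m x L component contributions
    contrib <- sweep(S, 2, model$b, `*`)
    out <- t(apply(contrib, 1, cumsum))
    if (L == 1) out <- matrix(contrib, ncol = 1)
  } else {
    for (l in seq_len(L)) {
      Wl <- model$W[, 1:l, drop = FALSE]
      Pl <- model$P[, 1:l, drop = FALSE]
      beta_l <- Wl %*% solve(crossprod(Pl, Wl), model$b[1:l])
      out[, l] <- as.vector(Xc %*% beta_l)
    }
  }
  out + model$y_mean
}

#' Training residual-norm curve
#'
#' Returns `|y_l|` for l = 1..L_max+1, where `y_1` is the centred
#' response and each subsequent entry is the residual after removing one
#' more principal motion. Because each component performs a least-squares
#' projection of the current residual onto its score vector, the sequence
#' is non-increasing.
#'
#' @inheritParams pma_fit
#' @param L_max Largest component count to evaluate.
#' @return Numeric vector of residual norms (length `L_max + 1`, shorter
#'   if fitting stopped early on vanishing covariance).
#' @export
training_residual_curve <- function(X, y, L_max, variant = c("as_printed", "nipals")) {
  variant <- match.arg(variant)
  pma_fit(X, y, L_max, variant = variant)$resid_norms
}

#' Reference transcription of the PMA recursion (testing oracle)
#'
#' A deliberately literal, loop-based implementation of the centering,
#' deflation, score/loading/coefficient recursion and prediction rule,
#' kept independent of [pma_fit()] so the two can be cross-checked on
#' random instances. Use only on small problems; it is quadratic-time by
#' construction.
#'
#' @inheritParams pma_fit
#' @return List with `x_mean`, `y_mean`, `L` and per-component list
#'   `comp` (each holding `w`, `c`, `p`, `b`).
#' @export
pma_fit_reference <- function(X, y, L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); d <- ncol(X)
  x_mean <- numeric(d)
  for (j in seq_len(d)) x_mean[j] <- sum(X[, j]) / n
  y_mean <- sum(y) / n
  Xc <- matrix(0, n, d)
  for (j in seq_len(d)) Xc[, j] <- X[, j] - x_mean[j]
  yc <- y - y_mean
  Xl <- Xc
  yl <- yc
  comp <- vector("list", L)
  for (l in seq_len(L)) {
    v <- numeric(d)
    for (j in seq_len(d)) v[j] <- sum(Xl[, j] * yl)
    nv <- sqrt(sum(v * v))
    w <- v / nv
    cl <- numeric(n)
    for (i in seq_len(n)) cl[i] <- sum(Xc[i, ] * w)
    cc <- sum(cl * cl)
    p <- numeric(d)
    for (j in seq_len(d)) p[j] <- sum(Xl[, j] * cl) / cc
    bl <- sum(cl * yl) / cc
    comp[[l]] <- list(w = w, c = cl, p = p, b = bl)
    for (j in seq_len(d)) Xl[, j] <- Xl[, j] - cl * p[j]
    yl <- yl - bl * cl
  }
  list(x_mean = x_mean, y_mean = y_mean, L = L, comp = comp)
}

#' Predict with the reference PMA transcription
#'
#' @param ref Output of [pma_fit_reference()].
#' @param newdata m x d matrix of predictor rows.
#' @return Numeric vector of m predictions.
#' @export
pma_predict_reference <- function(ref, newdata) {
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  m <- nrow(newdata)
  out <- numeric(m)
  for (i in seq_len(m)) {
    xi <- newdata[i, ] - ref$x_mean
    s <- 0
    for (l in seq_len(ref$L)) {
      s <- s + ref$comp[[l]]$b * sum(xi * ref$comp[[l]]$w)
    }
    out[i] <- s + ref$y_mean
  }
  out
}
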