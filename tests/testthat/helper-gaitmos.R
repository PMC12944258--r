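# Shared fixtures and independent oracles for the test suite. Everything
# is generated in code; no data files.

# A small, fast trial configuration: one participant, reduced step count
# and warm-up, three representative sites. Study-scale defaults are
# exercised separately where a test needs them.
small_config <- function(seed = 42, steps = 12, warmup = 6,
                         sites = c("right_knee", "sacral_crest", "skull_vertex"),
                         ...) {
  gait_sim_config(n_participants = 1, steps_per_foot_per_speed = steps,
                  warmup_s = warmup, sites = sites, seed = seed, ...)
}

random_regression <- function(seed, n = 20, d = 30, names = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  if (names) colnames(X) <- paste0("v", seq_len(d))
  y <- as.vector(X %*% rnorm(d)) + rnorm(n)
  Xnew <- matrix(rnorm(5 * d), 5, d)
  if (names) colnames(Xnew) <- colnames(X)
  list(X = X, y = y, Xnew = Xnew)
}

# Independent NIPALS PLS1 (single response), written from the textbook
# recursion and kept free of any gaitmos code: weight from deflated X,
# scores from deflated X, prediction through sequential deflation of the
# new sample. Used as the external oracle for the L = 1 limit.
nipals_pls1 <- function(X, y, ncomp) {
  xbar <- colMeans(X)
  ybar <- mean(y)
  E <- sweep(X, 2, xbar)
  f <- y - ybar
  W <- NULL; P <- NULL; q <- numeric(0)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    t_ <- drop(E %*% w)
    p <- drop(crossprod(E, t_)) / sum(t_^2)
    qa <- sum(t_ * f) / sum(t_^2)
    E <- E - tcrossprod(t_, p)
    f <- f - qa * t_
    W <- cbind(W, w); P <- cbind(P, p); q <- c(q, qa)
  }
  list(xbar = xbar, ybar = ybar, W = W, P = P, q = q)
}

nipals_pls1_predict <- function(fit, Xnew) {
  E <- sweep(Xnew, 2, fit$xbar)
  out <- rep(fit$ybar, nrow(Xnew))
  for (a in seq_along(fit$q)) {
    t_ <- drop(E %*% fit$W[, a])
    out <- out + fit$q[a] * t_
    E <- E - tcrossprod(t_, fit$P[, a])
  }
  out
}

# Constant-value IMU recording on a uniform grid.
constant_imu <- function(value = 1, rate = 100, duration = 5) {
  t <- seq(0, duration, by = 1 / rate)
  df <- data.frame(time_s = t, ax = value, ay = value, az = value,
                   gx = value, gy = value, gz = value)
  df
}

alternating_events <- function(times) {
  data.frame(time_s = times,
             foot = rep(c("left", "right"), length.out = length(times)),
             stringsAsFactors = FALSE)
}
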