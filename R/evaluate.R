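# Repeated stratified cross-validation, error metrics, component-count
# selection, the sensor-placement grid, and SD-band MoS categorisation.

#' Root mean squared error
#'
#' @param y_hat,y Equal-length numeric vectors (typically mm).
#' @return `sqrt(mean((y_hat - y)^2))`.
#' @export
rmse <- function(y_hat, y) {
  if (length(y_hat) != length(y) || length(y) == 0) {
    stopf("input error: y_hat and y must be equal nonzero lengths")
  }
  sqrt(mean((y_hat - y)^2))
}

#' Pearson correlation between estimated and reference values
#'
#' Returns `NA` with a warning if either vector is constant (the
#' correlation is then undefined).
#'
#' @param y_hat,y Numeric vectors of equal length >= 3.
#' @return Pearson product-moment correlation, or `NA`.
#' @export
pearson <- function(y_hat, y) {
  if (length(y_hat) != length(y) || length(y) < 3) {
    stopf("input error: need equal lengths >= 3")
  }
  if (stats::sd(y_hat) == 0 || stats::sd(y) == 0) {
    warnf("correlation undefined for constant vector; returning NA")
    return(NA_real_)
  }
  stats::cor(y_hat, y)
}

#' Stratified fold assignment
#'
#' Within every (participant, speed) stratum the samples are shuffled and
#' dealt round-robin to the k folds (from a random starting fold), so
#' samples recorded at the same speed by the same participant are evenly
#' distributed across folds: within-stratum fold sizes differ by at most
#' one.
#'
#' @param meta Data frame with one row per sample; columns `participant`
#'   and `speed_kmh` define the strata if present (either may be absent;
#'   with neither, all samples form one stratum). May also be an integer
#'   `n` for unstratified assignment.
#' @param k Number of folds, >= 2. Must not exceed the sample count.
#' @param seed Integer seed controlling the shuffle.
#' @return Integer vector of fold indices in 1..k, one per sample.
#' @export
make_folds <- function(meta, k = 10, seed = 1) {
  if (is.numeric(meta) && length(meta) == 1) {
    meta <- data.frame(.row = seq_len(meta))
  }
  n <- nrow(meta)
  if (k < 2) stopf("configuration error: k must be >= 2")
  if (k > n) stopf("configuration error: k = %d exceeds sample count %d", k, n)
  keys <- intersect(c("participant", "speed_kmh"), names(meta))
  stratum <- if (length(keys) == 0) rep(1L, n) else {
    interaction(meta[keys], drop = TRUE)
  }
  fold <- integer(n)
  with_local_seed(seed, {
    for (s in levels(factor(stratum))) {
      idx <- which(stratum == s)
      idx <- idx[sample.int(length(idx))]
      start <- sample.int(k, 1)
      fold[idx] <- ((start - 1 + seq_along(idx) - 1) %% k) + 1L
    }
  })
  fold
}

#' Repeated stratified k-fold cross-validation of a PMA model
#'
#' For each repetition (seed `base_seed + r`, r = 1..repetitions) the
#' samples are stratified into k folds; each fold is predicted by a model
#' fitted on the other k-1 folds (centering statistics recomputed inside
#' every training fold), and the held-out RMSE and Pearson correlation
#' are recorded. Summaries are the mean and standard deviation over all
#' k x repetitions fold-level values.
#'
#' @param dm A [build_design_matrix()] object, or any list with elements
#'   `X`, `y`, `meta`.
#' @param L Number of principal motions.
#' @param k Folds, default 10.
#' @param repetitions Number of repeated fold assignments, default 5.
#' @param base_seed Base seed; repetition r uses `base_seed + r`.
#' @param variant Passed to [pma_fit()].
#' @return Object of class `cv_result`: list with `folds` (data frame of
#'   per-fold `repetition`, `fold`, `n_test`, `rmse`, `pearson`) and
#'   `summary` (named vector: mean_rmse, sd_rmse, mean_pearson,
#'   sd_pearson).
#' @export
cross_validate <- function(dm, L, k = 10, repetitions = 5, base_seed = 1,
                           variant = "as_printed") {
  X <- dm$X; y <- dm$y
  if (is.null(X) || nrow(X) == 0) stopf("input error: empty design matrix")
  rows <- list()
  for (r in seq_len(repetitions)) {
    fold <- make_folds(dm$meta %||% nrow(X), k = k, seed = base_seed + r)
    for (f in sort(unique(fold))) {
      test <- fold == f
      if (sum(!test) < 2) {
        stopf("configuration error: fold %d leaves < 2 training samples", f)
      }
      if (!any(test)) next
      fit <- pma_fit(X[!test, , drop = FALSE], y[!test], L, variant = variant)
      y_hat <- predict(fit, X[test, , drop = FALSE])
      r_val <- if (sum(test) >= 3 && stats::sd(y[test]) > 0 && stats::sd(y_hat) > 0) {
        stats::cor(y_hat, y[test])
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        repetition = r, fold = f, n_test = sum(test),
        rmse = rmse(y_hat, y[test]), pearson = r_val
      )
    }
  }
  folds <- do.call(rbind, rows)
  structure(list(
    folds = folds,
    summary = c(mean_rmse = mean(folds$rmse),
                sd_rmse = stats::sd(folds$rmse),
                mean_pearson = mean(folds$pearson, na.rm = TRUE),
                sd_pearson = stats::sd(folds$pearson, na.rm = TRUE)),
    L = L, k = k, repetitions = repetitions, base_seed = base_seed
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cv_result> L = %d, %d folds x %d repetitions\n",
              x$L, x$k, x$repetitions))
  cat(sprintf("  RMSE %.2f +/- %.2f mm | r %.3f +/- %.3f\n",
              s["mean_rmse"], s["sd_rmse"], s["mean_pearson"], s["sd_pearson"]))
  invisible(x)
}

#' Select the number of principal motions by cross-validation
#'
#' Evaluates every component count in `L_range` with repeated stratified
#' k-fold cross-validation and returns the count with the smallest mean
#' held-out RMSE; ties break toward the smaller count. The deflation is
#' run once per fold at `max(L_range)` and all intermediate component
#' counts are read off the same path.
#'
#' @inheritParams cross_validate
#' @param L_range Candidate component counts, default 1:10.
#' @return List with `best_L` and `rmse_by_L` (named mean RMSE vector).
#' @export
select_L <- function(dm, L_range = 1:10, k = 10, repetitions = 5,
                     base_seed = 1, variant = "as_printed") {
  L_range <- sort(unique(as.integer(L_range)))
  X <- dm$X; y <- dm$y
  if (is.null(X) || nrow(X) == 0) stopf("input error: empty design matrix")
  L_max <- max(L_range)
  sums <- numeric(length(L_range))
  cnts <- numeric(length(L_range))
  for (r in seq_len(repetitions)) {
    fold <- make_folds(dm$meta %||% nrow(X), k = k, seed = base_seed + r)
    for (f in sort(unique(fold))) {
      test <- fold == f
      if (sum(!test) < 2) {
        stopf("configuration error: fold %d leaves < 2 training samples", f)
      }
      fit <- pma_fit(X[!test, , drop = FALSE], y[!test], L_max, variant = variant)
      path <- pma_path_predict(fit, X[test, , drop = FALSE])
      for (j in seq_along(L_range)) {
        l <- min(L_range[j], fit$L_effective)
        sums[j] <- sums[j] + rmse(path[, l], y[test])
        cnts[j] <- cnts[j] + 1
      }
    }
  }
  rmse_by_L <- stats::setNames(sums / cnts, L_range)
  list(best_L = L_range[which.min(rmse_by_L)], rmse_by_L = rmse_by_L)
}

#' Evaluate all single sites and site pairs
#'
#' Runs [cross_validate()] for every single site and every unordered pair
#' of sites, for one support foot and one MoS direction: S sites yield
#' `S + choose(S, 2)` cells (55 for ten sites). Pairs are keyed once,
#' with `site_a` before `site_b` in the declared site order.
#'
#' @param samples Step samples of a single support foot (see
#'   [step_samples_from_trial()]).
#' @param sites Sites to evaluate (>= 2).
#' @param direction `"anterior"` or `"mediolateral"`.
#' @inheritParams cross_validate
#' @return Object of class `placement_grid`: data frame with one row per
#'   cell (`site_a`, `site_b`, `support_foot`, `direction`, `L`,
#'   `mean_rmse`, `sd_rmse`, `mean_pearson`, `sd_pearson`).
#' @export
placement_grid <- function(samples, sites, direction, L, k = 10,
                           repetitions = 5, base_seed = 1,
                           variant = "as_printed") {
  if (length(sites) < 2) stopf("input error: need at least 2 sites")
  combos <- c(lapply(sites, identity),
              utils::combn(sites, 2, simplify = FALSE))
  rows <- lapply(combos, function(ss) {
    dm <- build_design_matrix(samples, ss, direction)
    cv <- cross_validate(dm, L, k = k, repetitions = repetitions,
                         base_seed = base_seed, variant = variant)
    s <- cv$summary
    data.frame(site_a = ss[1], site_b = ss[length(ss)],
               support_foot = dm$support_foot, direction = direction, L = L,
               mean_rmse = unname(s["mean_rmse"]), sd_rmse = unname(s["sd_rmse"]),
               mean_pearson = unname(s["mean_pearson"]),
               sd_pearson = unname(s["sd_pearson"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("placement_grid", "data.frame")
  out
}

#' Render a placement grid as a triangular text matrix
#'
#' Mirrors the conventional presentation: diagonal cells are single
#' sites, upper-triangular cells are pairs, entries are
#' `mean +/- sd (r)`.
#'
#' @param grid A [placement_grid()] result.
#' @return Character matrix (invisibly printed with [print()]).
#' @export
format_placement_matrix <- function(grid) {
  sites <- unique(c(grid$site_a, grid$site_b))
  m <- matrix("", length(sites), length(sites), dimnames = list(sites, sites))
  for (i in seq_len(nrow(grid))) {
    m[grid$site_a[i], grid$site_b[i]] <-
      sprintf("%.0f±%.0f (%.2f)", grid$mean_rmse[i], grid$sd_rmse[i],
              grid$mean_pearson[i])
  }
  m
}

#' @export
print.placement_grid <- function(x, ...) {
  cat(sprintf("<placement_grid> %d cells | %s MoS, %s support, L = %d\n",
              nrow(x), x$direction[1], x$support_foot[1], x$L[1]))
  print.data.frame(x, ...)
  invisible(x)
}

#' Categorise a MoS value against a reference distribution
#'
#' Descriptive SD bands relative to a reference mean and standard
#' deviation: values at or above `mean - sd` are `typical`; values in
#' `[mean - 2 sd, mean - sd)` are `cautionary`; values below `mean - 2 sd`
#' are `high_risk`. Only low values are flagged, because smaller MoS
#' means higher instability.
#'
#' @param value MoS value(s), mm.
#' @param ref_mean,ref_sd Reference distribution mean and sd, mm;
#'   `ref_sd` must be positive.
#' @return Factor with levels `typical`, `cautionary`, `high_risk`.
#' @export
categorize_mos <- function(value, ref_mean, ref_sd) {
  if (!is.finite(ref_sd) || ref_sd <= 0) {
    stopf("domain error: ref_sd must be positive")
  }
  z <- (value - ref_mean) / ref_sd
  out <- ifelse(z >= -1, "typical", ifelse(z >= -2, "cautionary", "high_risk"))
  factor(out, levels = c("typical", "cautionary", "high_risk"))
}
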