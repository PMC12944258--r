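# Step segmentation, time normalisation, and predictor assembly for the
# IMU-based MoS regression.

IMU_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")

check_imu_recording <- function(rec) {
  need <- c("time_s", IMU_CHANNELS)
  missing <- setdiff(need, names(rec))
  if (length(missing) > 0) {
    stopf("IMU input error: missing column(s): %s", paste(missing, collapse = ", "))
  }
  invisible(rec)
}

resample_window <- function(rec, t0, t1, n_points) {
  inside <- sum(rec$time_s >= t0 & rec$time_s <= t1)
  if (inside < 2) return(NULL)
  xout <- seq(t0, t1, length.out = n_points)
  if (t0 < rec$time_s[1] || t1 > rec$time_s[length(rec$time_s)]) return(NULL)
  out <- matrix(NA_real_, n_points, length(IMU_CHANNELS),
                dimnames = list(NULL, IMU_CHANNELS))
  for (ch in IMU_CHANNELS) {
    out[, ch] <- stats::approx(rec$time_s, rec[[ch]], xout = xout)$y
  }
  out
}

#' Segment an IMU recording into time-normalised step samples
#'
#' For each step opened by a heel contact of the support foot and closed
#' by the opposite foot's contact (0% and 50% of the gait cycle), every
#' channel is linearly interpolated at `n_points` equally spaced
#' normalised times over the closed window. Steps whose window contains
#' fewer than two IMU samples, or that fall outside the recording span,
#' are skipped with a warning.
#'
#' @param rec IMU recording data frame with columns `time_s`, `ax`, `ay`,
#'   `az` (m/s^2) and `gx`, `gy`, `gz` (rad/s) on a uniform time grid.
#' @param events Heel-contact data frame (`time_s`, `foot`), alternating.
#' @param support `"left"` or `"right"`: the support foot whose contacts
#'   open the analysed steps.
#' @param n_points Number of normalised time points per step, default 51.
#' @return List of `n_points` x 6 matrices (channel order ax, ay, az, gx,
#'   gy, gz), one per retained step, each with attributes `t_start` and
#'   `t_end`.
#' @export
segment_and_resample <- function(rec, events, support = c("left", "right"),
                                 n_points = 51) {
  support <- match.arg(support)
  check_imu_recording(rec)
  events <- check_events(events)
  if (n_points < 2) stopf("configuration error: n_points must be >= 2")
  openers <- which(events$foot == support)
  openers <- openers[openers < nrow(events)]
  out <- list()
  for (i in openers) {
    arr <- resample_window(rec, events$time_s[i], events$time_s[i + 1], n_points)
    if (is.null(arr)) {
      warnf("step at t = %.3f s has < 2 IMU samples in window; skipped",
            events$time_s[i])
      next
    }
    attr(arr, "t_start") <- events$time_s[i]
    attr(arr, "t_end") <- events$time_s[i + 1]
    out[[length(out) + 1]] <- arr
  }
  out
}

#' Flatten per-site step arrays into a predictor vector
#'
#' Concatenation order within a site is ax(0..50%), ay, az, gx, gy, gz;
#' sites are concatenated in the declared order. One site yields a
#' length-306 vector (51 points x 6 channels); two sites yield 612.
#'
#' @param arrays Named list of `51 x 6` step matrices, one per site.
#' @param sites Character vector (length 1 or 2) giving the site order.
#' @return Numeric vector of length `306 * length(sites)`.
#' @export
build_predictor_vector <- function(arrays, sites = names(arrays)) {
  if (length(sites) < 1 || length(sites) > 2) {
    stopf("input error: 1 or 2 sites supported, got %d", length(sites))
  }
  missing <- setdiff(sites, names(arrays))
  if (length(missing) > 0) {
    stopf("input error: site(s) not present in step sample: %s",
          paste(missing, collapse = ", "))
  }
  parts <- lapply(sites, function(s) {
    a <- arrays[[s]]
    if (!is.matrix(a) || ncol(a) != 6) {
      stopf("input error: site '%s' array must be an n_points x 6 matrix", s)
    }
    as.vector(a)  # column-major: ax block, then ay, ..., gz
  })
  unlist(parts, use.names = FALSE)
}

#' Reverse of [build_predictor_vector()]
#'
#' @param x Flat predictor vector.
#' @param sites Site labels in concatenation order.
#' @param n_points Points per step (default 51).
#' @return Named list of `n_points x 6` matrices.
#' @export
unflatten_predictor_vector <- function(x, sites, n_points = 51) {
  block <- n_points * 6
  if (length(x) != block * length(sites)) {
    stopf("input error: vector length %d does not match %d site(s) x %d",
          length(x), length(sites), block)
  }
  out <- lapply(seq_along(sites), function(i) {
    matrix(x[((i - 1) * block + 1):(i * block)], n_points, 6,
           dimnames = list(NULL, IMU_CHANNELS))
  })
  names(out) <- sites
  out
}

#' Extract labelled step samples from a synthetic trial
#'
#' Convenience bridge between the gait generator and the featurisation
#' stage: for each ground-truth step of the requested support foot, the
#' per-site IMU channels are resampled over the step window and paired
#' with the stored per-step minimum MoS labels.
#'
#' @param trial A trial from [generate_gait_trial()].
#' @param sites Sites to retain (default: all sites in the trial).
#' @param support `"left"` or `"right"`.
#' @param n_points Points per step, default 51.
#' @return List of step samples; each is a list with `participant`,
#'   `speed_kmh`, `support_foot`, `step_index`, `arrays` (named list of
#'   51 x 6 matrices) and `labels` (named vector, mm, elements `anterior`
#'   and `mediolateral`).
#' @export
step_samples_from_trial <- function(trial, sites = names(trial$imu),
                                    support = c("left", "right"),
                                    n_points = 51) {
  support <- match.arg(support)
  missing <- setdiff(sites, names(trial$imu))
  if (length(missing) > 0) {
    stopf("input error: site(s) not in trial: %s", paste(missing, collapse = ", "))
  }
  truth <- trial$truth[trial$truth$support_foot == support, , drop = FALSE]
  out <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    arrays <- lapply(trial$imu[sites], resample_window,
                     t0 = truth$t_start[i], t1 = truth$t_end[i],
                     n_points = n_points)
    if (any(vapply(arrays, is.null, logical(1)))) {
      warnf("step %d window not covered by IMU recording; skipped", i)
      next
    }
    out[[i]] <- list(
      participant = truth$participant[i],
      speed_kmh = truth$speed_kmh[i],
      support_foot = support,
      step_index = truth$step_index[i],
      arrays = arrays,
      labels = c(anterior = truth$min_anterior_mos_mm[i],
                 mediolateral = truth$min_mediolateral_mos_mm[i])
    )
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Assemble the design matrix for one support foot and MoS direction
#'
#' Rows are flattened step predictor vectors (306 columns per site);
#' the response is the per-step minimum MoS in the chosen direction, in
#' millimetres. Left- and right-support steps are analysed separately and
#' must never be mixed.
#'
#' @param samples List of step samples (see
#'   [step_samples_from_trial()]).
#' @param sites Character vector of 1 or 2 site labels.
#' @param direction `"anterior"` or `"mediolateral"`.
#' @return Object of class `design_matrix`: list with `X` (n x 306S
#'   matrix), `y` (mm), `meta` (data frame: participant, speed_kmh,
#'   support_foot, step_index), `sites`, `direction`, `support_foot`.
#' @export
build_design_matrix <- function(samples, sites,
                                direction = c("anterior", "mediolateral")) {
  direction <- match.arg(direction)
  if (length(samples) == 0) stopf("input error: no step samples supplied")
  feet <- unique(vapply(samples, `[[`, character(1), "support_foot"))
  if (length(feet) > 1) {
    stopf("input error: left- and right-support steps must not be mixed (got %s)",
          paste(feet, collapse = ", "))
  }
  X <- t(vapply(samples, function(s) build_predictor_vector(s$arrays, sites),
                numeric(51 * 6 * length(sites))))
  y <- vapply(samples, function(s) unname(s$labels[[direction]]), numeric(1))
  meta <- data.frame(
    participant = vapply(samples, function(s) as.character(s$participant), character(1)),
    speed_kmh = vapply(samples, function(s) as.numeric(s$speed_kmh), numeric(1)),
    support_foot = feet,
    step_index = vapply(samples, function(s) as.integer(s$step_index), integer(1)),
    stringsAsFactors = FALSE
  )
  structure(list(X = X, y = y, meta = meta, sites = sites,
                 direction = direction, support_foot = feet),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d steps x %d predictors | sites: %s | %s MoS, %s support\n",
              nrow(x$X), ncol(x$X), paste(x$sites, collapse = " + "),
              x$direction, x$support_foot))
  invisible(x)
}
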