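# Reference margin-of-stability computation from optical marker data.
#
# Marker frames use the lab coordinate convention fixed throughout the
# package: x mediolateral (+right), y anterior, z vertical up with z = 0 at
# the belt surface. Four markers are expected: left/right anterior superior
# iliac spine (ASIS_L, ASIS_R) and left/right forefoot (TOE_L, TOE_R,
# placed over the second/third metatarsal heads).

MARKER_NAMES <- c("ASIS_L", "ASIS_R", "TOE_L", "TOE_R")

marker_columns <- function() {
  as.vector(vapply(MARKER_NAMES, function(m) paste(m, c("x", "y", "z"), sep = "_"),
                   character(3)))
}

check_marker_series <- function(markers) {
  need <- c("time_s", marker_columns())
  missing <- setdiff(need, names(markers))
  if (length(missing) > 0) {
    stopf("marker input error: missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  invisible(markers)
}

#' Approximate the centre of mass from the ASIS markers
#'
#' The body centre of mass (CoM) is approximated as the pointwise midpoint
#' of the left and right anterior superior iliac spine markers, a standard
#' pelvis-level approximation of the whole-body CoM.
#'
#' @param markers Marker data frame with columns `time_s`,
#'   `ASIS_L_{x,y,z}`, `ASIS_R_{x,y,z}` (and usually the toe markers), in
#'   metres, lab frame.
#' @return Data frame with columns `time_s`, `x`, `y`, `z`: the CoM
#'   trajectory in metres.
#' @export
com_from_asis <- function(markers) {
  need <- c("time_s", paste0("ASIS_L_", c("x", "y", "z")),
            paste0("ASIS_R_", c("x", "y", "z")))
  missing <- setdiff(need, names(markers))
  if (length(missing) > 0) {
    stopf("marker input error: missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  data.frame(
    time_s = markers$time_s,
    x = (markers$ASIS_L_x + markers$ASIS_R_x) / 2,
    y = (markers$ASIS_L_y + markers$ASIS_R_y) / 2,
    z = (markers$ASIS_L_z + markers$ASIS_R_z) / 2
  )
}

#' Differentiate a trajectory by central finite differences
#'
#' Interior samples use the second-order central difference
#' `(x[i+1] - x[i-1]) / (2 dt)`; the first and last samples use one-sided
#' differences. Exact for position series that are polynomials of degree
#' two or less. No smoothing is applied.
#'
#' @param x Numeric vector or matrix (columns differentiated
#'   independently).
#' @param dt Sampling interval in seconds (uniform grid).
#' @return Object of the same shape as `x` containing velocities.
#' @export
finite_difference <- function(x, dt) {
  if (is.matrix(x) || is.data.frame(x)) {
    return(apply(as.matrix(x), 2, finite_difference, dt = dt))
  }
  n <- length(x)
  if (n < 3) stopf("input error: need at least 3 samples to differentiate")
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  v
}

#' Horizontal CoM velocity
#'
#' @param com CoM trajectory as returned by [com_from_asis()].
#' @param dt Sampling interval in seconds.
#' @return Data frame with columns `vx`, `vy` (m/s).
#' @export
com_velocity <- function(com, dt) {
  data.frame(vx = finite_difference(com$x, dt),
             vy = finite_difference(com$y, dt))
}

#' Natural frequency of the inverted-pendulum model
#'
#' `omega = sqrt(g / l)` where `l` is the distance from the CoM to the
#' ground.
#'
#' @param l CoM height above the ground in metres; must be positive.
#' @param g Gravitational acceleration, default 9.81 m/s^2.
#' @return Natural frequency in rad/s.
#' @examples
#' natural_frequency(9.81)  # 1
#' @export
natural_frequency <- function(l, g = 9.81) {
  if (any(!is.finite(l)) || any(l <= 0)) {
    stopf("domain error: CoM height l must be positive")
  }
  sqrt(g / l)
}

#' Extrapolated centre of mass (XCoM)
#'
#' The XCoM advances the horizontal CoM position by the CoM velocity
#' scaled by the inverted-pendulum natural frequency:
#' `xcom + (v + (0, belt)) / omega`. On a treadmill the belt speed is added
#' to the anterior (y) velocity component before extrapolation.
#'
#' @param x_com n x 2 matrix (or length-2 vector) of horizontal CoM
#'   positions, columns (x, y) in metres.
#' @param v_com Matching horizontal CoM velocities in m/s.
#' @param omega Natural frequency in rad/s, positive.
#' @param belt_speed_ms Treadmill belt speed in m/s (>= 0), default 0.
#' @return n x 2 matrix of XCoM positions.
#' @export
extrapolated_com <- function(x_com, v_com, omega, belt_speed_ms = 0) {
  if (!is.finite(omega) || omega <= 0) {
    stopf("domain error: omega must be positive")
  }
  if (belt_speed_ms < 0) stopf("domain error: belt speed must be >= 0")
  x_com <- rbind_vec2(x_com)
  v_com <- rbind_vec2(v_com)
  v_com[, 2] <- v_com[, 2] + belt_speed_ms
  x_com + v_com / omega
}

rbind_vec2 <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != 2) stopf("input error: expected 2 horizontal components")
  x
}

#' Anterior margin of stability
#'
#' Signed difference between the anterior base-of-support boundary and the
#' anterior XCoM component. Positive values mean the XCoM lies within the
#' anterior BoS boundary (stable); negative values mean forward balance is
#' compromised.
#'
#' @param bos_y Anterior BoS boundary position (m).
#' @param xxcom_y Anterior XCoM component (m).
#' @return Signed margin in metres.
#' @export
anterior_mos <- function(bos_y, xxcom_y) {
  bos_y - xxcom_y
}

#' Mediolateral margin of stability
#'
#' Absolute distance between the mediolateral BoS and XCoM components, so
#' left- and right-side margins are treated equivalently. Smaller values
#' mean reduced mediolateral stability.
#'
#' @param bos_x Mediolateral BoS position (m).
#' @param xxcom_x Mediolateral XCoM component (m).
#' @return Non-negative margin in metres.
#' @export
mediolateral_mos <- function(bos_x, xxcom_x) {
  abs(bos_x - xxcom_x)
}

#' Detect heel-contact events from forefoot marker trajectories
#'
#' On a treadmill the stance foot travels backwards with the belt, so each
#' heel contact coincides with a local maximum of the forefoot (toe)
#' marker's anterior (y) coordinate in the lab frame. Per foot, local
#' maxima separated by at least `refractory_s` are kept (highest first);
#' the two feet are then merged, sorted by time, and strict left/right
#' alternation is enforced.
#'
#' @param markers Marker data frame (see [com_from_asis()]) including
#'   `TOE_L_*` and `TOE_R_*` columns.
#' @param refractory_s Minimum separation between same-foot contacts in
#'   seconds, default 0.3.
#' @return Data frame with columns `time_s` and `foot`
#'   (`"left"`/`"right"`), strictly increasing in time and alternating in
#'   foot.
#' @export
detect_heel_contacts <- function(markers, refractory_s = 0.3) {
  check_marker_series(markers)
  t <- markers$time_s
  if (length(t) < 3) stopf("detection error: too few samples")
  one_foot <- function(y, foot) {
    n <- length(y)
    cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
    if (length(cand) == 0) {
      stopf("detection error: no heel-contact maxima found for %s toe marker (constant or monotone trajectory?)", foot)
    }
    keep <- integer(0)
    for (i in cand[order(y[cand], decreasing = TRUE)]) {
      if (all(abs(t[i] - t[keep]) >= refractory_s)) keep <- c(keep, i)
    }
    keep <- sort(keep)
    data.frame(time_s = t[keep], foot = foot, stringsAsFactors = FALSE)
  }
  ev <- rbind(one_foot(markers$TOE_L_y, "left"),
              one_foot(markers$TOE_R_y, "right"))
  ev <- ev[order(ev$time_s), , drop = FALSE]
  rownames(ev) <- NULL
  same <- which(ev$foot[-1] == ev$foot[-nrow(ev)])
  if (length(same) > 0) {
    stopf("detection error: feet do not alternate (consecutive %s contacts at t = %.3f s and t = %.3f s)",
          ev$foot[same[1]], ev$time_s[same[1]], ev$time_s[same[1] + 1])
  }
  check_events(ev)
}

check_events <- function(events) {
  need <- c("time_s", "foot")
  missing <- setdiff(need, names(events))
  if (length(missing) > 0) {
    stopf("event input error: missing column(s): %s", paste(missing, collapse = ", "))
  }
  if (!all(events$foot %in% c("left", "right"))) {
    stopf("event input error: foot must be 'left' or 'right'")
  }
  if (is.unsorted(events$time_s, strictly = TRUE)) {
    stopf("event input error: event times must be strictly increasing")
  }
  events
}

#' Frame-by-frame margin-of-stability series
#'
#' Assembles the anterior and mediolateral MoS at every marker frame from
#' the heel contact sequence. At each frame the support foot is the foot
#' of the most recent heel contact; the BoS boundary is that foot's toe
#' marker horizontal position. The pendulum length `l` is the trial-mean
#' vertical CoM coordinate, so `omega` is constant within a trial. Frames
#' before the first heel contact are excluded.
#'
#' @param markers Marker data frame (see [com_from_asis()]).
#' @param events Heel-contact data frame (`time_s`, `foot`), supplied or
#'   from [detect_heel_contacts()].
#' @param belt_speed_ms Belt speed in m/s, added to the anterior CoM
#'   velocity before extrapolation. Default 0.
#' @param g Gravitational acceleration (m/s^2).
#' @return Data frame with columns `time_s`, `support_foot`, `anterior_m`
#'   (signed) and `mediolateral_m` (non-negative), on the marker time grid
#'   from the first event onwards.
#' @export
mos_series <- function(markers, events, belt_speed_ms = 0, g = 9.81) {
  check_marker_series(markers)
  events <- check_events(events)
  t <- markers$time_s
  dt <- t[2] - t[1]
  com <- com_from_asis(markers)
  vel <- com_velocity(com, dt)
  l <- mean(com$z)
  omega <- natural_frequency(l, g)
  xx <- extrapolated_com(cbind(com$x, com$y), cbind(vel$vx, vel$vy),
                         omega, belt_speed_ms)
  idx <- findInterval(t, events$time_s)
  keep <- idx >= 1L
  idx <- idx[keep]
  support <- events$foot[idx]
  right <- support == "right"
  bos_x <- ifelse(right, markers$TOE_R_x[keep], markers$TOE_L_x[keep])
  bos_y <- ifelse(right, markers$TOE_R_y[keep], markers$TOE_L_y[keep])
  data.frame(
    time_s = t[keep],
    support_foot = support,
    anterior_m = anterior_mos(bos_y, xx[keep, 2]),
    mediolateral_m = mediolateral_mos(bos_x, xx[keep, 1]),
    stringsAsFactors = FALSE
  )
}

#' Per-step minimum margin of stability
#'
#' A step runs from one foot's heel contact to the opposite foot's heel
#' contact; the step label is the minimum MoS within that interval, taken
#' independently for the anterior and mediolateral directions. The support
#' foot of a step is the foot of the opening heel contact. Frames with
#' `t_open <= t < t_close` belong to the step. Output minima are reported
#' in millimetres, the conventional reporting unit.
#'
#' @param series MoS series from [mos_series()].
#' @param events Heel-contact data frame with at least two events.
#' @param participant,speed_kmh Optional identifiers copied into the
#'   output.
#' @return Data frame with one row per step: `participant`, `speed_kmh`,
#'   `support_foot`, `step_index` (per foot), `t_start`, `t_end`,
#'   `min_anterior_mos_mm`, `min_mediolateral_mos_mm`.
#' @export
min_mos_per_step <- function(series, events, participant = NA, speed_kmh = NA) {
  events <- check_events(events)
  if (nrow(events) < 2) stopf("input error: need at least 2 heel-contact events")
  out <- vector("list", nrow(events) - 1)
  counts <- c(left = 0L, right = 0L)
  for (i in seq_len(nrow(events) - 1)) {
    t0 <- events$time_s[i]
    t1 <- events$time_s[i + 1]
    sel <- series$time_s >= t0 & series$time_s < t1
    if (!any(sel)) {
      warnf("step opened at t = %.3f s contains no frames; skipped", t0)
      next
    }
    foot <- events$foot[i]
    counts[foot] <- counts[foot] + 1L
    out[[i]] <- data.frame(
      participant = participant,
      speed_kmh = speed_kmh,
      support_foot = foot,
      step_index = counts[[foot]],
      t_start = t0,
      t_end = t1,
      min_anterior_mos_mm = 1000 * min(series$anterior_m[sel]),
      min_mediolateral_mos_mm = 1000 * min(series$mediolateral_m[sel]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
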