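# Synthetic treadmill gait generator with analytically known per-step
# minimum MoS, plus a pure latent-linear generator matching the PMA model
# class. Both stand in for treadmill recordings when validating the
# marker -> MoS -> IMU-regression pipeline.

#' Canonical IMU site labels
#'
#' The ten body locations used throughout: xiphisternum, sacral crest,
#' bilateral knees, thighs and insteps, left wrist and skull vertex.
#'
#' @return Character vector of ten site labels.
#' @export
imu_sites <- function() {
  c("xiphisternum", "sacral_crest", "right_knee", "left_knee",
    "right_thigh", "left_thigh", "right_instep", "left_instep",
    "left_wrist", "skull_vertex")
}

# How strongly each site loads on the MoS-coupled latent waveforms.
# Lower-limb and sacral sites carry the gait-mechanical information;
# the wrist and skull carry none (arm swing / head motion are modelled
# as uninformative for stability).
site_mos_weight <- function(site) {
  w <- c(xiphisternum = 0.4, sacral_crest = 1, right_knee = 1, left_knee = 1,
         right_thigh = 1, left_thigh = 1, right_instep = 1, left_instep = 1,
         left_wrist = 0, skull_vertex = 0)
  out <- w[site]
  out[is.na(out)] <- 1
  unname(out)
}

#' Configuration for the synthetic gait generator
#'
#' Defaults reproduce the study conditions the package emulates: eight
#' participants walking at 2.5/3.0/3.5 km/h, 60 left-stance and 60
#' right-stance steps per participant per speed retained after a 60 s
#' warm-up is discarded, markers at 200 Hz and ten 6-axis IMUs at 100 Hz.
#'
#' @param n_participants Number of participants (default 8).
#' @param speeds_kmh Belt speeds in km/h (default 2.5, 3.0, 3.5).
#' @param steps_per_foot_per_speed Retained steps per support foot per
#'   speed (default 60).
#' @param step_frequency_hz Cadence (steps/s) per speed; recycled to the
#'   length of `speeds_kmh`. Default 1.6/1.7/1.8 Hz.
#' @param step_width_m Lateral toe-marker separation (m), default 0.23.
#' @param sway_amplitude_m Lateral CoM oscillation amplitude (m), default
#'   0.02.
#' @param com_height_m Mean CoM height above the belt (m), default 0.95.
#' @param marker_rate_hz Marker sampling rate, default 200.
#' @param imu_rate_hz IMU sampling rate, default 100.
#' @param sites IMU site labels, default [imu_sites()].
#' @param n_latent Number of latent waveforms mixed into the IMU
#'   channels: latent 1 drives anterior MoS variation, latent 2 (if
#'   present) mediolateral variation, the rest are uninformative
#'   nuisance synergies. Default 3.
#' @param noise_sd_accel,noise_sd_gyro IMU sensor noise sd (m/s^2,
#'   rad/s).
#' @param warmup_s Warm-up duration generated and discarded (first-minute
#'   exclusion), default 60 s.
#' @param step_reach_sd_m Per-step sd of the toe anterior position at
#'   heel contact (drives anterior MoS variability), default 0.012 m.
#' @param step_width_sd_m Per-step sd of lateral foot placement (drives
#'   mediolateral MoS variability), default 0.008 m.
#' @param seed Integer base seed; each (participant, speed) trial uses an
#'   independent stream derived from it.
#' @return List of class `gait_sim_config`.
#' @export
gait_sim_config <- function(n_participants = 8,
                            speeds_kmh = c(2.5, 3.0, 3.5),
                            steps_per_foot_per_speed = 60,
                            step_frequency_hz = c(1.6, 1.7, 1.8),
                            step_width_m = 0.23,
                            sway_amplitude_m = 0.02,
                            com_height_m = 0.95,
                            marker_rate_hz = 200,
                            imu_rate_hz = 100,
                            sites = imu_sites(),
                            n_latent = 3,
                            noise_sd_accel = 0.05,
                            noise_sd_gyro = 0.02,
                            warmup_s = 60,
                            step_reach_sd_m = 0.012,
                            step_width_sd_m = 0.008,
                            seed = 1L) {
  if (any(speeds_kmh <= 0)) stopf("configuration error: speeds must be positive")
  if (marker_rate_hz <= 0 || imu_rate_hz <= 0) {
    stopf("configuration error: sampling rates must be positive")
  }
  if (steps_per_foot_per_speed < 1) {
    stopf("configuration error: steps_per_foot_per_speed must be >= 1")
  }
  if (n_latent < 1) stopf("configuration error: n_latent must be >= 1")
  if (com_height_m <= 0) stopf("configuration error: com_height_m must be positive")
  structure(list(
    n_participants = n_participants,
    speeds_kmh = speeds_kmh,
    steps_per_foot_per_speed = steps_per_foot_per_speed,
    step_frequency_hz = rep_len(step_frequency_hz, length(speeds_kmh)),
    step_width_m = step_width_m,
    sway_amplitude_m = sway_amplitude_m,
    com_height_m = com_height_m,
    marker_rate_hz = marker_rate_hz,
    imu_rate_hz = imu_rate_hz,
    sites = sites,
    n_latent = n_latent,
    noise_sd_accel = noise_sd_accel,
    noise_sd_gyro = noise_sd_gyro,
    warmup_s = warmup_s,
    step_reach_sd_m = step_reach_sd_m,
    step_width_sd_m = step_width_sd_m,
    seed = as.integer(seed)
  ), class = "gait_sim_config")
}

# Latent waveforms over normalised step phase in [0, 1]. Latent 1 drives
# anterior MoS, latent 2 mediolateral, >= 3 are nuisance synergies.
latent_waveform <- function(j, phase) {
  if (j == 1) sin(pi * phase + 0.4)
  else if (j == 2) cos(pi * phase)
  else sin(2 * pi * (j - 2) * phase + (j - 2))
}

#' Generate one synthetic treadmill trial
#'
#' The CoM follows an inverted-pendulum-flavoured model: constant height,
#' a lateral sinusoid at stride frequency phased so the body sways toward
#' the support side, and a small anterior bounce at step frequency that
#' vanishes at heel contacts. Toe markers alternate rectangular-pulse
#' stepping consistent with the belt: during stance a toe travels
#' backwards at belt speed from a per-step randomised reach, during swing
#' it returns forward. IMU channels are a step-phase-locked baseline plus
#' linear mixtures of `n_latent` latent waveforms whose per-step scores
#' include the (standardised) step-to-step MoS drivers, plus Gaussian
#' sensor noise; skull and wrist sites carry zero loading on the
#' MoS-coupled latents.
#'
#' The stored ground-truth per-step minimum MoS is computed from the
#' noiseless marker model on the sampling grid using the package's stated
#' conventions (central-difference velocity, trial-mean CoM height,
#' frames from opening to closing contact), by direct evaluation
#' independent of the [mos_series()] code path.
#'
#' @param config A [gait_sim_config()].
#' @param participant Participant identifier (integer).
#' @param speed_kmh One of `config$speeds_kmh`.
#' @return Object of class `gait_trial`: list with `markers` (data
#'   frame), `imu` (named list of per-site data frames), `events`
#'   (heel-contact data frame bounding the retained steps), `truth` (one
#'   row per retained step: identifiers, window, minimum anterior and
#'   mediolateral MoS in mm, latent scores), `belt_speed_ms`,
#'   `participant`, `speed_kmh` and `config`.
#' @export
generate_gait_trial <- function(config, participant = 1, speed_kmh = config$speeds_kmh[1]) {
  speed_idx <- match(speed_kmh, config$speeds_kmh)
  if (is.na(speed_idx)) {
    stopf("input error: speed %.2f km/h not in config speeds (%s)",
          speed_kmh, paste(config$speeds_kmh, collapse = ", "))
  }
  f_step <- config$step_frequency_hz[speed_idx]
  T_stride <- 2 / f_step
  half <- T_stride / 2
  belt <- kmh_to_ms(speed_kmh)
  dt_m <- 1 / config$marker_rate_hz
  if (half < 4 * dt_m) {
    stopf("configuration error: step period (%.3f s) shorter than 4 marker samples", half)
  }
  omega <- sqrt(9.81 / config$com_height_m)
  N <- config$steps_per_foot_per_speed
  t0 <- 0.4
  # per-speed toe reach calibrated so the mean minimum anterior MoS
  # follows the reference distribution's speed trend (~40 mm at 2.5 km/h
  # falling ~56 mm per km/h)
  target_anterior <- (40.4 - 55.8 * (speed_kmh - 2.5)) / 1000
  base_reach <- target_anterior + belt / omega + belt * half

  # contact schedule: right foot at t0 + k T, left at t0 + T/2 + k T
  K <- ceiling((config$warmup_s + (N + 2) * T_stride) / T_stride) + 2
  t_right <- t0 + (0:K) * T_stride
  t_left <- t0 + half + (0:K) * T_stride

  seed <- trial_seed(config$seed, participant, speed_idx)
  trial <- with_local_seed(seed, {
    d_right <- stats::rnorm(K + 1, 0, config$step_reach_sd_m)
    d_left <- stats::rnorm(K + 1, 0, config$step_reach_sd_m)
    e_right <- stats::rnorm(K + 1, 0, config$step_width_sd_m)
    e_left <- stats::rnorm(K + 1, 0, config$step_width_sd_m)

    contacts <- rbind(
      data.frame(time_s = t_right, foot = "right", reach = base_reach + d_right,
                 lat = config$step_width_m / 2 + e_right,
                 delta = d_right, eta = e_right, stringsAsFactors = FALSE),
      data.frame(time_s = t_left, foot = "left", reach = base_reach + d_left,
                 lat = -config$step_width_m / 2 + e_left,
                 delta = d_left, eta = e_left, stringsAsFactors = FALSE)
    )
    contacts <- contacts[order(contacts$time_s), , drop = FALSE]
    rownames(contacts) <- NULL
    nC <- nrow(contacts)

    # nuisance latent scores, one per inter-contact interval
    n_nuis <- max(0, config$n_latent - 2)
    nuis <- if (n_nuis > 0) {
      matrix(stats::rnorm(nC * n_nuis), nC, n_nuis)
    } else matrix(0, nC, 0)

    # retained steps: first 2N contacts at or after the warm-up
    i0 <- which(contacts$time_s >= config$warmup_s)[1]
    if (is.na(i0) || i0 + 2 * N > nC) {
      stopf("configuration error: contact schedule too short for requested steps")
    }
    openers <- i0:(i0 + 2 * N - 1)
    ev <- contacts[i0:(i0 + 2 * N), c("time_s", "foot")]
    rownames(ev) <- NULL

    trim0 <- max(0, contacts$time_s[i0] - 1.0)
    trim1 <- contacts$time_s[i0 + 2 * N] + 0.5
    t_m <- seq(0, trim1 + dt_m, by = dt_m)
    t_m <- t_m[t_m >= trim0 & t_m <= trim1]

    # ---- CoM model (lateral sway phased so xxcom_x peaks mid right stance,
    # anterior bounce phased so its XCoM contribution vanishes at contacts)
    r_lat <- (2 * pi / T_stride) / omega
    r_ant <- (2 * pi * f_step) / omega
    b_ant <- 0.01
    com_xy <- function(t) {
      list(
        x = config$sway_amplitude_m * sin(2 * pi * (t - t0) / T_stride - atan(r_lat)),
        y = b_ant * sin(2 * pi * f_step * (t - t0) - atan(r_ant))
      )
    }
    com <- com_xy(t_m)

    # ---- toe trajectories: piecewise linear per foot
    toe_track <- function(times, reach, lat) {
      duty <- 0.6
      D <- duty * T_stride
      yk <- stats::approx(
        x = as.vector(rbind(times, times + D)),
        y = as.vector(rbind(reach, reach - belt * D)),
        xout = t_m, rule = 2)$y
      xk <- stats::approx(
        x = as.vector(rbind(times, times + D)),
        y = as.vector(rbind(lat, lat)),
        xout = t_m, rule = 2)$y
      list(y = yk, x = xk)
    }
    right_c <- contacts[contacts$foot == "right", ]
    left_c <- contacts[contacts$foot == "left", ]
    toe_r <- toe_track(right_c$time_s, right_c$reach, right_c$lat)
    toe_l <- toe_track(left_c$time_s, left_c$reach, left_c$lat)

    pelvis_half <- 0.12
    markers <- data.frame(
      time_s = t_m,
      ASIS_L_x = com$x - pelvis_half, ASIS_L_y = com$y, ASIS_L_z = config$com_height_m,
      ASIS_R_x = com$x + pelvis_half, ASIS_R_y = com$y, ASIS_R_z = config$com_height_m,
      TOE_L_x = toe_l$x, TOE_L_y = toe_l$y, TOE_L_z = 0.02,
      TOE_R_x = toe_r$x, TOE_R_y = toe_r$y, TOE_R_z = 0.02
    )

    # ---- ground-truth MoS on the marker grid (direct evaluation,
    # independent of the mos_series() code path)
    cx <- com$x
    cy <- com$y
    nm <- length(t_m)
    vx <- c((cx[2] - cx[1]) / dt_m,
            (cx[3:nm] - cx[1:(nm - 2)]) / (2 * dt_m),
            (cx[nm] - cx[nm - 1]) / dt_m)
    vy <- c((cy[2] - cy[1]) / dt_m,
            (cy[3:nm] - cy[1:(nm - 2)]) / (2 * dt_m),
            (cy[nm] - cy[nm - 1]) / dt_m)
    xx_x <- cx + vx / omega
    xx_y <- cy + (vy + belt) / omega

    counts <- c(left = 0L, right = 0L)
    truth <- vector("list", length(openers))
    for (m in seq_along(openers)) {
      i <- openers[m]
      tA <- contacts$time_s[i]; tB <- contacts$time_s[i + 1]
      sel <- t_m >= tA & t_m < tB
      foot <- contacts$foot[i]
      counts[foot] <- counts[foot] + 1L
      bos_y <- if (foot == "right") toe_r$y[sel] else toe_l$y[sel]
      bos_x <- if (foot == "right") toe_r$x[sel] else toe_l$x[sel]
      s1 <- if (config$step_reach_sd_m > 0) contacts$delta[i] / config$step_reach_sd_m else 0
      s2 <- if (config$step_width_sd_m > 0) contacts$eta[i] / config$step_width_sd_m else 0
      scores <- c(s1, if (config$n_latent >= 2) s2,
                  if (ncol(nuis) > 0) nuis[i, ])
      truth[[m]] <- data.frame(
        participant = participant, speed_kmh = speed_kmh,
        support_foot = foot, step_index = counts[[foot]],
        t_start = tA, t_end = tB,
        min_anterior_mos_mm = 1000 * min(bos_y - xx_y[sel]),
        min_mediolateral_mos_mm = 1000 * min(abs(bos_x - xx_x[sel])),
        t(stats::setNames(scores, paste0("score_", seq_along(scores)))),
        stringsAsFactors = FALSE
      )
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL

    # ---- IMU signals
    dt_i <- 1 / config$imu_rate_hz
    t_i <- seq(0, trim1 + dt_i, by = dt_i)
    t_i <- t_i[t_i >= trim0 & t_i <= trim1]
    ni <- length(t_i)
    iv <- findInterval(t_i, contacts$time_s)
    in_step <- iv >= 1L & iv < nC
    phase <- numeric(ni)
    phase[in_step] <- (t_i[in_step] - contacts$time_s[iv[in_step]]) /
      (contacts$time_s[iv[in_step] + 1] - contacts$time_s[iv[in_step]])
    J <- config$n_latent
    G <- matrix(0, ni, J)
    S <- matrix(0, ni, J)
    for (j in seq_len(J)) {
      G[, j] <- latent_waveform(j, phase)
      sj <- if (j == 1) {
        if (config$step_reach_sd_m > 0) contacts$delta / config$step_reach_sd_m else numeric(nC)
      } else if (j == 2) {
        if (config$step_width_sd_m > 0) contacts$eta / config$step_width_sd_m else numeric(nC)
      } else {
        nuis[, j - 2]
      }
      S[in_step, j] <- sj[iv[in_step]]
    }
    G[!in_step, ] <- 0
    latent_ts <- G * S  # ni x J latent signal values

    ch_scale <- c(1, 1, 1, 0.5, 0.5, 0.5)
    noise_sd <- c(rep(config$noise_sd_accel, 3), rep(config$noise_sd_gyro, 3))
    imu <- stats::setNames(vector("list", length(config$sites)), config$sites)
    for (site in config$sites) {
      amp0 <- stats::runif(6, 0.5, 1.5) * ch_scale
      ph0 <- stats::runif(6, 0, 2 * pi)
      wgt <- rep(1, J)
      if (J >= 1) wgt[1] <- site_mos_weight(site)
      if (J >= 2) wgt[2] <- site_mos_weight(site)
      M <- matrix(stats::rnorm(J * 6), J, 6) * (0.8 * rep(ch_scale, each = J)) * wgt
      base <- outer(t_i, rep(1, 6))
      for (ch in 1:6) base[, ch] <- amp0[ch] * sin(2 * pi * f_step * t_i + ph0[ch])
      sig <- base + latent_ts %*% M +
        matrix(stats::rnorm(ni * 6), ni, 6) %*% diag(noise_sd)
      colnames(sig) <- IMU_CHANNELS
      imu[[site]] <- data.frame(time_s = t_i, sig)
    }

    list(markers = markers, imu = imu, events = ev, truth = truth)
  })

  structure(c(trial, list(belt_speed_ms = belt, participant = participant,
                          speed_kmh = speed_kmh, config = config)),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> participant %s at %.1f km/h | %d steps (%d/foot), %d sites\n",
              x$participant, x$speed_kmh, nrow(x$truth),
              sum(x$truth$support_foot == "left"), length(x$imu)))
  cat(sprintf("  markers: %d frames @ %g Hz | IMU: %d samples @ %g Hz\n",
              nrow(x$markers), x$config$marker_rate_hz,
              nrow(x$imu[[1]]), x$config$imu_rate_hz))
  invisible(x)
}

#' Specification for the latent-linear generator
#'
#' Draws data from the exact model class the PMA estimator assumes:
#' `X = C P' + E`, `y = C b + e`, with latent scores `C` having
#' independent standard-normal columns.
#'
#' @param n_samples Number of samples.
#' @param dim Predictor length (default 306, one sensor's flattened step).
#' @param n_latent True number of latent components.
#' @param loading_matrix Optional `dim x n_latent` loading matrix
#'   (columns must be linearly independent); drawn standard-normal if
#'   omitted.
#' @param coeffs Per-latent regression weights, default
#'   `n_latent:1 + 1` scaled so the signal clearly dominates unit
#'   response noise.
#' @param noise_sd_x Entrywise sd of `E`, default 0.1.
#' @param noise_sd_y Sd of `e`, default 1.
#' @param seed Integer seed.
#' @return List of class `latent_linear_spec`.
#' @export
latent_linear_spec <- function(n_samples = 480, dim = 306, n_latent = 3,
                               loading_matrix = NULL, coeffs = NULL,
                               noise_sd_x = 0.1, noise_sd_y = 1, seed = 1L) {
  if (n_latent < 1) stopf("configuration error: n_latent must be >= 1")
  if (dim < n_latent) stopf("configuration error: dim must be >= n_latent")
  if (!is.null(loading_matrix)) {
    loading_matrix <- as.matrix(loading_matrix)
    if (!all(dim(loading_matrix) == c(dim, n_latent))) {
      stopf("configuration error: loading_matrix must be %d x %d", dim, n_latent)
    }
    if (qr(loading_matrix)$rank < n_latent) {
      stopf("configuration error: loading columns must be linearly independent")
    }
  }
  coeffs <- coeffs %||% (n_latent:1 + 1)
  if (length(coeffs) != n_latent) {
    stopf("configuration error: coeffs must have length n_latent")
  }
  structure(list(n_samples = n_samples, dim = dim, n_latent = n_latent,
                 loading_matrix = loading_matrix, coeffs = coeffs,
                 noise_sd_x = noise_sd_x, noise_sd_y = noise_sd_y,
                 seed = as.integer(seed)),
            class = "latent_linear_spec")
}

#' Generate a latent-linear dataset
#'
#' @param spec A [latent_linear_spec()].
#' @return List with `X` (n x dim), `y` (length n) and `truth` (list with
#'   the drawn `C`, `P`, `b`).
#' @export
generate_latent_dataset <- function(spec) {
  with_local_seed(spec$seed, {
    n <- spec$n_samples
    d <- spec$dim
    L <- spec$n_latent
    C <- matrix(stats::rnorm(n * L), n, L)
    P <- spec$loading_matrix %||% matrix(stats::rnorm(d * L), d, L)
    if (qr(P)$rank < L) stopf("configuration error: degenerate loading matrix drawn")
    X <- tcrossprod(C, P)
    if (spec$noise_sd_x > 0) {
      X <- X + matrix(stats::rnorm(n * d, 0, spec$noise_sd_x), n, d)
    }
    y <- as.vector(C %*% spec$coeffs)
    if (spec$noise_sd_y > 0) y <- y + stats::rnorm(n, 0, spec$noise_sd_y)
    list(X = X, y = y, truth = list(C = C, P = P, b = spec$coeffs))
  })
}

#' Simulate labelled step samples for several participants and speeds
#'
#' Convenience wrapper looping [generate_gait_trial()] and
#' [step_samples_from_trial()] over a participant/speed grid and pooling
#' the samples, ready for [build_design_matrix()].
#'
#' @param config A [gait_sim_config()].
#' @param participants Participant ids (default `1:config$n_participants`).
#' @param speeds_kmh Speeds to simulate (default all configured speeds).
#' @param sites Sites to retain.
#' @param support `"left"` or `"right"`.
#' @return List of step samples pooled across trials.
#' @export
simulate_step_samples <- function(config, participants = seq_len(config$n_participants),
                                  speeds_kmh = config$speeds_kmh,
                                  sites = config$sites,
                                  support = c("left", "right")) {
  support <- match.arg(support)
  out <- list()
  for (p in participants) {
    for (v in speeds_kmh) {
      trial <- generate_gait_trial(config, p, v)
      out <- c(out, step_samples_from_trial(trial, sites, support))
    }
  }
  out
}
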