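test_that("CoM approximation is the pointwise ASIS midpoint", {
  mk <- data.frame(time_s = 0:2 / 100,
                   ASIS_L_x = c(-0.1, 0, 0), ASIS_L_y = c(0, 0, 0.02),
                   ASIS_L_z = c(0.9, 0.9, 0.88),
                   ASIS_R_x = c(0.1, 0, 0.2), ASIS_R_y = c(0, 0, 0.04),
                   ASIS_R_z = c(0.9, 0.9, 0.90))
  com <- com_from_asis(mk)
  expect_equal(unlist(com[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0.9))
  expect_equal(unlist(com[2, c("x", "y", "z")]), c(x = 0, y = 0, z = 0.9))
  expect_equal(unlist(com[3, c("x", "y", "z")]), c(x = 0.1, y = 0.03, z = 0.89))
  expect_error(com_from_asis(mk[, -2]), "ASIS_L_x")
})

test_that("central-difference velocity is exact for polynomials up to degree 2", {
  t <- seq(0, 2, by = 0.01)
  expect_equal(finite_difference(0.5 * t, 0.01), rep(0.5, length(t)))
  expect_equal(finite_difference(rep(3, length(t)), 0.01), rep(0, length(t)))
  v <- finite_difference(t^2, 0.01)
  i <- which(abs(t - 1) < 1e-12)
  expect_equal(v[i], 2.0, tolerance = 1e-12)
  expect_equal(v[2:(length(t) - 1)], 2 * t[2:(length(t) - 1)], tolerance = 1e-10)
  expect_error(finite_difference(c(1, 2), 0.1), "3 samples")
})

test_that("natural frequency follows the inverted-pendulum closed form", {
  expect_equal(natural_frequency(9.81), 1.0)
  expect_equal(natural_frequency(1.0), sqrt(9.81))
  expect_error(natural_frequency(0), "positive")
  expect_error(natural_frequency(-1), "positive")
})

test_that("XCoM extrapolation: identity limit, arithmetic, belt correction", {
  expect_equal(extrapolated_com(c(0, 0), c(0.1, 0.2), 2), cbind(0.05, 0.10))
  x <- c(0.3, -0.1)
  expect_equal(extrapolated_com(x, c(0, 0), 1.5), rbind(x), ignore_attr = TRUE)
  belt <- kmh_to_ms(3.0)
  expect_equal(extrapolated_com(c(0, 0), c(0, 0), 2, belt)[1, 2],
               0.41667, tolerance = 1e-4)
  expect_error(extrapolated_com(c(0, 0), c(0, 0), 0), "omega")
})

test_that("anterior margin is signed, mediolateral is absolute and symmetric", {
  expect_equal(anterior_mos(0.30, 0.25), 0.05)
  expect_equal(anterior_mos(0.2, 0.2), 0)
  expect_equal(anterior_mos(0.20, 0.26), -0.06)
  expect_equal(mediolateral_mos(0.10, 0.02), 0.08)
  expect_equal(mediolateral_mos(0.02, 0.10), 0.08)
  expect_equal(mediolateral_mos(0.5, 0.5), 0)
})

test_that("heel contacts detected as toe-marker anterior peaks alternate at half-stride", {
  t <- seq(0, 6, by = 0.005)
  T_ <- 1.2
  mk <- data.frame(time_s = t,
                   ASIS_L_x = -0.1, ASIS_L_y = 0, ASIS_L_z = 0.9,
                   ASIS_R_x = 0.1, ASIS_R_y = 0, ASIS_R_z = 0.9,
                   TOE_L_x = -0.1, TOE_L_y = sin(2 * pi * t / T_), TOE_L_z = 0.02,
                   TOE_R_x = 0.1, TOE_R_y = sin(2 * pi * (t - T_ / 2) / T_), TOE_R_z = 0.02)
  ev <- detect_heel_contacts(mk)
  expect_true(all(ev$foot[-1] != ev$foot[-nrow(ev)]))
  gaps <- diff(ev$time_s)
  expect_equal(gaps, rep(T_ / 2, length(gaps)), tolerance = 0.01)
  mk$TOE_L_y <- 0.3
  expect_error(detect_heel_contacts(mk), "detection error")
})

test_that("detector recovers generator contact times within one marker sample", {
  tr <- generate_gait_trial(small_config(), 1, 3.0)
  det <- detect_heel_contacts(tr$markers)
  dt <- 1 / tr$config$marker_rate_hz
  for (i in seq_len(nrow(tr$events))) {
    d <- min(abs(det$time_s - tr$events$time_s[i]))
    expect_lte(d, dt + 1e-9)
  }
})

test_that("static posture with zero belt gives constant anterior MoS", {
  t <- seq(0, 2, by = 0.005)
  mk <- data.frame(time_s = t,
                   ASIS_L_x = -0.1, ASIS_L_y = 0.02, ASIS_L_z = 0.9,
                   ASIS_R_x = 0.1, ASIS_R_y = 0.02, ASIS_R_z = 0.9,
                   TOE_L_x = -0.1, TOE_L_y = 0.25, TOE_L_z = 0.02,
                   TOE_R_x = 0.1, TOE_R_y = 0.25, TOE_R_z = 0.02)
  ev <- data.frame(time_s = 0.1, foot = "left")
  s <- mos_series(mk, ev, belt_speed_ms = 0)
  expect_equal(s$anterior_m, rep(0.23, nrow(s)))
  expect_true(all(s$time_s >= 0.1))
})

test_that("anterior MoS strictly decreases with belt speed, all else fixed", {
  tr <- generate_gait_trial(small_config(), 1, 3.0)
  s1 <- mos_series(tr$markers, tr$events, belt_speed_ms = 0.6)
  s2 <- mos_series(tr$markers, tr$events, belt_speed_ms = 0.9)
  expect_true(all(s2$anterior_m < s1$anterior_m))
  expect_true(all(s1$mediolateral_m >= 0))
})

test_that("mirror symmetry: swapping sides and negating x preserves mediolateral MoS", {
  tr <- generate_gait_trial(small_config(), 1, 3.0)
  mk <- tr$markers
  mirrored <- data.frame(
    time_s = mk$time_s,
    ASIS_L_x = -mk$ASIS_R_x, ASIS_L_y = mk$ASIS_R_y, ASIS_L_z = mk$ASIS_R_z,
    ASIS_R_x = -mk$ASIS_L_x, ASIS_R_y = mk$ASIS_L_y, ASIS_R_z = mk$ASIS_L_z,
    TOE_L_x = -mk$TOE_R_x, TOE_L_y = mk$TOE_R_y, TOE_L_z = mk$TOE_R_z,
    TOE_R_x = -mk$TOE_L_x, TOE_R_y = mk$TOE_L_y, TOE_R_z = mk$TOE_L_z)
  ev <- tr$events
  ev_m <- transform(ev, foot = ifelse(foot == "left", "right", "left"))
  s <- mos_series(mk, ev, belt_speed_ms = tr$belt_speed_ms)
  s_m <- mos_series(mirrored, ev_m, belt_speed_ms = tr$belt_speed_ms)
  expect_equal(s_m$mediolateral_m, s$mediolateral_m, tolerance = 1e-12)
  expect_equal(s_m$anterior_m, s$anterior_m, tolerance = 1e-12)
})

test_that("per-step minima pick out constructed dips and constants", {
  t <- seq(0, 1.2, by = 0.01)
  ev <- data.frame(time_s = c(0, 0.4, 0.8), foot = c("left", "right", "left"))
  s <- data.frame(time_s = t, support_foot = "left",
                  anterior_m = rep(0.05, length(t)),
                  mediolateral_m = rep(0.08, length(t)))
  lab <- min_mos_per_step(s, ev)
  expect_equal(nrow(lab), 2)
  expect_equal(lab$min_anterior_mos_mm, c(50, 50))
  expect_equal(lab$min_mediolateral_mos_mm, c(80, 80))
  expect_equal(lab$support_foot, c("left", "right"))
  s$anterior_m[t > 0.45 & t < 0.55] <- -0.0154
  lab2 <- min_mos_per_step(s, ev)
  expect_equal(lab2$min_anterior_mos_mm[2], -15.4)
  expect_equal(lab2$min_anterior_mos_mm[1], 50)
})
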