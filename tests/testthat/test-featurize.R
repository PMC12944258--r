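test_that("resampling is exact for constant and linear channels", {
  rec <- constant_imu(value = 2.5)
  ev <- alternating_events(c(1.0, 1.6, 2.2, 2.8))
  out <- segment_and_resample(rec, ev, support = "left")
  expect_equal(length(out), 2)
  expect_true(all(vapply(out, function(a) all(a == 2.5), logical(1))))
  expect_equal(dim(out[[1]]), c(51, 6))

  rec$ax <- 3 * rec$time_s - 1   # linear ramp: endpoints must be exact
  out <- segment_and_resample(rec, ev, support = "left")
  expect_equal(unname(out[[1]][1, "ax"]), 3 * 1.0 - 1)
  expect_equal(unname(out[[1]][51, "ax"]), 3 * 1.6 - 1)
  expect_equal(out[[1]][, "ax"], 3 * seq(1.0, 1.6, length.out = 51) - 1,
               tolerance = 1e-12)
})

test_that("resampling a sinusoid stays within the linear-interpolation bound", {
  rate <- 100; T_ <- 0.8
  rec <- constant_imu(rate = rate)
  rec$gz <- sin(2 * pi * rec$time_s / T_)
  ev <- alternating_events(c(1.0, 1.0 + T_ / 2))
  out <- segment_and_resample(rec, ev, support = "left")
  xs <- seq(1.0, 1.0 + T_ / 2, length.out = 51)
  bound <- (1 / rate)^2 * (2 * pi / T_)^2 / 8
  expect_lte(max(abs(out[[1]][, "gz"] - sin(2 * pi * xs / T_))), bound)
})

test_that("steps with too few IMU samples are skipped with a warning", {
  rec <- constant_imu(rate = 2, duration = 4)   # 2 Hz: 0.3 s window has < 2 samples
  ev <- alternating_events(c(1.05, 1.35, 2.05, 3.05))
  expect_warning(out <- segment_and_resample(rec, ev, support = "left"),
                 "skipped")
  expect_equal(length(out), 1)
})

test_that("predictor layout: 306 per site, 612 for two, ax block verbatim", {
  a1 <- matrix(seq_len(51 * 6), 51, 6, dimnames = list(NULL, c("ax","ay","az","gx","gy","gz")))
  a2 <- a1 + 1000
  v1 <- build_predictor_vector(list(knee = a1), "knee")
  expect_length(v1, 306)
  expect_equal(v1[1:51], a1[, "ax"])
  expect_equal(v1[52:102], a1[, "ay"])
  expect_equal(v1[256:306], a1[, "gz"])
  v2 <- build_predictor_vector(list(knee = a1, instep = a2), c("knee", "instep"))
  expect_length(v2, 612)
  expect_equal(v2[1:306], v1)
  expect_equal(v2[307:357], a2[, "ax"])
  expect_error(build_predictor_vector(list(a = a1, b = a1, c = a1), c("a","b","c")),
               "1 or 2 sites")
  expect_error(build_predictor_vector(list(knee = a1[, 1:5]), "knee"), "x 6")
})

test_that("flatten/unflatten round-trips the step arrays exactly", {
  set.seed(1)
  arrays <- list(knee = matrix(rnorm(306), 51, 6, dimnames = list(NULL, c("ax","ay","az","gx","gy","gz"))),
                 wrist = matrix(rnorm(306), 51, 6, dimnames = list(NULL, c("ax","ay","az","gx","gy","gz"))))
  v <- build_predictor_vector(arrays, c("knee", "wrist"))
  back <- unflatten_predictor_vector(v, c("knee", "wrist"))
  expect_equal(back$knee, arrays$knee)
  expect_equal(back$wrist, arrays$wrist)
})

test_that("resampling is idempotent on an already-normalised 51-point grid", {
  t51 <- seq(2, 2.5, length.out = 51)
  rec <- data.frame(time_s = t51, ax = rnorm(51), ay = 0, az = 0,
                    gx = 0, gy = 0, gz = 0)
  ev <- alternating_events(c(2, 2.5))
  out <- segment_and_resample(rec, ev, support = "left")
  expect_equal(out[[1]][, "ax"], rec$ax, tolerance = 1e-12)
})

test_that("design matrix aligns rows with labels and rejects bad input", {
  cfg <- small_config(seed = 4, steps = 8)
  samples <- simulate_step_samples(cfg, participants = 1, speeds_kmh = 3.0,
                                   support = "right")
  dm <- build_design_matrix(samples, "right_knee", "anterior")
  expect_equal(dim(dm$X), c(8, 306))
  expect_equal(length(dm$y), 8)
  expect_equal(dm$support_foot, "right")

  perm <- sample(length(samples))
  dm_p <- build_design_matrix(samples[perm], "right_knee", "anterior")
  expect_equal(dm_p$X, dm$X[perm, ], ignore_attr = TRUE)
  expect_equal(dm_p$y, dm$y[perm])

  expect_error(build_design_matrix(list(), "right_knee", "anterior"), "no step samples")
  mixed <- c(samples[1], step_samples_from_trial(
    generate_gait_trial(cfg, 1, 3.0), "right_knee", "left")[1])
  expect_error(build_design_matrix(mixed, "right_knee", "anterior"),
               "must not be mixed")
  expect_error(build_design_matrix(samples, "elbow", "anterior"), "elbow")
})
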