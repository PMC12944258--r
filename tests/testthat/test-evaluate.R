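test_that("rmse and pearson behave as the textbook definitions", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  y <- rnorm(10); yh <- y + rnorm(10)
  expect_equal(rmse(yh + 5, y + 5), rmse(yh, y))
  expect_error(rmse(1:3, 1:2), "equal")
  expect_equal(pearson(2 * y + 1, y), 1)
  expect_equal(pearson(-y, y), -1)
  expect_equal(pearson(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
  expect_warning(r <- pearson(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(r))
})

test_that("stratified folds are balanced within every (participant, speed) stratum", {
  meta1 <- data.frame(participant = 1, speed_kmh = 3.0)[rep(1, 60), ]
  f <- make_folds(meta1, k = 10, seed = 1)
  expect_equal(as.integer(table(f)), rep(6L, 10))

  meta <- expand.grid(participant = 1:8, speed_kmh = c(2.5, 3, 3.5))
  meta <- meta[rep(seq_len(nrow(meta)), each = 60), ]
  f <- make_folds(meta, k = 10, seed = 2)
  expect_equal(as.integer(table(f)), rep(144L, 10))
  per_stratum <- table(interaction(meta$participant, meta$speed_kmh), f)
  expect_true(all(per_stratum == 6))

  expect_identical(make_folds(meta, 10, seed = 3), make_folds(meta, 10, seed = 3))
  differs <- vapply(1:5, function(s) {
    !identical(make_folds(meta, 10, seed = s), make_folds(meta, 10, seed = s + 50))
  }, logical(1))
  expect_true(any(differs))
  expect_error(make_folds(meta1[1:5, ], k = 10), "exceeds")
})

test_that("every sample lands in exactly one fold and order does not matter", {
  meta <- data.frame(participant = rep(1:3, each = 25), speed_kmh = 3)
  f <- make_folds(meta, k = 5, seed = 4)
  expect_length(f, 75)
  expect_true(all(f %in% 1:5))
  expect_true(all(table(f[meta$participant == 2]) == 5))
})

test_that("cross-validation recovers a noiseless one-latent model exactly", {
  d <- generate_latent_dataset(latent_linear_spec(
    n_samples = 60, dim = 40, n_latent = 1, noise_sd_x = 0, noise_sd_y = 0, seed = 6))
  dm <- list(X = d$X, y = d$y, meta = NULL)
  cv <- cross_validate(dm, 1, k = 10, repetitions = 2, base_seed = 1)
  expect_lt(cv$summary[["mean_rmse"]], 1e-8)
  expect_equal(nrow(cv$folds), 20)
})

test_that("no leakage: CV RMSE on response-independent predictors stays near sd(y)", {
  ratios <- vapply(1:3, function(s) {
    set.seed(s)
    X <- matrix(rnorm(120 * 50), 120, 50)
    y <- rnorm(120)
    cv <- cross_validate(list(X = X, y = y, meta = NULL), 3,
                         k = 10, repetitions = 2, base_seed = s)
    cv$summary[["mean_rmse"]] / sd(y)
  }, numeric(1))
  expect_true(all(ratios >= 0.9))
})

test_that("select_L finds a single exact component and reports the RMSE path", {
  d <- generate_latent_dataset(latent_linear_spec(
    n_samples = 60, dim = 40, n_latent = 1, noise_sd_x = 0, noise_sd_y = 0, seed = 8))
  # noiseless data exhausts the covariance after one component; the
  # early-stop warning is the designed behaviour
  sel <- suppressWarnings(select_L(list(X = d$X, y = d$y, meta = NULL), 1:5,
                                   k = 5, repetitions = 2, base_seed = 1))
  expect_equal(sel$best_L, 1L)
  expect_length(sel$rmse_by_L, 5)
  expect_lt(sel$rmse_by_L[["1"]], 1e-8)
})

test_that("placement grid enumerates singles and pairs with symmetric keying", {
  cfg <- small_config(seed = 13, steps = 15,
                      sites = c("right_knee", "sacral_crest", "skull_vertex"))
  samples <- simulate_step_samples(cfg, participants = 1, speeds_kmh = 3.0,
                                   support = "left")
  grid <- placement_grid(samples, cfg$sites, "anterior", L = 3,
                         k = 5, repetitions = 1, base_seed = 1)
  expect_equal(nrow(grid), 3 + choose(3, 2))
  singles <- grid[grid$site_a == grid$site_b, ]
  expect_equal(sort(singles$site_a), sort(cfg$sites))
  pairs <- grid[grid$site_a != grid$site_b, ]
  key <- apply(pairs[, c("site_a", "site_b")], 1, function(r) paste(sort(r), collapse = "|"))
  expect_equal(anyDuplicated(key), 0)
  # informative lower-limb site beats the zero-loading skull site
  r_knee <- singles$mean_rmse[singles$site_a == "right_knee"]
  r_skull <- singles$mean_rmse[singles$site_a == "skull_vertex"]
  expect_lt(r_knee, r_skull)
  m <- format_placement_matrix(grid)
  expect_equal(dim(m), c(3, 3))
  expect_true(all(nzchar(diag(m))))
  expect_error(placement_grid(samples, "right_knee", "anterior", 3), "2 sites")
})

test_that("MoS values categorise into SD bands with only low values flagged", {
  expect_equal(as.character(categorize_mos(76.8, 76.8, 13.8)), "typical")
  expect_equal(as.character(categorize_mos(76.8 - 1.5 * 13.8, 76.8, 13.8)), "cautionary")
  expect_equal(as.character(categorize_mos(76.8 - 2.5 * 13.8, 76.8, 13.8)), "high_risk")
  expect_equal(as.character(categorize_mos(76.8 + 3 * 13.8, 76.8, 13.8)), "typical")
  expect_equal(as.character(categorize_mos(76.8 - 13.8, 76.8, 13.8)), "typical")
  expect_equal(as.character(categorize_mos(76.8 - 2 * 13.8, 76.8, 13.8)), "cautionary")
  expect_equal(as.character(categorize_mos(c(80, 50, 40), 76.8, 13.8)),
               c("typical", "cautionary", "high_risk"))
  expect_error(categorize_mos(50, 76.8, 0), "positive")
})
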