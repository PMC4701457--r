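test_that("planted weight patterns match direct Gaussian-sum evaluation", {
  cfg <- generator_config(grid_shape = c(8, 8, 6), mask_kind = "full",
                          n_blobs = 0, seed = 1)
  expect_equal(make_weight_pattern(cfg), array(0, dim = c(8, 8, 6)))

  # delta limit: a near-zero-width bump at the grid midpoint hits one voxel
  cfg1 <- generator_config(grid_shape = c(9, 9, 9), mask_kind = "full",
                           n_blobs = 1, blob_sigma_mm = 1e-4, seed = 1)
  w <- make_weight_pattern(cfg1, centers = matrix(c(5, 5, 5), 1))
  expect_equal(sum(w != 0), 1)
  expect_equal(w[5, 5, 5], 1)

  # two-bump pattern against an independent voxelwise formula evaluation
  cfg2 <- generator_config(grid_shape = c(7, 6, 5), mask_kind = "full",
                           n_blobs = 2, blob_sigma_mm = 4, seed = 3)
  ctr <- matrix(c(2, 3, 2, 5, 4, 4), 2, byrow = TRUE)
  w2 <- make_weight_pattern(cfg2, centers = ctr, signs = c(1, -1))
  s <- 4 / 3.1
  oracle <- array(0, dim = c(7, 6, 5))
  for (i in 1:7) for (j in 1:6) for (k in 1:5) {
    d1 <- (i - 2)^2 + (j - 3)^2 + (k - 2)^2
    d2 <- (i - 5)^2 + (j - 4)^2 + (k - 4)^2
    oracle[i, j, k] <- exp(-d1 / (2 * s^2)) - exp(-d2 / (2 * s^2))
  }
  expect_equal(w2, oracle, tolerance = 1e-12)

  # random centers are drawn inside the mask, support stays inside it
  cfg3 <- generator_config(grid_shape = c(10, 10, 8), mask_kind = "ellipsoid",
                           n_blobs = 3, blob_sigma_mm = 5, seed = 9)
  w3 <- make_weight_pattern(cfg3)
  expect_true(all(is.finite(w3)))
  expect_true(all(w3[!rvrdecode:::config_mask(cfg3)] == 0))

  expect_error(make_weight_pattern(
    generator_config(grid_shape = c(3, 8, 8), blob_sigma_mm = 20,
                     n_blobs = 1)), "too small")
})

test_that("score draws honor location, clipping and the preset moments", {
  cfg0 <- generator_config(score_model = "custom", score_loc = 10,
                           score_scale = 0, score_bounds = c(0, 30))
  expect_equal(draw_scores(cfg0, 15)$observed, rep(10, 15))

  # screen-like sample mean vs. numeric integration of the clipped normal
  cfg <- generator_config(score_model = "screen_like", seed = 11)
  sc <- draw_scores(cfg, 20000)
  cens_mean <- 0 * pnorm(0, 15.5, 6.3) +
    30 * (1 - pnorm(30, 15.5, 6.3)) +
    integrate(function(x) x * dnorm(x, 15.5, 6.3), 0, 30)$value
  expect_lt(abs(mean(sc$observed) - cens_mean), 4 * 6.3 / sqrt(20000))
  expect_gte(min(sc$observed), 0)
  expect_lte(max(sc$observed), 30)

  # near-scan scores are right-skewed and sit near their target location
  near <- draw_scores(generator_config(score_model = "nearscan_like",
                                       seed = 5), 20000)
  m <- mean(near$observed)
  skew <- mean((near$observed - m)^3) / sd(near$observed)^3
  expect_gt(skew, 0.3)
  expect_lt(abs(m - 4.7), 1.5)  # clipping at 0 shifts the mean upward a bit
  expect_gte(min(near$observed), 0)
  # monotone transform: observed is non-decreasing in the latent severity
  expect_true(all(diff(near$observed[order(near$latent)]) >= 0))

  expect_error(draw_scores(cfg, 0), "at least 1")

  cfgint <- generator_config(score_model = "screen_like",
                             integerize_scores = TRUE, seed = 2)
  obs <- draw_scores(cfgint, 500)$observed
  expect_true(all(obs == round(obs)))
})

test_that("generated studies are noiseless-exact, clip-free of NaN on demand, and reproducible", {
  dir1 <- withr::local_tempdir()
  cfg <- generator_config(grid_shape = c(5, 5, 4), mask_kind = "full",
                          n_subjects = 6, n_blobs = 1, blob_sigma_mm = 4,
                          noise_sd = 0, confound_pattern_gain = 0,
                          nan_rate = 0, seed = 21)
  st <- generate_study(cfg, dir1)
  w <- st$ground_truth$weight_volume
  z <- st$ground_truth$latent_scores
  for (i in seq_len(6)) {
    v <- read_volume(st$paths$volumes[i])$data
    expect_equal(v, z[i] * w, tolerance = 1e-12)
    expect_false(anyNA(v))
  }

  # bit-identical regeneration under the same config + seed
  dir2 <- withr::local_tempdir()
  st2 <- generate_study(cfg, dir2)
  expect_identical(readBin(st$paths$subjects, "raw", 1e5),
                   readBin(st2$paths$subjects, "raw", 1e5))
  expect_identical(read_volume(st$paths$volumes[3])$data,
                   read_volume(st2$paths$volumes[3])$data)

  expect_error(generate_study(generator_config(nan_rate = 1), dir1),
               "no finite voxel")
})

test_that("confound prevalence matches its Bernoulli target", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(grid_shape = c(2, 1, 1), mask_kind = "full",
                          n_subjects = 4000, n_blobs = 0, noise_sd = 0,
                          nan_rate = 0, confound_prevalence = 0.526,
                          seed = 77)
  st <- generate_study(cfg, dir)
  p_hat <- mean(st$ground_truth$confound_vector)
  expect_lt(abs(p_hat - 0.526), 4 * sqrt(0.526 * 0.474 / 4000))
  expect_identical(st$subjects$confound, st$ground_truth$confound_vector)
})

test_that("written volumes round-trip exactly and feed the downstream mask", {
  st <- tiny_study(nan_rate = 0.05, seed = 13)
  arrs <- lapply(unname(st$paths$volumes), function(p) read_volume(p)$data)
  mask <- build_common_mask(unname(st$paths$volumes))
  # NaN-intersection: a voxel survives iff finite in every subject
  oracle <- Reduce(`&`, lapply(arrs, is.finite))
  expect_equal(mask$include, oracle)
  expect_gt(mask$n_excluded, 0)

  # round trip through vector extraction and back
  v1 <- arrs[[1]][mask$include]
  vol <- vector_to_volume(v1, mask)
  expect_equal(vol[mask$include], v1)
})

test_that("confound score shift and pattern gain act as configured", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(grid_shape = c(4, 4, 3), mask_kind = "full",
                          n_subjects = 400, n_blobs = 1, blob_sigma_mm = 3,
                          noise_sd = 0, nan_rate = 0,
                          confound_prevalence = 0.5,
                          confound_score_shift = 5, seed = 31)
  st <- generate_study(cfg, dir)
  tt <- confound_score_ttest(st$subjects$score_screen,
                             st$ground_truth$confound_vector)
  expect_lt(tt$p, 0.01)
  expect_gt(tt$group_means["confound_1"] - tt$group_means["confound_0"], 2)
})
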