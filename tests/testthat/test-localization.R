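block_mask <- function(d) {
  d <- as.integer(d)
  structure(list(grid_shape = d, affine = NULL,
                 include = array(TRUE, dim = d), V = prod(d),
                 n_excluded = 0L),
            class = "mask_volume")
}

write_atlas_fixture <- function(dir, labels_volume, labels_df) {
  nii <- file.path(dir, "atlas.nii.gz")
  tsv <- file.path(dir, "labels.tsv")
  write_volume(labels_volume, nii)
  utils::write.table(labels_df, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  list(nii = nii, tsv = tsv)
}

test_that("fold-averaged weight maps are unit-norm means", {
  expect_equal(average_weight_map(list(c(1, 0), c(0, 1))),
               c(1, 1) / sqrt(2), tolerance = 1e-12)
  v <- c(3, -4)
  expect_equal(average_weight_map(list(v)), v / 5, tolerance = 1e-12)

  withr::with_seed(1, folds <- replicate(5, rnorm(30), simplify = FALSE))
  avg <- average_weight_map(folds)
  brute <- Reduce(`+`, folds) / 5
  expect_equal(sqrt(sum(avg^2)), 1, tolerance = 1e-10)
  expect_equal(avg, brute / sqrt(sum(brute^2)), tolerance = 1e-12)

  expect_warning(z <- average_weight_map(list(rep(0, 4), rep(0, 4))),
                 "zero")
  expect_equal(z, rep(0, 4))
  expect_error(average_weight_map(list(1:3, 1:4)), "length")
})

test_that("region normalized weights are per-region means of absolute weights", {
  d <- c(4, 2, 1)
  mask <- block_mask(d)
  lab <- array(c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L), dim = d)
  atlas <- structure(list(label_volume = lab,
                          labels = c(`1` = "A", `2` = "B"),
                          background_value = 0L,
                          dropped_regions = character(0)),
                     class = "atlas_label_map")

  # uniform |w|: every region's NW equals the constant
  nw_u <- region_normalized_weights(rep(-0.5, 8), mask, atlas)
  expect_equal(nw_u$mean_abs_weight, c(0.5, 0.5))

  # hand case: A has |w| {0.2, 0.4, 0.2, 0.4}, B has 0.1 everywhere
  w <- rep(0, 8)
  w[lab == 1] <- c(0.2, -0.4, 0.2, -0.4)
  w[lab == 2] <- 0.1
  nw <- region_normalized_weights(w, mask, atlas)
  expect_equal(nw$mean_abs_weight[nw$region_name == "A"], 0.3)
  expect_equal(nw$mean_abs_weight[nw$region_name == "B"], 0.1)

  # random map, random 6-region atlas vs. brute-force voxel loop
  d6 <- c(5, 4, 3)
  mask6 <- block_mask(d6)
  withr::with_seed(2, {
    lab6 <- array(sample(0:6, prod(d6), replace = TRUE), dim = d6)
    w6 <- rnorm(prod(d6))
  })
  present <- sort(unique(lab6[lab6 > 0]))
  atlas6 <- structure(list(label_volume = lab6,
                           labels = stats::setNames(paste0("R", present),
                                                    present),
                           background_value = 0L,
                           dropped_regions = character(0)),
                      class = "atlas_label_map")
  nw6 <- region_normalized_weights(w6, mask6, atlas6)
  wvol <- vector_to_volume(w6, mask6)
  for (g in present) {
    tot <- 0; cnt <- 0
    for (i in 1:5) for (j in 1:4) for (k in 1:3)
      if (lab6[i, j, k] == g) { tot <- tot + abs(wvol[i, j, k]); cnt <- cnt + 1 }
    expect_equal(nw6$mean_abs_weight[nw6$label_value == g], tot / cnt,
                 tolerance = 1e-12)
  }
})

test_that("region ranking conserves percentages and breaks ties by name", {
  nw <- data.frame(region_name = c("A", "B"), label_value = 1:2,
                   n_voxels = c(2L, 2L), mean_abs_weight = c(0.3, 0.1))
  rk <- rank_regions(nw)
  expect_equal(rk$pct_total_nw, c(75, 25))
  expect_equal(rk$region_name, c("A", "B"))
  expect_equal(rk$cumulative_pct[2], 100, tolerance = 1e-8)

  ties <- data.frame(region_name = c("delta", "alpha", "echo", "bravo",
                                     "charlie"),
                     label_value = 1:5, n_voxels = rep(1L, 5),
                     mean_abs_weight = rep(0.2, 5))
  rt <- rank_regions(ties)
  expect_equal(rt$pct_total_nw, rep(20, 5))
  expect_equal(rt$region_name,
               c("alpha", "bravo", "charlie", "delta", "echo"))

  # scale invariance of percentages
  scaled <- nw; scaled$mean_abs_weight <- nw$mean_abs_weight * 37.5
  expect_equal(rank_regions(scaled)$pct_total_nw, rk$pct_total_nw,
               tolerance = 1e-12)

  expect_warning(empty <- rank_regions(
    data.frame(region_name = "A", label_value = 1L, n_voxels = 1L,
               mean_abs_weight = 0)), "zero")
  expect_equal(nrow(empty), 0)
})

test_that("atlas loading joins labels, auto-names gaps and drops empty regions", {
  dir <- withr::local_tempdir()
  d <- c(4, 4, 2)
  mask <- block_mask(d)
  lab <- array(rep(c(1L, 2L), each = 16), dim = d)
  fx <- write_atlas_fixture(dir, lab,
                            data.frame(label_value = 1:2,
                                       region_name = c("left", "right")))
  atlas <- load_atlas(fx$nii, fx$tsv, mask)
  expect_equal(unname(atlas$labels), c("left", "right"))

  # a label present in the volume but absent from the TSV is auto-named
  lab99 <- lab; lab99[1, 1, 1] <- 99L
  fx99 <- write_atlas_fixture(dir, lab99,
                              data.frame(label_value = 1:2,
                                         region_name = c("left", "right")))
  expect_warning(a99 <- load_atlas(fx99$nii, fx99$tsv, mask), "auto-named")
  expect_true("label_99" %in% a99$labels)

  # region entirely outside the analysis mask is dropped with a warning
  mask_half <- mask
  mask_half$include[, , 2] <- FALSE
  mask_half$V <- sum(mask_half$include)
  lab_z <- array(0L, dim = d); lab_z[, , 1] <- 1L; lab_z[, , 2] <- 2L
  fxz <- write_atlas_fixture(dir, lab_z,
                             data.frame(label_value = 1:2,
                                        region_name = c("in", "out")))
  expect_warning(az <- load_atlas(fxz$nii, fxz$tsv, mask_half), "dropped")
  expect_equal(unname(az$labels), "in")
  expect_equal(unname(az$dropped_regions), "out")

  # grid mismatch is an error
  mask_small <- block_mask(c(3, 3, 2))
  expect_error(load_atlas(fx$nii, fx$tsv, mask_small), "grid")
})

test_that("a planted blob's region ranks first", {
  st <- tiny_study(grid_shape = c(8, 8, 4), n_subjects = 30, n_blobs = 1,
                   blob_sigma_mm = 4, noise_sd = 0.2, nan_rate = 0,
                   atlas_blocks = c(2, 2, 1), seed = 19)
  mask <- build_common_mask(unname(st$paths$volumes))
  ds <- assemble_dataset(st$paths$volumes, st$subjects, "score_screen", mask)
  res <- run_decoding(ds, make_loo(30))
  atlas <- load_atlas(st$paths$atlas, st$paths$atlas_labels, mask)
  rk <- rank_regions(region_normalized_weights(res$weight_map, mask, atlas))

  w_true <- st$ground_truth$weight_volume
  peak <- arrayInd(which.max(abs(w_true)), dim(w_true))
  peak_label <- atlas$label_volume[peak]
  expect_equal(rk$label_value[1], peak_label)
  expect_equal(sum(rk$pct_total_nw), 100, tolerance = 1e-8)

  # weight map sign covaries with the planted pattern
  wt_vec <- w_true[mask$include]
  expect_gt(cor(res$weight_map, wt_vec), 0)
})
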