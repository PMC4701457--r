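#' Configuration for the synthetic-study generator
#'
#' The generator emulates the structure of a multi-site pediatric reward-task
#' fMRI decoding study: per-subject GLM coefficient volumes whose pattern is a
#' planted spatial weight map scaled by a latent symptom severity, plus
#' spatially smooth noise; a parent-rated 0-30 mania score observed at two
#' time points (an approximately normal "screen" score, mean 15.5 / SD 6.3,
#' and a right-skewed "near-scan" score, location 4.7 / scale 5.4); and a
#' binary psychotropic-medication confound with prevalence 52.6%.
#'
#' @param grid_shape Integer vector of 3 positive voxel counts per axis.
#' @param voxel_size_mm Isotropic voxel edge in mm (3.1 mm, mirroring the
#'   acquisition this emulates).
#' @param mask_kind `"full"` (whole grid) or `"ellipsoid"` (inscribed
#'   ellipsoid, a crude brain outline).
#' @param n_subjects Number of subjects (default 57).
#' @param n_blobs Number of planted signed Gaussian signal bumps (0 = no
#'   signal).
#' @param blob_sigma_mm Gaussian SD of each bump, in mm.
#' @param noise_sd Interior voxel SD of the additive noise field.
#' @param noise_smooth_fwhm_mm FWHM of the Gaussian smoothing applied to the
#'   white noise field (8 mm echoes the preprocessing kernel of the study
#'   design this emulates); 0 = white noise.
#' @param score_model `"screen_like"`, `"nearscan_like"` or `"custom"`;
#'   selects which score column carries the planted brain-score association
#'   and which marginal distribution [draw_scores()] produces.
#' @param score_loc,score_scale,score_bounds Location, scale and
#'   `c(low, high)` clipping bounds used when `score_model = "custom"`.
#' @param integerize_scores Round observed scores to integers (half away from
#'   zero), as item-sum questionnaire totals are.
#' @param confound_prevalence Bernoulli probability of confound = 1
#'   (default 0.526).
#' @param confound_score_shift Additive effect (score units) of confound = 1
#'   on the latent score; default 0 (no confound-score association).
#' @param confound_pattern_gain Amplitude of the confound's own spatial
#'   pattern added to the volumes of confounded subjects; default 0.
#' @param nan_rate Per subject-voxel probability of injecting a NaN inside
#'   the mask (exercises NaN-intersection mask building).
#' @param atlas_blocks Integer vector of 3: blocks per axis of the synthetic
#'   labelled atlas partitioning the mask.
#' @param seed Integer RNG seed; identical config + seed gives bit-identical
#'   outputs.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(grid_shape = c(16, 16, 12),
                             voxel_size_mm = 3.1,
                             mask_kind = c("ellipsoid", "full"),
                             n_subjects = 57,
                             n_blobs = 3,
                             blob_sigma_mm = 6,
                             noise_sd = 1,
                             noise_smooth_fwhm_mm = 8,
                             score_model = c("screen_like", "nearscan_like",
                                             "custom"),
                             score_loc = 15.5,
                             score_scale = 6.3,
                             score_bounds = c(0, 30),
                             integerize_scores = FALSE,
                             confound_prevalence = 0.526,
                             confound_score_shift = 0,
                             confound_pattern_gain = 0,
                             nan_rate = 0.005,
                             atlas_blocks = c(3, 3, 2),
                             seed = 1) {
  mask_kind <- match.arg(mask_kind)
  score_model <- match.arg(score_model)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            voxel_size_mm > 0,
            n_subjects >= 1, n_blobs >= 0,
            blob_sigma_mm > 0, noise_sd >= 0, noise_smooth_fwhm_mm >= 0,
            score_scale >= 0, length(score_bounds) == 2,
            length(atlas_blocks) == 3, all(atlas_blocks >= 1))
  if (score_bounds[1] >= score_bounds[2])
    stop("score_bounds must satisfy low < high")
  if (confound_prevalence < 0 || confound_prevalence > 1)
    stop("confound_prevalence must lie in [0, 1]")
  if (nan_rate < 0 || nan_rate > 1) stop("nan_rate must lie in [0, 1]")
  structure(list(
    grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
    mask_kind = mask_kind, n_subjects = as.integer(n_subjects),
    n_blobs = as.integer(n_blobs), blob_sigma_mm = blob_sigma_mm,
    noise_sd = noise_sd, noise_smooth_fwhm_mm = noise_smooth_fwhm_mm,
    score_model = score_model, score_loc = score_loc,
    score_scale = score_scale, score_bounds = as.numeric(score_bounds),
    integerize_scores = isTRUE(integerize_scores),
    confound_prevalence = confound_prevalence,
    confound_score_shift = confound_score_shift,
    confound_pattern_gain = confound_pattern_gain,
    nan_rate = nan_rate, atlas_blocks = as.integer(atlas_blocks),
    seed = as.integer(seed)),
    class = "generator_config")
}

# Boolean generation mask implied by the config (full grid or inscribed
# ellipsoid).  This is the *generation* support; the analysis mask is built
# downstream from the written volumes by the NaN-intersection rule.
config_mask <- function(config) {
  d <- config$grid_shape
  if (config$mask_kind == "full") return(array(TRUE, dim = d))
  ctr <- (d + 1) / 2
  rad <- pmax(d / 2, 0.5)
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  v <- ((g$x - ctr[1]) / rad[1])^2 + ((g$y - ctr[2]) / rad[2])^2 +
    ((g$z - ctr[3]) / rad[3])^2
  array(v <= 1, dim = d)
}

config_affine <- function(config) {
  a <- diag(c(-config$voxel_size_mm, config$voxel_size_mm,
              config$voxel_size_mm, 1))
  a[1:3, 4] <- -(config$grid_shape / 2) *
    c(-config$voxel_size_mm, config$voxel_size_mm, config$voxel_size_mm)
  a
}

#' Plant a spatial weight pattern
#'
#' Builds the ground-truth voxel weight map as a sum of `n_blobs` signed
#' Gaussian bumps (signs alternate +, -, +, ...), with centers drawn
#' uniformly among mask voxels unless supplied.  Zero outside the mask.
#'
#' @param config A [generator_config()].
#' @param centers Optional matrix (n_blobs x 3) of voxel coordinates for the
#'   bump centers, overriding the random draw.
#' @param signs Optional vector of bump signs (+1/-1).
#' @param seed RNG seed for the center draw (defaults to `config$seed`).
#' @return A 3D array on the grid; all-zero when `n_blobs = 0`.
#' @export
make_weight_pattern <- function(config, centers = NULL, signs = NULL,
                                seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  d <- config$grid_shape
  w <- array(0, dim = d)
  if (config$n_blobs == 0L) return(w)
  extent_mm <- min(d) * config$voxel_size_mm
  if (config$blob_sigma_mm > extent_mm / 2)
    stop("grid too small for a blob of sigma ", config$blob_sigma_mm,
         " mm (shortest axis spans ", extent_mm, " mm)")
  mask <- config_mask(config)
  if (is.null(centers)) {
    idx <- which(mask)
    centers <- with_seed(seed, {
      pick <- idx[sample.int(length(idx), config$n_blobs, replace = TRUE)]
      arrayInd(pick, d)
    })
  } else {
    centers <- matrix(as.numeric(centers), ncol = 3)
    if (nrow(centers) != config$n_blobs)
      stop("centers must have one row per blob")
  }
  if (is.null(signs)) signs <- rep(c(1, -1), length.out = config$n_blobs)
  s_vox <- config$blob_sigma_mm / config$voxel_size_mm
  ax <- lapply(d, seq_len)
  for (b in seq_len(config$n_blobs)) {
    dx2 <- outer(outer((ax[[1]] - centers[b, 1])^2,
                       (ax[[2]] - centers[b, 2])^2, "+"),
                 (ax[[3]] - centers[b, 3])^2, "+")
    w <- w + signs[b] * exp(-dx2 / (2 * s_vox^2))
  }
  w[!mask] <- 0
  w
}

#' Draw symptom scores
#'
#' Draws `n` observed scores and the latent standardized severities behind
#' them.  `screen_like` is a clipped normal with location 15.5, scale 6.3 on
#' \[0, 30\]; `nearscan_like` is a right-skewed clipped half-normal-style
#' construction (a monotone probability-transform of the same latent normal,
#' standardized, at location 4.7, scale 5.4 on \[0, 30\]); `custom` uses the
#' config's `score_loc` / `score_scale` / `score_bounds` with a normal latent.
#'
#' @param config A [generator_config()].
#' @param n Number of subjects to draw (>= 1).
#' @param seed RNG seed (defaults to `config$seed`).
#' @return List with `observed` (clipped, optionally integerized scores) and
#'   `latent` (standardized latent severities; what the planted brain pattern
#'   scales with).
#' @export
draw_scores <- function(config, n, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (n < 1) stop("n must be at least 1")
  z <- with_seed(seed, rnorm(n))
  score_transform(config, z, config$score_model)
}

# Map latent standard normals to (observed, latent standardized) scores for
# one score model.  The near-scan transform sends z through the half-normal
# quantile map qnorm((1 + pnorm(z)) / 2), which is monotone in z and
# half-normally distributed, then standardizes by the half-normal moments
# sqrt(2/pi) and sqrt(1 - 2/pi).
score_transform <- function(config, z, model) {
  par <- switch(model,
    screen_like   = list(loc = 15.5, scale = 6.3, bounds = c(0, 30)),
    nearscan_like = list(loc = 4.7,  scale = 5.4, bounds = c(0, 30)),
    custom        = list(loc = config$score_loc, scale = config$score_scale,
                         bounds = config$score_bounds))
  t_z <- if (model == "nearscan_like") {
    h <- stats::qnorm((1 + stats::pnorm(z)) / 2)
    (h - sqrt(2 / pi)) / sqrt(1 - 2 / pi)
  } else z
  obs <- clip(par$loc + par$scale * t_z, par$bounds[1], par$bounds[2])
  if (config$integerize_scores) obs <- round_half_away(obs)
  list(observed = obs, latent = t_z)
}

# Block-partition atlas over the generation mask: label = index of the
# (atlas_blocks) block a voxel falls in; 0 (background) outside the mask.
config_atlas <- function(config) {
  d <- config$grid_shape
  nb <- config$atlas_blocks
  bx <- pmin(ceiling(seq_len(d[1]) / ceiling(d[1] / nb[1])), nb[1])
  by <- pmin(ceiling(seq_len(d[2]) / ceiling(d[2] / nb[2])), nb[2])
  bz <- pmin(ceiling(seq_len(d[3]) / ceiling(d[3] / nb[3])), nb[3])
  lab <- outer(outer(bx, (by - 1) * nb[1], "+"),
               (bz - 1) * nb[1] * nb[2], "+")
  lab <- array(as.integer(lab), dim = d)
  lab[!config_mask(config)] <- 0L
  lab
}

#' Generate a complete synthetic study on disk
#'
#' Writes one NIfTI coefficient volume per subject
#' (`x_i = z_i * w + confound_pattern_gain * c_i * w_c + smooth noise`, NaN
#' outside the generation mask and at `nan_rate` inside it), a subjects CSV
#' (`subject_id,score_screen,score_nearscan,confound`), the generation mask,
#' a synthetic block atlas with its label TSV, the true weight map, a
#' ground-truth CSV (latent severities) and a YAML echo of the config.
#'
#' Both score columns derive from one latent severity `z`: the screen column
#' through the screen-like transform, the near-scan column through the
#' skewed near-scan transform, so both are (monotonically) related to the
#' planted pattern, as two time points of one trait would be.  The pattern
#' itself scales with the latent of the column selected by
#' `config$score_model`, to which `confound_score_shift` is also applied.
#'
#' @param config A [generator_config()].
#' @param out_dir Writable output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths; `volumes` is
#'   named by subject id), `subjects` (the subjects table), and
#'   `ground_truth` (`weight_volume`, `confound_weight_volume`,
#'   `latent_scores`, `confound_vector`).
#' @export
generate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "generator_config"))
  if (config$nan_rate >= 1)
    stop("nan_rate = 1 would leave no finite voxel in the common mask")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  d <- config$grid_shape
  n <- config$n_subjects
  mask <- config_mask(config)
  affine <- config_affine(config)

  w <- make_weight_pattern(config, seed = config$seed)
  w_c <- if (config$confound_pattern_gain != 0)
    make_weight_pattern(config, seed = config$seed + 1L)
  else array(0, dim = d)

  sigma_vox <- config$noise_smooth_fwhm_mm /
    (2 * sqrt(2 * log(2))) / config$voxel_size_mm

  gt <- with_seed(config$seed + 2L, {
    z <- rnorm(n)
    cvec <- rbinom(n, 1L, config$confound_prevalence)
    sc_screen <- score_transform(config, z, "screen_like")
    sc_near <- score_transform(config, z, "nearscan_like")
    primary <- switch(config$score_model,
                      screen_like = sc_screen, nearscan_like = sc_near,
                      custom = score_transform(config, z, "custom"))
    par_scale <- switch(config$score_model, screen_like = 6.3,
                        nearscan_like = 5.4, custom = config$score_scale)
    shift_lat <- if (par_scale > 0)
      config$confound_score_shift / par_scale else 0
    z_pat <- primary$latent + shift_lat * cvec
    obs_primary <- clip(primary$observed + config$confound_score_shift * cvec,
                        config$score_bounds[1], config$score_bounds[2])
    screen <- if (config$score_model == "screen_like") obs_primary
              else sc_screen$observed
    near <- if (config$score_model == "nearscan_like") obs_primary
            else sc_near$observed
    if (config$score_model == "custom") screen <- obs_primary
    vols <- vector("list", n)
    for (i in seq_len(n)) {
      noise <- array(0, dim = d)
      if (config$noise_sd > 0) {
        white <- array(rnorm(prod(d)), dim = d)
        sm <- smooth_gaussian_3d(white, sigma_vox)
        noise <- config$noise_sd * sm$arr / sqrt(sm$var_scale)
      }
      x <- z_pat[i] * w + config$confound_pattern_gain * cvec[i] * w_c + noise
      x[!mask] <- NA_real_
      if (config$nan_rate > 0) {
        inside <- which(mask)
        hit <- inside[runif(length(inside)) < config$nan_rate]
        x[hit] <- NA_real_
      }
      vols[[i]] <- x
    }
    list(z_pat = z_pat, cvec = cvec, screen = screen, near = near,
         vols = vols)
  })

  ids <- sprintf("sub-%03d", seq_len(n))
  vol_paths <- file.path(out_dir, paste0(ids, "_beta.nii.gz"))
  names(vol_paths) <- ids
  for (i in seq_len(n))
    write_volume(gt$vols[[i]], vol_paths[i], affine = affine)

  subjects <- data.frame(subject_id = ids,
                         score_screen = gt$screen,
                         score_nearscan = gt$near,
                         confound = gt$cvec)
  subjects_path <- file.path(out_dir, "subjects.csv")
  write.csv(subjects, subjects_path, row.names = FALSE, quote = FALSE)

  mask_path <- file.path(out_dir, "mask.nii.gz")
  write_volume(array(as.numeric(mask), dim = d), mask_path, affine = affine)

  atlas <- config_atlas(config)
  atlas_path <- file.path(out_dir, "atlas.nii.gz")
  write_volume(atlas, atlas_path, affine = affine)
  labs <- sort(unique(as.integer(atlas[atlas > 0])))
  labels <- data.frame(label_value = labs,
                       region_name = sprintf("region_%02d", labs))
  labels_path <- file.path(out_dir, "atlas_labels.tsv")
  utils::write.table(labels, labels_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  weights_path <- file.path(out_dir, "true_weights.nii.gz")
  write_volume(w, weights_path, affine = affine)

  gt_path <- file.path(out_dir, "ground_truth.csv")
  write.csv(data.frame(subject_id = ids, latent_score = gt$z_pat,
                       confound = gt$cvec),
            gt_path, row.names = FALSE, quote = FALSE)

  config_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), config_path)

  invisible(list(
    paths = list(volumes = vol_paths, subjects = subjects_path,
                 mask = mask_path, atlas = atlas_path,
                 atlas_labels = labels_path, true_weights = weights_path,
                 ground_truth = gt_path, config = config_path,
                 out_dir = out_dir),
    subjects = subjects,
    ground_truth = list(weight_volume = w, confound_weight_volume = w_c,
                        latent_scores = gt$z_pat, confound_vector = gt$cvec)))
}
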