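#' Validate a pipeline run configuration
#'
#' A run configuration has three sections: `paths` (out_dir and, when not
#' produced by the simulate stage, volumes_dir / subjects_csv / mask / atlas
#' / atlas_labels), `analysis` (score_column, scheme `"loo"` or `"kfold"`,
#' k, seed, control_confound, n_perm, rvr options), and `generator` (a
#' [generator_config()] argument list for the simulate stage).  Unknown keys
#' anywhere are rejected.
#'
#' @param config Nested list, or path to a YAML file holding one.
#' @return The resolved config (class `run_config`), defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  allowed_top <- c("paths", "analysis", "generator")
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0)
      stop("unknown ", where, " key(s): ", paste(bad, collapse = ", "))
  }
  check_keys(config, allowed_top, "config")
  paths <- config$paths
  check_keys(paths, c("out_dir", "volumes_dir", "subjects_csv", "mask",
                      "atlas", "atlas_labels", "weight_map"), "paths")
  if (is.null(paths$out_dir)) stop("paths$out_dir is required")
  analysis <- config$analysis
  check_keys(analysis, c("score_column", "scheme", "k", "seed",
                         "control_confound", "n_perm", "rvr",
                         "alpha"), "analysis")
  defaults <- list(score_column = "score_screen", scheme = "loo", k = 4L,
                   seed = 1L, control_confound = FALSE, n_perm = 1000L,
                   rvr = list(), alpha = 0.05)
  analysis <- utils::modifyList(defaults, if (is.null(analysis)) list()
                                          else analysis)
  analysis$scheme <- match.arg(analysis$scheme, c("loo", "kfold"))
  gen <- config$generator
  if (!is.null(gen)) {
    gen_cfg <- do.call(generator_config, gen)  # validates keys and values
    gen <- unclass(gen_cfg)
  }
  structure(list(paths = paths, analysis = analysis, generator = gen),
            class = "run_config")
}

write_manifest <- function(stage, out_dir, config, inputs) {
  inputs <- inputs[file.exists(unlist(inputs))]
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("rvrdecode")),
    seed = config$analysis$seed,
    inputs = lapply(inputs, function(p) unname(tools::md5sum(p))),
    config = list(analysis = config$analysis,
                  generator = config$generator))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

pipeline_dataset <- function(config) {
  p <- config$paths
  for (f in c("volumes_dir", "subjects_csv"))
    if (is.null(p[[f]])) stop("paths$", f, " is required for this stage")
  subjects <- read.csv(p$subjects_csv, stringsAsFactors = FALSE)
  vol_paths <- file.path(p$volumes_dir,
                         paste0(subjects$subject_id, "_beta.nii.gz"))
  names(vol_paths) <- subjects$subject_id
  missing <- vol_paths[!file.exists(vol_paths)]
  if (length(missing) > 0)
    stop("missing coefficient volume(s): ", paste(missing, collapse = ", "))
  base_mask <- if (!is.null(p$mask)) read_volume(p$mask)$data else NULL
  mask <- build_common_mask(unname(vol_paths), base_mask = base_mask)
  assemble_dataset(vol_paths, subjects, config$analysis$score_column, mask)
}

pipeline_scheme <- function(config, dataset) {
  a <- config$analysis
  if (a$scheme == "loo") make_loo(nrow(dataset$X))
  else make_kfold(dataset$scores, a$k, seed = a$seed)
}

#' Run the full synthetic-study decoding pipeline
#'
#' Orchestrates `simulate` (synthetic study on disk), `decode`
#' (cross-validated RVR decoding; writes predictions CSV, summary JSON and
#' the weight-map NIfTI), `permtest` (label-permutation significance;
#' writes summary JSON and the null-distribution CSV) and `localize`
#' (atlas-based region ranking; writes the ranking CSV and a region-value
#' NIfTI).  Every stage writes a manifest (input MD5s, seed, package
#' version) so a run can be reproduced from its output directory alone;
#' re-running an unchanged config is idempotent.
#'
#' @param config A [run_config()] (or list / YAML path coercible to one).
#' @param stages Subset of `c("simulate", "decode", "permtest",
#'   "localize")`, in pipeline order.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of per-stage results.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "decode", "permtest",
                                    "localize"),
                         quiet = FALSE) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  say <- function(...) if (!quiet) message(...)
  out_dir <- config$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(paths = config$paths, analysis = config$analysis,
                        generator = config$generator),
                   file.path(out_dir, "config_resolved.yaml"))
  results <- list()

  if ("simulate" %in% stages) {
    if (is.null(config$generator))
      stop("the simulate stage needs a generator section")
    study_dir <- if (!is.null(config$paths$volumes_dir))
      config$paths$volumes_dir else file.path(out_dir, "study")
    say("simulate: writing synthetic study to ", study_dir)
    study <- generate_study(do.call(generator_config, config$generator),
                            study_dir)
    config$paths$volumes_dir <- study_dir
    config$paths$subjects_csv <- study$paths$subjects
    if (is.null(config$paths$mask)) config$paths$mask <- study$paths$mask
    if (is.null(config$paths$atlas)) config$paths$atlas <- study$paths$atlas
    if (is.null(config$paths$atlas_labels))
      config$paths$atlas_labels <- study$paths$atlas_labels
    write_manifest("simulate", out_dir, config,
                   list(subjects = study$paths$subjects))
    results$simulate <- study
  }

  needs_data <- any(c("decode", "permtest") %in% stages)
  if (needs_data) {
    dataset <- pipeline_dataset(config)
    say(sprintf("data: %d subjects x %d voxels (%d voxels excluded by the NaN rule)",
                nrow(dataset$X), ncol(dataset$X), dataset$mask$n_excluded))
  }

  if ("decode" %in% stages) {
    scheme <- pipeline_scheme(config, dataset)
    say("decode: ", scheme$kind, " cross-validation on ",
        config$analysis$score_column)
    dec <- run_decoding(dataset, scheme,
                        control_confound = config$analysis$control_confound,
                        rvr_options = config$analysis$rvr)
    write.csv(data.frame(subject_id = dataset$subject_ids,
                         y_true = dec$y_true, y_pred = dec$y_pred),
              file.path(out_dir, "predictions.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(r = dec$r, mse = dec$mse, scheme = scheme$kind, k = scheme$k,
           control_confound = config$analysis$control_confound,
           score_column = config$analysis$score_column,
           mean_fold_r = dec$mean_fold_r,
           mean_fold_mse = dec$mean_fold_mse),
      file.path(out_dir, "decoding_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    wm_path <- file.path(out_dir, "weight_map.nii.gz")
    write_volume(vector_to_volume(dec$weight_map, dataset$mask), wm_path,
                 affine = dataset$mask$affine)
    config$paths$weight_map <- wm_path
    write_manifest("decode", out_dir, config,
                   list(subjects = config$paths$subjects_csv))
    say(sprintf("decode: r = %.3f, MSE = %.3f", dec$r, dec$mse))
    results$decode <- dec
  }

  if ("permtest" %in% stages) {
    a <- config$analysis
    say("permtest: ", a$n_perm, " permutations")
    perm <- permutation_test(
      dataset,
      scheme_spec = list(kind = a$scheme, k = a$k, seed = a$seed),
      control_confound = a$control_confound, n_perm = a$n_perm,
      seed = a$seed, rvr_options = a$rvr)
    jsonlite::write_json(summarize_permutation(perm, a$alpha),
                         file.path(out_dir, "permtest_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(data.frame(null_r = perm$null_r, null_mse = perm$null_mse),
              file.path(out_dir, "null_distribution.csv"),
              row.names = FALSE)
    write_manifest("permtest", out_dir, config,
                   list(subjects = config$paths$subjects_csv))
    say(sprintf("permtest: p_r = %.4g, p_mse = %.4g", perm$p_r, perm$p_mse))
    results$permtest <- perm
  }

  if ("localize" %in% stages) {
    p <- config$paths
    if (is.null(p$weight_map))
      stop("localize needs a weight map: run decode first or set ",
           "paths$weight_map")
    for (f in c("atlas", "atlas_labels"))
      if (is.null(p[[f]])) stop("paths$", f, " is required for localize")
    if (!needs_data) {
      dataset <- pipeline_dataset(config)
    }
    mask <- dataset$mask
    wm <- volume_to_vector(read_volume(p$weight_map)$data, mask)
    atlas <- load_atlas(p$atlas, p$atlas_labels, mask)
    ranking <- rank_regions(region_normalized_weights(wm, mask, atlas))
    write.csv(as.data.frame(ranking),
              file.path(out_dir, "region_ranking.csv"), row.names = FALSE)
    write_volume(region_value_volume(ranking, mask, atlas),
                 file.path(out_dir, "region_pct_nw.nii.gz"),
                 affine = mask$affine)
    write_manifest("localize", out_dir, config,
                   list(weight_map = p$weight_map, atlas = p$atlas))
    say(sprintf("localize: %d regions ranked; top region %s (%.2f%% of NW)",
                nrow(ranking), ranking$region_name[1],
                ranking$pct_total_nw[1]))
    results$localize <- ranking
  }

  invisible(results)
}
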