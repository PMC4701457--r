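#' Average per-fold weights into the final weight map
#'
#' The final voxel weight map is the elementwise mean of the per-fold primal
#' weight vectors divided by its Euclidean norm (so reported maps are on a
#' common unit-norm scale).
#'
#' @param per_fold_weights List of equal-length numeric vectors, one per
#'   fold.
#' @return Length-V vector with `||.||_2 = 1`, or all zeros (with a warning)
#'   when every fold weight is zero.
#' @export
average_weight_map <- function(per_fold_weights) {
  if (length(per_fold_weights) == 0) stop("need at least one fold")
  V <- length(per_fold_weights[[1]])
  if (!all(lengths(per_fold_weights) == V))
    stop("per-fold weight vectors differ in length")
  m <- Reduce(`+`, per_fold_weights) / length(per_fold_weights)
  nrm <- sqrt(sum(m^2))
  if (nrm == 0) {
    warning("all per-fold weights are zero; returning a zero weight map")
    return(m)
  }
  m / nrm
}

#' Load a labelled atlas onto the analysis grid
#'
#' Reads an integer-valued label volume and its label lookup TSV
#' (`label_value<TAB>region_name`).  The volume must already be on the
#' analysis grid: no resampling is performed, a grid mismatch is an error.
#' Labels present in the volume but missing from the TSV are auto-named
#' `label_<value>` with a warning; regions whose intersection with the
#' analysis mask is empty are dropped with a warning.
#'
#' @param label_nifti_path Path to the label NIfTI.
#' @param label_tsv_path Path to the two-column TSV.
#' @param mask A `mask_volume`.
#' @param background_value Label treated as background (default 0).
#' @return Object of class `atlas_label_map`: `label_volume` (integer
#'   array), `labels` (named character vector, names = label values),
#'   `background_value`, `dropped_regions`.
#' @export
load_atlas <- function(label_nifti_path, label_tsv_path, mask,
                       background_value = 0L) {
  stopifnot(inherits(mask, "mask_volume"))
  vol <- read_volume(label_nifti_path)$data
  if (!identical(dim(vol), mask$grid_shape))
    stop("atlas grid does not match the analysis mask; resampling is not ",
         "supported")
  if (max(abs(vol - round(vol)), na.rm = TRUE) > 1e-6)
    stop("atlas volume is not integer-valued")
  vol <- array(as.integer(round(vol)), dim = dim(vol))
  tsv <- read.delim(label_tsv_path, header = TRUE,
                    stringsAsFactors = FALSE)
  if (ncol(tsv) < 2)
    stop("label TSV needs columns label_value and region_name")
  labels <- as.character(tsv[[2]])
  names(labels) <- as.character(as.integer(tsv[[1]]))
  present <- sort(unique(vol[vol != background_value & !is.na(vol)]))
  missing <- setdiff(as.character(present), names(labels))
  if (length(missing) > 0) {
    warning("label(s) missing from the TSV, auto-named: ",
            paste(missing, collapse = ", "))
    auto <- paste0("label_", missing)
    names(auto) <- missing
    labels <- c(labels, auto)
  }
  in_mask <- vol[mask$include]
  counts <- table(factor(in_mask[in_mask != background_value],
                         levels = present))
  dropped <- present[counts == 0]
  if (length(dropped) > 0)
    warning(length(dropped), " region(s) have no voxels inside the ",
            "analysis mask and are dropped: ",
            paste(labels[as.character(dropped)], collapse = ", "))
  structure(list(label_volume = vol,
                 labels = labels[as.character(setdiff(present, dropped))],
                 background_value = as.integer(background_value),
                 dropped_regions = labels[as.character(dropped)]),
            class = "atlas_label_map")
}

#' Per-region normalized weights
#'
#' For each atlas region `g` with masked voxel set `S_g`, the normalized
#' weight is the mean absolute voxel weight
#' `NW(g) = sum_{v in S_g} |w_v| / |S_g|` — the region sum normalized by the
#' number of (masked) voxels in the region.  Background and out-of-mask
#' voxels never contribute.
#'
#' @param weight_map Length-V numeric vector on the mask's feature order.
#' @param mask A `mask_volume`.
#' @param atlas An `atlas_label_map` on the same grid.
#' @return Data frame with `region_name`, `label_value`, `n_voxels`,
#'   `mean_abs_weight`.
#' @export
region_normalized_weights <- function(weight_map, mask, atlas) {
  stopifnot(inherits(mask, "mask_volume"),
            inherits(atlas, "atlas_label_map"))
  if (length(weight_map) != mask$V)
    stop("weight_map length does not match the mask")
  if (!identical(dim(atlas$label_volume), mask$grid_shape))
    stop("atlas grid does not match the analysis mask")
  lab <- atlas$label_volume[mask$include]
  keep_vals <- as.integer(names(atlas$labels))
  sel <- lab %in% keep_vals
  if (!any(sel)) stop("no atlas region overlaps the analysis mask")
  f <- factor(lab[sel], levels = keep_vals)
  nv <- as.integer(table(f))
  sums <- as.numeric(tapply(abs(weight_map[sel]), f, sum, default = 0))
  data.frame(region_name = unname(atlas$labels),
             label_value = keep_vals,
             n_voxels = nv,
             mean_abs_weight = sums / nv,
             stringsAsFactors = FALSE)
}

#' Rank regions by their share of the total normalized weights
#'
#' Each region's percentage is `100 * NW(g) / sum_h NW(h)`; regions are
#' ranked by descending percentage (ties broken by region name) and a
#' cumulative percentage is attached, enabling statements like "the top 20
#' regions carry X% of the total normalized weights".
#'
#' @param nw_table Data frame from [region_normalized_weights()].
#' @return Object of class `region_ranking` (a data frame) with `rank`,
#'   `region_name`, `label_value`, `n_voxels`, `mean_abs_weight`,
#'   `pct_total_nw`, `cumulative_pct`; empty (with a warning) when all
#'   weights are zero.
#' @export
rank_regions <- function(nw_table) {
  total <- sum(nw_table$mean_abs_weight)
  if (total == 0) {
    warning("all region weights are zero; returning an empty ranking")
    out <- nw_table[0, , drop = FALSE]
    out$rank <- integer(0)
    out$pct_total_nw <- numeric(0)
    out$cumulative_pct <- numeric(0)
    class(out) <- c("region_ranking", class(out))
    return(out)
  }
  pct <- 100 * nw_table$mean_abs_weight / total
  ord <- order(-pct, nw_table$region_name)
  out <- nw_table[ord, , drop = FALSE]
  out$pct_total_nw <- pct[ord]
  out$cumulative_pct <- cumsum(out$pct_total_nw)
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("region_ranking", class(out))
  out
}

#' Region-value volume for visualization
#'
#' Builds a 3D volume in which every masked voxel carries its region's share
#' of the total normalized weights (background elsewhere), the region-level
#' counterpart of the voxel weight map.
#'
#' @param ranking A `region_ranking`.
#' @param mask A `mask_volume`.
#' @param atlas The `atlas_label_map` the ranking was computed from.
#' @return Numeric 3D array.
#' @export
region_value_volume <- function(ranking, mask, atlas) {
  stopifnot(inherits(ranking, "region_ranking"),
            inherits(mask, "mask_volume"),
            inherits(atlas, "atlas_label_map"))
  vol <- array(0, dim = mask$grid_shape)
  lut <- stats::setNames(ranking$pct_total_nw,
                         as.character(ranking$label_value))
  lab <- atlas$label_volume[mask$include]
  vals <- lut[as.character(lab)]
  vals[is.na(vals)] <- 0
  vol[mask$include] <- vals
  vol
}
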