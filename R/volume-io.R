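#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti keeping the array and its affine together.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume()`: a list with `data` (numeric 3D array) and
#'   `affine` (4 x 4 voxel-to-world transform).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d)) d <- length(img)
  d <- c(d, rep(1L, max(0L, 3L - length(d))))  # keep singleton axes
  list(data = array(as.numeric(img), dim = d),
       affine = unclass(RNifti::xform(img)))
}

#' @rdname read_volume
#' @param data Numeric 3D array to write.
#' @param affine Optional 4 x 4 voxel-to-world transform (default: identity
#'   scaled to 1 mm voxels as RNifti provides).
#' @export
write_volume <- function(data, path, affine = NULL) {
  img <- RNifti::asNifti(data)
  if (!is.null(affine)) {
    stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
    RNifti::qform(img) <- structure(affine, code = 2L)
    RNifti::sform(img) <- structure(affine, code = 2L)
  }
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

load_volume_list <- function(volumes) {
  if (is.character(volumes)) volumes <- lapply(volumes, read_volume)
  lapply(volumes, function(v) {
    if (is.list(v) && !is.null(v$data)) v
    else list(data = array(as.numeric(v), dim = dim(v)), affine = NULL)
  })
}

#' Build the analysis mask by the NaN-intersection rule
#'
#' A voxel enters the analysis only if it is finite in *every* subject's
#' coefficient volume (voxels with a NaN in at least one participant are
#' excluded) and, when given, lies inside `base_mask`.  Feature columns are
#' ordered by a fixed axis-priority scan of the retained voxels (first axis
#' fastest), so weight maps are reproducible across runs.
#'
#' @param volumes List of 3D arrays, list of `read_volume()` results, or a
#'   character vector of NIfTI paths.  All must share the grid shape; when
#'   affines are available they must agree within 1e-4 per entry (volumes
#'   are never resampled).
#' @param base_mask Optional logical/0-1 3D array restricting the mask.
#' @return An object of class `mask_volume`: `grid_shape`, `affine`,
#'   `include` (logical array), `V` (number of features), `n_excluded`
#'   (voxels removed by the NaN rule within the base mask).
#' @export
build_common_mask <- function(volumes, base_mask = NULL) {
  vols <- load_volume_list(volumes)
  if (length(vols) == 0) stop("no volumes supplied")
  d <- dim(vols[[1]]$data)
  if (length(d) != 3) stop("volumes must be 3D")
  affine <- vols[[1]]$affine
  for (i in seq_along(vols)) {
    if (!identical(dim(vols[[i]]$data), d))
      stop("volume ", i, " has a different grid shape")
    ai <- vols[[i]]$affine
    if (!is.null(affine) && !is.null(ai) && max(abs(ai - affine)) > 1e-4)
      stop("volume ", i, " has a mismatching affine (tolerance 1e-4); ",
           "volumes are never resampled")
  }
  if (is.null(base_mask)) {
    base <- array(TRUE, dim = d)
  } else {
    if (!identical(dim(base_mask), d))
      stop("base_mask grid shape does not match the volumes")
    base <- array(as.logical(base_mask != 0), dim = d)
  }
  finite_all <- array(TRUE, dim = d)
  for (v in vols) finite_all <- finite_all & is.finite(v$data)
  include <- base & finite_all
  if (!any(include))
    stop("empty analysis mask: every voxel has a non-finite value in at ",
         "least one subject (or the base mask is empty)")
  structure(list(grid_shape = d, affine = affine, include = include,
                 V = sum(include), n_excluded = sum(base & !finite_all)),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("Analysis mask: %d x %d x %d grid, %d voxels retained (%d excluded by the NaN rule)\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$V, x$n_excluded))
  invisible(x)
}

#' Assemble the subject-by-voxel dataset
#'
#' Extracts masked voxel values from one coefficient volume per subject into
#' an N x V matrix whose row order follows the subjects table (not file
#' order) and whose column order is the mask's fixed voxel scan.
#'
#' @param volume_paths Character vector of NIfTI paths, named by
#'   `subject_id` (or unnamed and aligned with the table rows).
#' @param subjects_table Data frame with columns `subject_id`, `confound`
#'   (strictly 0/1) and the score column.
#' @param score_column Name of the score column to decode.
#' @param mask A `mask_volume` from [build_common_mask()].
#' @return An object of class `subject_dataset`: `X` (N x V, NaN-free),
#'   `scores`, `score_name`, `confound`, `subject_ids`, `mask`.
#' @export
assemble_dataset <- function(volume_paths, subjects_table, score_column,
                             mask) {
  stopifnot(inherits(mask, "mask_volume"))
  tab <- as.data.frame(subjects_table)
  if (!"subject_id" %in% names(tab)) stop("subjects table needs subject_id")
  if (!score_column %in% names(tab))
    stop("score column not found: ", score_column)
  if (!"confound" %in% names(tab)) stop("subjects table needs confound")
  n <- nrow(tab)
  if (!is.null(names(volume_paths))) {
    missing <- setdiff(tab$subject_id, names(volume_paths))
    if (length(missing) > 0)
      stop("no volume for subject(s): ", paste(missing, collapse = ", "))
    volume_paths <- volume_paths[as.character(tab$subject_id)]
  } else if (length(volume_paths) != n) {
    stop("unnamed volume_paths must match the table row-for-row")
  }
  scores <- tab[[score_column]]
  if (!is.numeric(scores) || anyNA(scores))
    stop("scores must be numeric and complete")
  confound <- tab$confound
  if (!all(confound %in% c(0, 1)))
    stop("confound must contain only 0/1 values")
  X <- matrix(NA_real_, n, mask$V)
  for (i in seq_len(n)) {
    v <- read_volume(volume_paths[i])
    if (!identical(dim(v$data), mask$grid_shape))
      stop("volume for ", tab$subject_id[i], " is not on the mask grid")
    X[i, ] <- v$data[mask$include]
  }
  if (!all(is.finite(X)))
    stop("non-finite values inside the mask; build the mask from these ",
         "volumes with build_common_mask()")
  structure(list(X = X, scores = as.numeric(scores),
                 score_name = score_column,
                 confound = as.integer(confound),
                 subject_ids = as.character(tab$subject_id), mask = mask),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("Subject dataset: %d subjects x %d voxels (score: %s; %d confounded)\n",
              nrow(x$X), ncol(x$X), x$score_name, sum(x$confound)))
  invisible(x)
}

#' Build a subject dataset directly from a feature matrix
#'
#' Convenience constructor for simulation studies that never touch disk: the
#' rows of `X` become the subjects and, unless a mask is supplied, the
#' features are laid out on a synthetic `V x 1 x 1` grid.
#'
#' @param X Numeric N x V matrix, finite.
#' @param scores Numeric score vector of length N.
#' @param confound Binary confound vector of length N (default all 0).
#' @param score_name Label for the score column.
#' @param mask Optional `mask_volume` with `V` retained voxels.
#' @return A `subject_dataset`.
#' @export
dataset_from_matrix <- function(X, scores, confound = rep(0L, nrow(X)),
                                score_name = "score", mask = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  if (length(scores) != nrow(X)) stop("one score per row of X is required")
  if (length(confound) != nrow(X) || !all(confound %in% c(0, 1)))
    stop("confound must be a binary vector with one entry per row")
  if (is.null(mask)) {
    d <- c(ncol(X), 1L, 1L)
    mask <- structure(list(grid_shape = d, affine = diag(4),
                           include = array(TRUE, dim = d),
                           V = ncol(X), n_excluded = 0L),
                      class = "mask_volume")
  }
  if (mask$V != ncol(X)) stop("mask retains ", mask$V, " voxels but X has ",
                              ncol(X), " columns")
  structure(list(X = X, scores = as.numeric(scores), score_name = score_name,
                 confound = as.integer(confound),
                 subject_ids = sprintf("sub-%03d", seq_len(nrow(X))),
                 mask = mask),
            class = "subject_dataset")
}

#' Map a feature vector back onto the voxel grid
#'
#' Inverse of the masking step: `volume[coord] = w[voxel_index(coord)]`
#' inside the mask, 0 outside.
#'
#' @param w Numeric vector of length `mask$V`.
#' @param mask A `mask_volume`.
#' @return Numeric 3D array.
#' @export
vector_to_volume <- function(w, mask) {
  stopifnot(inherits(mask, "mask_volume"))
  if (length(w) != mask$V)
    stop("w has length ", length(w), " but the mask retains ", mask$V,
         " voxels")
  vol <- array(0, dim = mask$grid_shape)
  vol[mask$include] <- w
  vol
}

#' @rdname vector_to_volume
#' @param volume Numeric 3D array on the mask grid.
#' @export
volume_to_vector <- function(volume, mask) {
  stopifnot(inherits(mask, "mask_volume"))
  if (!identical(dim(volume), mask$grid_shape))
    stop("volume is not on the mask grid")
  as.numeric(volume[mask$include])
}
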