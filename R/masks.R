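#' Binary voxel masks in world coordinates
#'
#' A `voxel_mask` is a binary 3D segmentation grid plus the affine map from
#' voxel indices to millimetre world coordinates. The internal convention is
#' RAS world axes and a 4x4 affine that maps **1-based** voxel indices
#' `(i, j, k, 1)` to world mm, so `voxel_world(mask)` of voxel `(1,1,1)` is
#' the world position of the first voxel centre.
#'
#' @param grid 3D array; values are binarized at > 0.5.
#' @param affine 4x4 matrix mapping 1-based voxel index to world mm.
#' @param allow_empty keep an all-zero grid instead of erroring (used by
#'   resampling, which can legitimately map everything outside the field of
#'   view).
#' @return An object of class `voxel_mask` with elements `grid` (integer 0/1
#'   array), `affine` and `spacing` (mm per voxel along each grid axis).
#' @export
voxel_mask <- function(grid, affine, allow_empty = FALSE) {
  grid <- as.array(grid)
  if (length(dim(grid)) != 3L || any(dim(grid) < 1L)) {
    stop("mask grid must be a non-empty 3D array", call. = FALSE)
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine[1:3, 1:3])) < 1e-12) {
    stop("mask affine is singular", call. = FALSE)
  }
  g <- array(as.integer(grid > 0.5), dim(grid))
  if (!allow_empty && sum(g) == 0L) {
    stop("empty segmentation: mask contains no foreground voxels", call. = FALSE)
  }
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive", call. = FALSE)
  structure(list(grid = g, affine = affine, spacing = spacing),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<voxel_mask> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm, %d foreground (%.1f mm^3)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              sum(x$grid), mask_volume(x)))
  invisible(x)
}

#' Voxel volume and total mask volume
#' @param mask A `voxel_mask`.
#' @return `voxel_volume`: volume of one voxel (mm^3); `mask_volume`: total
#'   foreground volume (mm^3).
#' @export
voxel_volume <- function(mask) abs(det(mask$affine[1:3, 1:3]))

#' @rdname voxel_volume
#' @export
mask_volume <- function(mask) sum(mask$grid) * voxel_volume(mask)

#' World coordinates of foreground voxel centres
#' @param mask A `voxel_mask`.
#' @param which_vox optional n x 3 matrix of 1-based voxel indices; default is
#'   all foreground voxels.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_world <- function(mask, which_vox = NULL) {
  if (is.null(which_vox)) {
    which_vox <- which(mask$grid == 1L, arr.ind = TRUE)
  }
  if (nrow(which_vox) == 0L) {
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  w <- cbind(which_vox, 1) %*% t(mask$affine)
  colnames(w) <- c("x", "y", "z", "h")
  w[, 1:3, drop = FALSE]
}

# world mm -> zero-based continuous voxel coordinates (for Rcpp samplers)
world_to_voxel0 <- function(mask, pts) {
  inv <- solve(mask$affine)
  v <- cbind(pts, 1) %*% t(inv)
  v[, 1:3, drop = FALSE] - 1
}

#' Read a NIfTI binary mask
#'
#' Loads a NIfTI segmentation, binarizes at > 0.5 and canonicalises the grid
#' to RAS axis order so the internal frame is +X right, +Y anterior,
#' +Z superior. World coordinates are unchanged by the reorientation.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [voxel_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("mask file not found: %s", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("unreadable NIfTI file '%s': %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  if (attr(RNifti::xform(img), "code") > 0L) RNifti::orientation(img) <- "RAS"
  aff0 <- structure(RNifti::xform(img), imagedim = NULL, code = NULL) # 0-based index -> world
  aff0 <- matrix(as.numeric(aff0), 4, 4)
  # shift to 1-based voxel indices
  aff <- aff0
  aff[1:3, 4] <- aff0[1:3, 4] - aff0[1:3, 1:3] %*% c(1, 1, 1)
  voxel_mask(array(as.numeric(img), dim(img)), aff)
}

#' Write a mask as NIfTI
#' @param mask A `voxel_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  aff0 <- mask$affine
  aff0[1:3, 4] <- aff0[1:3, 4] + mask$affine[1:3, 1:3] %*% c(1, 1, 1)
  img <- RNifti::asNifti(array(as.integer(mask$grid), dim(mask$grid)))
  RNifti::sform(img) <- structure(aff0, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Apply a rigid transform to landmarks or a mask
#'
#' Landmarks are mapped exactly. Masks are resampled by nearest neighbour
#' onto the original grid: the output grid holds, at each voxel centre `p`,
#' the input value at `t^-1(p)`, which preserves binarity.
#'
#' @param x A [landmark_set()] or [voxel_mask()].
#' @param t A [rigid_transform()].
#' @param frame optional new frame tag for landmark sets.
#' @return An object of the same type as `x`.
#' @export
apply_transform <- function(x, t, frame = NULL) {
  UseMethod("apply_transform")
}

#' @export
apply_transform.landmark_set <- function(x, t, frame = NULL) {
  pts <- rt_apply(t, x$points)
  rownames(pts) <- rownames(x$points)
  landmark_set(pts, frame = frame %||% x$frame,
               patient_id = x$patient_id, timepoint = x$timepoint)
}

#' @export
apply_transform.voxel_mask <- function(x, t, frame = NULL) {
  d <- dim(x$grid)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3])))
  w <- voxel_world(x, idx)
  src <- rt_apply(rt_invert(t), w)
  v0 <- world_to_voxel0(x, src)
  vals <- .nearest_sample(as.numeric(x$grid), dim(x$grid), v0)
  voxel_mask(array(vals, d), x$affine, allow_empty = TRUE)
}

#' Move a mask exactly by updating its affine
#'
#' Re-expresses the mask in a new frame by composing the rigid transform
#' into the voxel-to-world affine. Unlike [apply_transform()], this loses no
#' information (no resampling) and works for arbitrarily large motions; the
#' resulting grid axes are generally no longer aligned with the world axes,
#' which all measurement code supports. Used by the pipeline to carry masks
#' into the oriented, registered frame.
#'
#' @param mask A [voxel_mask()].
#' @param t A [rigid_transform()].
#' @return A [voxel_mask()] with identical grid and updated affine.
#' @export
transform_grid <- function(mask, t) {
  voxel_mask(mask$grid, rt_as_matrix(t) %*% mask$affine, allow_empty = TRUE)
}

#' Jaccard overlap of two masks on a shared grid
#' @param a,b `voxel_mask` objects with identical grids/affines.
#' @return Jaccard index in `[0, 1]`.
#' @export
mask_jaccard <- function(a, b) {
  stopifnot(all(dim(a$grid) == dim(b$grid)))
  inter <- sum(a$grid & b$grid)
  uni <- sum(a$grid | b$grid)
  if (uni == 0) return(1)
  inter / uni
}
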