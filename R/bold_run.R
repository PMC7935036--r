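#' Masked BOLD run container
#'
#' A `bold_run` holds the in-mask voxel-by-time signal matrix of one fMRI run
#' (or of a concatenation of runs) together with its spatial metadata. Rows
#' are in-mask voxels in a fixed linearization (see [mask_index_table()]),
#' columns are time frames.
#'
#' @param data numeric matrix, one row per in-mask voxel, one column per frame.
#' @param mask 3D array (logical or 0/1) marking in-mask voxels.
#' @param affine 4x4 voxel-to-world (MNI mm) transform; maps 0-based (i,j,k,1)
#'   to (x,y,z,1) in mm, the NIfTI convention.
#' @param tr_seconds repetition time in seconds.
#' @param run_id opaque run label.
#' @param boundaries 0-based start frames of the constituent runs inside the
#'   concatenation (a single run has `boundaries = 0`).
#'
#' @return An object of class `bold_run` with elements `data`, `mask`,
#'   `affine`, `tr_seconds`, `run_id`, `boundaries`.
#' @export
bold_run <- function(data, mask, affine, tr_seconds = NA_real_,
                     run_id = "run", boundaries = 0L) {
  data <- as.matrix(data)
  mask <- check_mask(mask)
  if (!is.matrix(affine) || !identical(dim(affine), c(4L, 4L))) {
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  }
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12) {
    stop("`affine` must be invertible", call. = FALSE)
  }
  n_vox <- sum(mask != 0)
  if (nrow(data) != n_vox) {
    stop(sprintf("data has %d rows but mask has %d voxels", nrow(data), n_vox),
         call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("non-finite values inside the mask", call. = FALSE)
  }
  structure(
    list(data = data, mask = mask, affine = affine,
         tr_seconds = tr_seconds, run_id = run_id,
         boundaries = as.integer(boundaries)),
    class = "bold_run"
  )
}

check_mask <- function(mask) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array", call. = FALSE)
  mask <- array(as.numeric(mask != 0), dim = dim(mask))
  if (sum(mask) < 1) stop("mask contains no voxels", call. = FALSE)
  mask
}

#' In-mask voxel linearization
#'
#' Returns the (i,j,k) array indices of the in-mask voxels in the fixed row
#' order used throughout the package: C-order over (i,j,k), i.e. k varies
#' fastest, then j, then i. Indices are 1-based R array subscripts; subtract 1
#' for the NIfTI 0-based voxel convention.
#'
#' @param mask 3D array marking in-mask voxels.
#' @return integer matrix with one row per in-mask voxel and columns i, j, k.
#' @export
mask_index_table <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  colnames(idx) <- c("i", "j", "k")
  idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
}

# linear (Fortran) positions of the C-ordered mask voxels inside the array
mask_linear_positions <- function(mask) {
  d <- dim(mask)
  idx <- mask_index_table(mask)
  idx[, 1] + (idx[, 2] - 1L) * d[1] + (idx[, 3] - 1L) * d[1] * d[2]
}

#' Extract in-mask values from a 3D volume
#'
#' @param volume 3D array on the mask's grid.
#' @param mask 3D mask array.
#' @return numeric vector, one value per in-mask voxel in the package's
#'   fixed voxel order.
#' @export
mask_volume <- function(volume, mask) {
  if (!identical(dim(volume)[1:3], dim(mask))) {
    stop("volume and mask grids differ", call. = FALSE)
  }
  volume[mask_linear_positions(mask)]
}

#' Embed an in-mask vector back into a 3D volume
#'
#' Inverse of [mask_volume()]: values are placed at the mask voxels, zero
#' elsewhere.
#'
#' @param values numeric vector, one value per in-mask voxel.
#' @param mask 3D mask array.
#' @return 3D array with the mask's dimensions.
#' @export
unmask_volume <- function(values, mask) {
  pos <- mask_linear_positions(mask)
  if (length(values) != length(pos)) {
    stop("length of values does not match the mask voxel count", call. = FALSE)
  }
  vol <- array(0, dim = dim(mask))
  vol[pos] <- values
  vol
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run '%s'> %d in-mask voxels x %d frames, TR = %s s, %d run(s)\n",
              x$run_id, nrow(x$data), ncol(x$data),
              format(x$tr_seconds), length(x$boundaries)))
  invisible(x)
}

#' Number of frames in a run
#' @param run a `bold_run`.
#' @return integer frame count.
#' @export
n_frames <- function(run) ncol(run$data)

#' Number of in-mask voxels in a run
#' @param run a `bold_run`.
#' @return integer voxel count.
#' @export
n_voxels <- function(run) nrow(run$data)
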