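#' Load a 4D BOLD run with a brain mask
#'
#' Reads a 4D NIfTI-1 volume and a 3D binary mask on the same grid and
#' returns the masked voxel-by-time matrix. Voxel rows follow the fixed
#' linearization of [mask_index_table()].
#'
#' @param bold_path path to a 4D NIfTI (.nii or .nii.gz).
#' @param mask_path path to a 3D binary NIfTI on the same grid.
#' @param tr_seconds repetition time in seconds; defaults to the time pixdim
#'   recorded in the BOLD header.
#' @param affine_tol maximum absolute elementwise difference tolerated
#'   between the two affines.
#' @return a [bold_run()].
#' @export
load_run <- function(bold_path, mask_path, tr_seconds = NULL,
                     affine_tol = 1e-4) {
  bold <- RNifti::readNifti(bold_path)
  mask_img <- RNifti::readNifti(mask_path)
  bdim <- dim(bold)
  if (length(bdim) == 3L) bdim <- c(bdim, 1L)
  if (length(bdim) != 4L) {
    stop("BOLD image must be 4D (or 3D single-frame)", call. = FALSE)
  }
  mdim <- dim(mask_img)
  if (length(mdim) != 3L || !identical(as.integer(bdim[1:3]), as.integer(mdim))) {
    stop(sprintf("grid mismatch: BOLD %s vs mask %s",
                 paste(bdim[1:3], collapse = "x"),
                 paste(mdim, collapse = "x")), call. = FALSE)
  }
  aff_b <- unclass(RNifti::xform(bold))[1:4, 1:4]
  aff_m <- unclass(RNifti::xform(mask_img))[1:4, 1:4]
  if (max(abs(aff_b - aff_m)) > affine_tol) {
    stop("affine mismatch between BOLD and mask", call. = FALSE)
  }
  mask <- check_mask(array(as.numeric(mask_img), dim = mdim))
  if (is.null(tr_seconds)) {
    pd <- RNifti::pixdim(bold)
    tr_seconds <- if (length(pd) >= 4) pd[4] else NA_real_
  }
  pos <- mask_linear_positions(mask)
  flat <- matrix(as.numeric(bold), nrow = prod(bdim[1:3]), ncol = bdim[4])
  data <- flat[pos, , drop = FALSE]
  if (!all(is.finite(data))) {
    stop("non-finite voxel values inside the mask", call. = FALSE)
  }
  bold_run(data, mask, aff_b, tr_seconds = tr_seconds,
           run_id = basename(bold_path))
}

#' Write an in-mask map as a 3D NIfTI volume
#'
#' Values are placed at mask voxels (package voxel order), zero elsewhere.
#'
#' @param values numeric vector, one value per in-mask voxel.
#' @param mask 3D mask array.
#' @param affine 4x4 voxel-to-mm transform.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
save_map <- function(values, mask, affine, path) {
  mask <- check_mask(mask)
  vol <- unmask_volume(values, mask)
  img <- RNifti::asNifti(vol)
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- vox
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D NIfTI map back into package voxel order
#'
#' @param path path to a 3D NIfTI volume.
#' @param mask 3D mask array on the same grid.
#' @return numeric vector of in-mask values.
#' @export
load_map <- function(path, mask) {
  img <- RNifti::readNifti(path)
  mask_volume(array(as.numeric(img), dim = dim(img)[1:3]), check_mask(mask))
}

#' Standardize voxel time series to zero mean, unit variance
#'
#' Each voxel row is centred and scaled to unit sample variance. Rows with
#' zero variance map to all-zero rows so no NaN can propagate into the
#' downstream clustering.
#'
#' @param run a [bold_run()].
#' @return a standardized `bold_run`.
#' @export
standardize <- function(run) {
  x <- run$data
  if (ncol(x) < 2L) stop("standardization needs at least 2 frames", call. = FALSE)
  m <- rowMeans(x)
  xc <- x - m
  v <- rowSums(xc^2) / (ncol(x) - 1)
  keep <- v > 1e-24
  xc[keep, ] <- xc[keep, , drop = FALSE] / sqrt(v[keep])
  xc[!keep, ] <- 0
  run$data <- xc
  run
}

#' Spatial Gaussian smoothing of a run
#'
#' Each frame is embedded in its 3D volume (zero outside the mask), smoothed
#' with an isotropic Gaussian of the given full width at half maximum in mm
#' (separable truncated kernel, zero padding, no boundary renormalization),
#' and re-masked. `fwhm_mm = 0` returns the input unchanged.
#'
#' @param run a [bold_run()].
#' @param fwhm_mm kernel full width at half maximum in mm (>= 0).
#' @return a smoothed `bold_run`.
#' @export
smooth_run <- function(run, fwhm_mm) {
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) {
    stop("`fwhm_mm` must be >= 0", call. = FALSE)
  }
  if (fwhm_mm == 0) return(run)
  vox <- sqrt(colSums(run$affine[1:3, 1:3]^2))
  sigmas <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox   # sigma in voxels per axis
  pos <- mask_linear_positions(run$mask)
  d <- dim(run$mask)
  out <- run$data
  for (t in seq_len(ncol(out))) {
    vol <- array(0, dim = d)
    vol[pos] <- run$data[, t]
    vol <- gaussian_smooth_volume(vol, sigmas)
    out[, t] <- vol[pos]
  }
  run$data <- out
  run
}

# separable convolution, one truncated normalized kernel per axis, zero padding
gaussian_smooth_volume <- function(vol, sigmas) {
  d <- dim(vol)
  for (axis in 1:3) {
    s <- sigmas[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    kern <- exp(-0.5 * ((-r:r) / s)^2)
    kern <- kern / sum(kern)
    n <- d[axis]
    band <- matrix(0, n, n)
    for (off in -r:r) {
      rows <- seq_len(n)[seq_len(n) + off >= 1 & seq_len(n) + off <= n]
      band[cbind(rows, rows + off)] <- kern[off + r + 1]
    }
    perm <- c(axis, setdiff(1:3, axis))
    v <- aperm(vol, perm)
    dp <- dim(v)
    v <- band %*% matrix(v, nrow = n)
    vol <- aperm(array(v, dim = dp), order(perm))
  }
  vol
}

#' Drop censored frames from a run
#'
#' @param run a [bold_run()].
#' @param censor_mask keep/drop flags, one per frame: logical, or 0/1 with 1
#'   meaning keep.
#' @return a `bold_run` holding the retained frames in their original order.
#' @export
apply_censor <- function(run, censor_mask) {
  keep <- as.logical(censor_mask)
  if (length(keep) != n_frames(run)) {
    stop(sprintf("censor mask has %d entries for %d frames",
                 length(keep), n_frames(run)), call. = FALSE)
  }
  if (anyNA(keep)) stop("censor mask contains NA", call. = FALSE)
  if (!any(keep)) stop("censoring would drop every frame", call. = FALSE)
  run$data <- run$data[, keep, drop = FALSE]
  run$boundaries <- 0L
  run
}

#' Read a censor mask from a single-column TSV of 0/1 flags
#'
#' @param path path to the TSV (no header), one row per frame, 1 = keep.
#' @return logical vector.
#' @export
read_censor_tsv <- function(path) {
  v <- utils::read.table(path, header = FALSE)[[1]]
  if (!all(v %in% c(0, 1))) stop("censor file must contain only 0/1", call. = FALSE)
  as.logical(v)
}

#' Convert an MNI mm coordinate to an in-mask voxel
#'
#' The nearest voxel centre to the MNI point is found through the inverse
#' affine; exact half-way ties round toward the smaller voxel index. If that
#' voxel lies outside the mask, the nearest in-mask voxel by Euclidean mm
#' distance is returned with `snapped = TRUE`; ties go to the smallest voxel
#' row index.
#'
#' @param affine 4x4 voxel-to-mm transform.
#' @param mask 3D mask array.
#' @param mni_mm length-3 MNI coordinate in mm.
#' @param max_snap_mm maximum allowed distance (mm) from the point to any
#'   in-mask voxel centre before an error is raised.
#' @return list with `row` (1-based row index into the masked data matrix),
#'   `ijk` (0-based voxel coordinates), `snapped`, `distance_mm`.
#' @export
mni_to_voxel <- function(affine, mask, mni_mm, max_snap_mm = 10) {
  mask <- check_mask(mask)
  v <- solve(affine, c(mni_mm, 1))[1:3]            # 0-based fractional voxel
  ijk0 <- ceiling(v - 0.5)                          # half-way ties round down
  idx <- mask_index_table(mask)                     # 1-based
  centers_mm <- t(affine[1:3, 1:3] %*% t(idx - 1) + affine[1:3, 4])
  d2 <- colSums((t(centers_mm) - mni_mm)^2)
  nearest <- which.min(d2)                          # first index wins ties
  dist_mm <- sqrt(d2[nearest])
  if (dist_mm > max_snap_mm) {
    stop(sprintf("MNI point is %.1f mm from the nearest in-mask voxel (limit %.1f)",
                 dist_mm, max_snap_mm), call. = FALSE)
  }
  inside <- all(ijk0 >= 0) && all(ijk0 < dim(mask)) &&
    mask[matrix(ijk0 + 1, nrow = 1)] != 0
  if (inside) {
    row <- which(idx[, 1] == ijk0[1] + 1 & idx[, 2] == ijk0[2] + 1 &
                   idx[, 3] == ijk0[3] + 1)
    list(row = row, ijk = as.integer(ijk0), snapped = FALSE,
         distance_mm = sqrt(sum((affine[1:3, 1:3] %*% ijk0 +
                                   affine[1:3, 4] - mni_mm)^2)))
  } else {
    list(row = nearest, ijk = as.integer(idx[nearest, ] - 1L), snapped = TRUE,
         distance_mm = dist_mm)
  }
}

#' Read seed definitions from a JSON file
#'
#' Expects a JSON list of objects `{name, mni_mm}` with `mni_mm` a length-3
#' mm coordinate.
#'
#' @param path path to the JSON file.
#' @return data frame with columns `name`, `x`, `y`, `z`.
#' @export
read_seeds_json <- function(path) {
  seeds <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  do.call(rbind, lapply(seeds, function(s) {
    if (is.null(s$name) || length(s$mni_mm) != 3) {
      stop("each seed needs a `name` and a 3-vector `mni_mm`", call. = FALSE)
    }
    data.frame(name = s$name, x = s$mni_mm[1], y = s$mni_mm[2], z = s$mni_mm[3])
  }))
}

#' Concatenate runs along time
#'
#' Runs must share the mask, affine and TR. Frame order is the given run
#' order; the result records the 0-based start frame of each constituent run
#' so that windows spanning run boundaries can optionally be excluded.
#'
#' @param runs list of [bold_run()] objects.
#' @return a single concatenated `bold_run`.
#' @export
concatenate_runs <- function(runs) {
  if (length(runs) == 0) stop("no runs to concatenate", call. = FALSE)
  if (length(runs) == 1) return(runs[[1]])
  ref <- runs[[1]]
  for (r in runs[-1]) {
    if (!identical(dim(r$mask), dim(ref$mask)) ||
        any((r$mask != 0) != (ref$mask != 0))) {
      stop("runs have different masks", call. = FALSE)
    }
    if (max(abs(r$affine - ref$affine)) > 1e-6) {
      stop("runs have different affines", call. = FALSE)
    }
    if (!isTRUE(all.equal(r$tr_seconds, ref$tr_seconds))) {
      stop("runs have different TR", call. = FALSE)
    }
  }
  lens <- vapply(runs, n_frames, integer(1))
  bold_run(do.call(cbind, lapply(runs, function(r) r$data)),
           ref$mask, ref$affine, tr_seconds = ref$tr_seconds,
           run_id = paste(vapply(runs, function(r) r$run_id, character(1)),
                          collapse = "+"),
           boundaries = cumsum(c(0L, lens[-length(lens)])))
}
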