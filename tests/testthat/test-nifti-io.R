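test_that("loading a masked 4D run keeps shape, values and voxel order", {
  set.seed(11)
  d <- c(10, 10, 10)
  mask <- array(0, dim = d)
  mask[3:7, 3:7, 2:5] <- 1                         # 5*5*4 = 100 voxels
  mask[sample(which(mask == 1), 0)] <- 1
  extra <- sample(which(mask == 0), 300)
  mask[extra] <- 1                                  # 400-voxel mask
  data4d <- array(rnorm(prod(d) * 50), dim = c(d, 50))
  aff <- diag(4); aff[1:3, 1:3] <- diag(c(4, 4, 4)); aff[1:3, 4] <- -20
  paths <- write_toy_nifti(data4d, mask, aff)

  run <- load_run(paths$bold, paths$mask)
  expect_equal(dim(run$data), c(400L, 50L))
  # row order is the documented C-order over (i,j,k)
  idx <- mask_index_table(mask)
  expect_true(all(diff(order(idx[, 1], idx[, 2], idx[, 3])) == 1))
  v <- 137
  expect_equal(run$data[v, ], data4d[idx[v, 1], idx[v, 2], idx[v, 3], ],
               tolerance = 1e-6)

  # empty mask errors
  paths0 <- write_toy_nifti(data4d, array(0, dim = d), aff)
  expect_error(load_run(paths0$bold, paths0$mask), "no voxels")

  # grid mismatch errors
  small_mask <- array(1, dim = c(8, 8, 8))
  paths_bad <- write_toy_nifti(array(rnorm(8^3 * 3), dim = c(8, 8, 8, 3)),
                               small_mask, aff)
  expect_error(load_run(paths$bold, paths_bad$mask), "grid mismatch")
})

test_that("save_map/load_map roundtrip is exact inside the mask", {
  set.seed(12)
  mask <- array(rbinom(6^3, 1, 0.5), dim = c(6, 6, 6))
  aff <- diag(4); aff[1:3, 1:3] <- diag(c(3, 3, 3))
  values <- rnorm(sum(mask))
  path <- tempfile(fileext = ".nii.gz")
  save_map(values, mask, aff, path)
  expect_equal(load_map(path, mask), values, tolerance = 1e-12)
  # ones vector reproduces the mask volume
  path2 <- tempfile(fileext = ".nii.gz")
  save_map(rep(1, sum(mask)), mask, aff, path2)
  img <- RNifti::readNifti(path2)
  expect_equal(array(as.numeric(img), dim = dim(mask)), mask)
  expect_error(save_map(values[-1], mask, aff, tempfile(fileext = ".nii")),
               "does not match")
  expect_error(save_map(numeric(0), array(0, dim = c(4, 4, 4)), aff,
                        tempfile(fileext = ".nii")), "no voxels")
})

test_that("masking/unmasking roundtrips the in-mask voxels", {
  set.seed(13)
  mask <- array(rbinom(5^3, 1, 0.6), dim = c(5, 5, 5))
  values <- rnorm(sum(mask))
  expect_identical(mask_volume(unmask_volume(values, mask), mask), values)
})

test_that("standardization gives zero mean, unit variance, and is idempotent", {
  set.seed(14)
  x <- matrix(rnorm(27 * 40, mean = 5, sd = 3), 27, 40)
  x[5, ] <- 7                 # constant row
  run <- toy_run(x, grid = c(3, 3, 3))
  out <- standardize(run)
  m <- rowMeans(out$data)
  v <- apply(out$data, 1, var)
  expect_lt(max(abs(m)), 1e-10)
  expect_lt(max(abs(v[-5] - 1)), 1e-10)
  expect_equal(out$data[5, ], rep(0, 40))          # zero-variance convention
  twice <- standardize(out)
  expect_equal(twice$data, out$data, tolerance = 1e-10)
  # the worked example row
  r <- standardize(toy_run(matrix(rep(c(1, 2, 3), each = 1), 1, 3),
                           grid = c(1, 1, 1)))$data
  expect_equal(mean(r), 0, tolerance = 1e-12)
  expect_equal(var(as.numeric(r)), 1, tolerance = 1e-12)
  expect_error(standardize(toy_run(matrix(1, 1, 1), grid = c(1, 1, 1))),
               "at least 2 frames")
})

test_that("Gaussian smoothing conserves interior impulse mass and fixes constants", {
  d <- c(15, 15, 15)
  mask <- array(1, dim = d)
  aff <- diag(4); aff[1:3, 1:3] <- diag(c(4, 4, 4))
  impulse <- array(0, dim = d); impulse[8, 8, 8] <- 1
  run <- bold_run(cbind(mask_volume(impulse, mask)), mask, aff)
  sm <- smooth_run(run, 6)
  # 6 mm FWHM on 4 mm voxels: kernel well inside the grid, mass conserved
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)
  expect_lt(max(sm$data), 1)                        # genuinely spread out
  # constant volume is a fixed point away from the zero-padded boundary
  # (the kernel is truncated and not renormalized at edges, so boundary
  # voxels lose mass by design)
  const <- bold_run(cbind(rep(2.5, prod(d))), mask, aff)
  sm_const <- smooth_run(const, 6)
  interior <- unmask_volume(rep(1, prod(d)), mask)
  interior[c(1:3, 13:15), , ] <- 0
  interior[, c(1:3, 13:15), ] <- 0
  interior[, , c(1:3, 13:15)] <- 0
  keep <- mask_volume(interior, mask) == 1
  expect_equal(sm_const$data[keep, 1], const$data[keep, 1], tolerance = 1e-6)
  # fwhm 0 is the identity; negative fwhm errors
  expect_identical(smooth_run(run, 0)$data, run$data)
  expect_error(smooth_run(run, -1), ">= 0")
})

test_that("censoring keeps the flagged frames in order", {
  x <- matrix(seq_len(8 * 5), nrow = 8)
  run <- toy_run(x, grid = c(2, 2, 2))
  expect_identical(apply_censor(run, rep(1, 5))$data, x)
  kept <- apply_censor(run, c(1, 0, 1, 0, 1))
  expect_identical(kept$data, x[, c(1, 3, 5)])
  expect_error(apply_censor(run, c(1, 0)), "5 frames")
  expect_error(apply_censor(run, rep(0, 5)), "every frame")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("1", "0", "1", "0", "1"), tsv)
  expect_identical(apply_censor(run, read_censor_tsv(tsv))$data, kept$data)
})

test_that("MNI-to-voxel conversion inverts the affine and snaps into the mask", {
  mask <- array(1, dim = c(10, 10, 10))
  ident <- diag(4)
  expect_identical(mni_to_voxel(ident, mask, c(2, 3, 4))$ijk, c(2L, 3L, 4L))
  # 4 mm isotropic scaling, zero offset: (8,8,8) mm -> voxel (2,2,2)
  aff4 <- diag(4); aff4[1:3, 1:3] <- diag(c(4, 4, 4))
  expect_identical(mni_to_voxel(aff4, mask, c(8, 8, 8))$ijk, c(2L, 2L, 2L))
  # exact half-way point ties toward the lower index
  expect_identical(mni_to_voxel(ident, mask, c(2.5, 3, 4))$ijk, c(2L, 3L, 4L))
  # out-of-mask point snaps to the nearest in-mask voxel with a flag
  holey <- mask; holey[1:5, , ] <- 0
  res <- mni_to_voxel(ident, holey, c(3, 4, 4))
  expect_true(res$snapped)
  expect_identical(res$ijk[1], 5L)
  # beyond the snap limit errors
  expect_error(mni_to_voxel(ident, holey, c(-50, 4, 4)), "limit")
  # affine roundtrip identity on in-mask voxel centers
  idx <- mask_index_table(mask)
  for (r in c(1, 123, 777)) {
    mm <- aff4[1:3, 1:3] %*% (idx[r, ] - 1) + aff4[1:3, 4]
    expect_equal(mni_to_voxel(aff4, mask, as.numeric(mm))$row, r)
  }
})

test_that("run concatenation sums frames and demands matching geometry", {
  set.seed(15)
  a <- toy_run(matrix(rnorm(8 * 420), 8), grid = c(2, 2, 2))
  b <- toy_run(matrix(rnorm(8 * 810), 8), grid = c(2, 2, 2))
  cc <- concatenate_runs(list(a, b))
  expect_equal(n_frames(cc), 1230)
  expect_identical(cc$boundaries, c(0L, 420L))
  expect_identical(cc$data, cbind(a$data, b$data))
  expect_identical(concatenate_runs(list(a)), a)
  ba <- concatenate_runs(list(b, a))
  expect_identical(sort(ba$data[1, ]), sort(cc$data[1, ]))
  other <- toy_run(matrix(rnorm(8 * 10), 8), grid = c(2, 2, 2), voxel_mm = 3)
  expect_error(concatenate_runs(list(a, other)), "affine")
})
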