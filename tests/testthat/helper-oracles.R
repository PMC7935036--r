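# Independent oracles and small in-code fixtures for the test suite.

# Brute-force average-linkage agglomeration on a distance matrix: merge the
# closest cluster pair (ties to the lexicographically lowest pair) while the
# minimum average inter-cluster distance stays <= cut. Average linkage is
# monotone, so this greedy partition equals a dendrogram cut at `cut`.
brute_force_average_linkage <- function(dist_mat, cut) {
  clusters <- as.list(seq_len(nrow(dist_mat)))
  repeat {
    if (length(clusters) == 1) break
    best <- NULL
    best_d <- Inf
    for (a in seq_len(length(clusters) - 1)) {
      for (b in (a + 1):length(clusters)) {
        d <- mean(dist_mat[clusters[[a]], clusters[[b]], drop = FALSE])
        if (d < best_d - 1e-12) {
          best_d <- d
          best <- c(a, b)
        }
      }
    }
    if (best_d > cut) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(nrow(dist_mat))
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

# Exhaustive assignment oracle: best one-to-one pairing maximizing total
# profit, enumerating permutations of the larger set's columns.
brute_force_assignment <- function(profit) {
  n1 <- nrow(profit)
  n2 <- ncol(profit)
  if (n1 <= n2) {
    perms <- all_permutations(n2)
    best <- -Inf
    best_pairs <- NULL
    for (p in perms) {
      cols <- p[seq_len(n1)]
      tot <- sum(profit[cbind(seq_len(n1), cols)])
      if (tot > best + 1e-12) {
        best <- tot
        best_pairs <- cbind(seq_len(n1), cols)
      }
    }
  } else {
    sub <- brute_force_assignment(t(profit))
    best <- sub$total
    best_pairs <- sub$pairs[, 2:1, drop = FALSE]
  }
  list(total = best, pairs = best_pairs)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# partitions equal up to relabelling iff co-membership relations coincide
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# small bold_run on an n^3 grid with given data (rows follow mask order)
toy_run <- function(data, grid = NULL, voxel_mm = 4) {
  n_vox <- nrow(data)
  if (is.null(grid)) {
    side <- round(n_vox^(1 / 3))
    stopifnot(side^3 == n_vox)
    grid <- rep(side, 3)
  }
  mask <- array(1, dim = grid)
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(rep(voxel_mm, 3))
  bold_run(data, mask, aff, tr_seconds = 2.2)
}

# two-group toy signal: voxels in `groups` share orthogonal sinusoid courses
grouped_signal <- function(groups, n_frames, noise = 0) {
  tt <- seq_len(n_frames)
  courses <- rbind(sin(2 * pi * tt / 17), cos(2 * pi * tt / 7),
                   sin(2 * pi * tt / 5), cos(2 * pi * tt / 29))
  x <- courses[groups, , drop = FALSE]
  if (noise > 0) x <- x + matrix(rnorm(length(x), sd = noise), nrow = nrow(x))
  x
}

# write a small 4D NIfTI + mask pair to tempfiles, returning the paths
write_toy_nifti <- function(data4d, mask, affine, dir = tempdir()) {
  bold_path <- tempfile("bold", fileext = ".nii.gz", tmpdir = dir)
  mask_path <- tempfile("mask", fileext = ".nii.gz", tmpdir = dir)
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(data4d)
  RNifti::pixdim(img) <- c(vox, 1)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, bold_path)
  mimg <- RNifti::asNifti(mask)
  RNifti::pixdim(mimg) <- vox
  RNifti::qform(mimg) <- structure(affine, code = 2L)
  RNifti::sform(mimg) <- structure(affine, code = 2L)
  RNifti::writeNifti(mimg, mask_path)
  list(bold = bold_path, mask = mask_path)
}

# deterministic label shuffle for negative controls
with_seed_labels <- function(labels, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample(labels)
}
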