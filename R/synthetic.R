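#' Specification of a synthetic dynamic-parcellation dataset
#'
#' Describes a 4D BOLD-like simulation in which voxels group into contiguous
#' parcels sharing a latent time course, and the parcel partition switches
#' between a small number of recurring spatial configurations (states) over
#' time, plus Gaussian noise. Subject identity is the set of partitions;
#' replication sets share partitions but draw fresh state sequences and
#' signals.
#'
#' @param grid_shape 3D grid dimensions in voxels.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param n_states number of planted states (recurring partitions).
#' @param k_true parcels per state partition.
#' @param dwell_targets fractions of time per state; must sum to 1.
#' @param segment_length_frames mean contiguous frames per state visit.
#' @param n_frames frames per run.
#' @param n_subjects number of simulated subjects.
#' @param n_sets_per_subject replication sets per subject.
#' @param noise_sigma standard deviation of additive Gaussian noise relative
#'   to the unit-variance latent parcel signals.
#' @param tr_seconds repetition time stamped on simulated runs.
#' @param rng_seed integer base seed; every draw derives from it.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(grid_shape = c(12, 12, 12), voxel_size_mm = 4,
                           n_states = 2, k_true = 12,
                           dwell_targets = c(0.6, 0.4),
                           segment_length_frames = 200, n_frames = 1000,
                           n_subjects = 1, n_sets_per_subject = 1,
                           noise_sigma = 0.3, tr_seconds = 2.2,
                           rng_seed = 1) {
  if (n_states < 1) stop("n_states must be >= 1", call. = FALSE)
  if (k_true < 2) stop("k_true must be >= 2", call. = FALSE)
  if (length(dwell_targets) != n_states) {
    stop("one dwell target per state", call. = FALSE)
  }
  if (abs(sum(dwell_targets) - 1) > 1e-9) {
    stop("dwell_targets must sum to 1", call. = FALSE)
  }
  if (any(dwell_targets <= 0)) stop("dwell targets must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 n_states = as.integer(n_states), k_true = as.integer(k_true),
                 dwell_targets = dwell_targets,
                 segment_length_frames = segment_length_frames,
                 n_frames = as.integer(n_frames),
                 n_subjects = as.integer(n_subjects),
                 n_sets_per_subject = as.integer(n_sets_per_subject),
                 noise_sigma = noise_sigma, tr_seconds = tr_seconds,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

# deterministic sub-seed scheme: one base seed drives every stream
derive_seed <- function(base, stream, index = 0L) {
  as.integer((as.numeric(base) * 1009 + stream * 9973 + index * 263) %%
               2147483629)
}

synthetic_affine <- function(spec) {
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(rep(spec$voxel_size_mm, 3))
  aff[1:3, 4] <- -spec$voxel_size_mm * (spec$grid_shape / 2)
  aff
}

# Voronoi partition of the full grid around k sampled voxel centres
voronoi_partition <- function(grid_shape, k) {
  n <- prod(grid_shape)
  coords <- as.matrix(expand.grid(i = seq_len(grid_shape[1]),
                                  j = seq_len(grid_shape[2]),
                                  k = seq_len(grid_shape[3])))
  centers <- coords[sample.int(n, k), , drop = FALSE]
  d2 <- outer(rowSums(coords^2), rowSums(centers^2), "+") -
    2 * tcrossprod(coords, centers)
  labels_fortran <- max.col(-d2, ties.method = "first")
  vol <- array(labels_fortran, dim = grid_shape)
  mask <- array(1, dim = grid_shape)
  vol[mask_linear_positions(mask)]   # package (C-order) voxel order
}

#' Plant ground-truth partitions and a state sequence
#'
#' Per state, a random Voronoi partition of the grid into `k_true` contiguous
#' parcels is drawn; partitions are resampled (bounded retries) until every
#' pair of seed parcels has Dice below `max_seed_dice`, so states are
#' spatially separable by construction. The state sequence consists of
#' contiguous segments with jittered lengths around `segment_length_frames`,
#' interleaved in shuffled order; realized per-state frame counts equal the
#' dwell targets up to rounding.
#'
#' @param spec a [synthetic_spec()].
#' @param subject_index 0-based subject index (selects the subject's
#'   partition stream).
#' @param max_seed_dice separation requirement between planted seed parcels.
#' @param max_retries resampling bound before an error.
#' @return list of class `ground_truth`: `partitions` (n_states x n_voxels
#'   label matrix), `seed_parcels` (binary matrix), `state_sequence`
#'   (per-frame 1-based state id), `seed_row`, `mask`, `affine`,
#'   `subject_index`, `dwell_realized`.
#' @export
make_ground_truth <- function(spec, subject_index = 0L, max_seed_dice = 0.3,
                              max_retries = 200) {
  mask <- array(1, dim = spec$grid_shape)
  n_vox <- prod(spec$grid_shape)
  seed_row <- seed_center_row(spec$grid_shape)
  partitions <- with_rng_seed(derive_seed(spec$rng_seed, 1L, subject_index), {
    for (attempt in seq_len(max_retries)) {
      P <- t(vapply(seq_len(spec$n_states), function(s) {
        voronoi_partition(spec$grid_shape, spec$k_true)
      }, integer(n_vox)))
      seeds <- t(apply(P, 1, function(lab) as.integer(lab == lab[seed_row])))
      ok <- TRUE
      if (spec$n_states > 1) {
        for (a in seq_len(spec$n_states - 1)) {
          for (b in (a + 1):spec$n_states) {
            if (dice(seeds[a, ], seeds[b, ]) >= max_seed_dice) ok <- FALSE
          }
        }
      }
      if (ok) break
      P <- NULL
    }
    if (is.null(P)) {
      stop("could not plant states with separated seed parcels", call. = FALSE)
    }
    P
  })
  seed_parcels <- t(apply(partitions, 1, function(lab) {
    as.integer(lab == lab[seed_row])
  }))
  structure(list(partitions = partitions, seed_parcels = seed_parcels,
                 state_sequence = NULL, seed_row = seed_row, mask = mask,
                 affine = synthetic_affine(spec),
                 subject_index = as.integer(subject_index),
                 dwell_realized = NULL),
            class = "ground_truth")
}

seed_center_row <- function(grid_shape) {
  mask <- array(1, dim = grid_shape)
  idx <- mask_index_table(mask)
  ctr <- ceiling(grid_shape / 2)
  which(idx[, 1] == ctr[1] & idx[, 2] == ctr[2] & idx[, 3] == ctr[3])
}

# contiguous-segment state sequence hitting the dwell targets up to rounding
sample_state_sequence <- function(spec) {
  frames <- round(spec$dwell_targets * spec$n_frames)
  frames[spec$n_states] <- spec$n_frames - sum(frames[-spec$n_states])
  segments <- list()
  for (s in seq_len(spec$n_states)) {
    n_seg <- max(1L, round(frames[s] / spec$segment_length_frames))
    w <- stats::rexp(n_seg) + 0.25        # jittered relative lengths
    lens <- floor(frames[s] * w / sum(w))
    lens[1] <- lens[1] + frames[s] - sum(lens)
    lens <- lens[lens > 0]
    for (l in lens) segments[[length(segments) + 1]] <- rep(s, l)
  }
  segments <- segments[sample.int(length(segments))]
  seq_out <- unlist(segments)
  stopifnot(length(seq_out) == spec$n_frames)
  as.integer(seq_out)
}

smooth_unit_course <- function(len, half_width = 2) {
  z <- stats::rnorm(len + 2 * half_width)
  z <- stats::filter(z, rep(1 / (2 * half_width + 1), 2 * half_width + 1),
                     sides = 2)
  z <- as.numeric(z[(half_width + 1):(half_width + len)])
  if (len < 2 || stats::sd(z) == 0) return(rep(0, len))
  as.numeric(scale(z))
}

#' Simulate a BOLD run from planted ground truth
#'
#' A fresh state sequence is drawn (contiguous segments honouring the dwell
#' targets); within each segment, every parcel of the active partition gets
#' an independent smooth unit-variance latent course, shared by its voxels;
#' Gaussian noise of standard deviation `noise_sigma` is added and each
#' voxel row is standardized. Latent courses are resampled at each segment,
#' so windows straddling a transition are genuinely mixed.
#'
#' @param spec a [synthetic_spec()].
#' @param ground_truth a [make_ground_truth()] result.
#' @param set_index 0-based replication-set index (its own noise/sequence
#'   stream; partitions are shared across sets).
#' @return list with `run` (a [bold_run()]) and `ground_truth` (the input
#'   with `state_sequence` and `dwell_realized` filled in for this set).
#' @export
simulate_bold <- function(spec, ground_truth, set_index = 0L) {
  gt <- ground_truth
  n_vox <- ncol(gt$partitions)
  stream <- derive_seed(spec$rng_seed, 2L,
                        gt$subject_index * 1000L + as.integer(set_index))
  out <- with_rng_seed(stream, {
    state_seq <- sample_state_sequence(spec)
    x <- matrix(0, n_vox, spec$n_frames)
    t0 <- 1L
    while (t0 <= spec$n_frames) {
      s <- state_seq[t0]
      t1 <- t0
      while (t1 < spec$n_frames && state_seq[t1 + 1] == s) t1 <- t1 + 1L
      len <- t1 - t0 + 1L
      courses <- t(vapply(seq_len(spec$k_true), function(p) {
        smooth_unit_course(len)
      }, numeric(len)))
      x[, t0:t1] <- courses[gt$partitions[s, ], , drop = FALSE]
      t0 <- t1 + 1L
    }
    if (spec$noise_sigma > 0) {
      x <- x + matrix(stats::rnorm(length(x), sd = spec$noise_sigma),
                      nrow = n_vox)
    }
    list(x = x, state_seq = state_seq)
  })
  gt$state_sequence <- out$state_seq
  gt$dwell_realized <- as.numeric(table(factor(out$state_seq,
                                               levels = seq_len(spec$n_states))) /
                                    spec$n_frames)
  run <- bold_run(out$x, gt$mask, gt$affine, tr_seconds = spec$tr_seconds,
                  run_id = sprintf("sim_sub-%02d_set-%d",
                                   gt$subject_index, set_index))
  list(run = standardize(run), ground_truth = gt)
}

#' Simulate a full multi-subject, multi-set dataset
#'
#' @param spec a [synthetic_spec()].
#' @return nested list `subjects[[s]]$sets[[r]]` each holding `run` and
#'   `ground_truth`; partitions are shared across a subject's sets.
#' @export
simulate_dataset <- function(spec) {
  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    gt <- make_ground_truth(spec, subject_index = s - 1L)
    sets <- vector("list", spec$n_sets_per_subject)
    for (r in seq_len(spec$n_sets_per_subject)) {
      sets[[r]] <- simulate_bold(spec, gt, set_index = r - 1L)
    }
    subjects[[s]] <- list(subject_index = s - 1L, ground_truth = gt,
                          sets = sets)
  }
  list(spec = spec, subjects = subjects)
}

#' Write a simulated dataset to NIfTI + JSON ground truth
#'
#' Emits, per subject and set, a 4D BOLD NIfTI, plus one shared mask volume
#' and a JSON ground-truth file (partitions, seed parcels, state sequences),
#' so the file-based pipeline runs on simulated data exactly as on real data.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- dataset$spec
  mask <- dataset$subjects[[1]]$ground_truth$mask
  aff <- dataset$subjects[[1]]$ground_truth$affine
  save_map(rep(1, sum(mask)), mask, aff, file.path(out_dir, "mask.nii.gz"))
  gt_json <- list(spec = unclass(spec), subjects = list())
  for (sub in dataset$subjects) {
    sid <- sprintf("sub-%02d", sub$subject_index)
    gt <- sub$ground_truth
    entry <- list(subject = sid,
                  partitions = unname(split(gt$partitions,
                                            row(gt$partitions))),
                  seed_parcels = unname(split(gt$seed_parcels,
                                              row(gt$seed_parcels))),
                  seed_row = gt$seed_row, sets = list())
    for (i in seq_along(sub$sets)) {
      set <- sub$sets[[i]]
      path <- file.path(out_dir, sprintf("%s_set-%d_bold.nii.gz", sid, i - 1))
      img <- RNifti::asNifti(array(
        t(apply_unmask_frames(set$run)), # voxels back into the grid
        dim = c(spec$grid_shape, n_frames(set$run))))
      RNifti::pixdim(img) <- c(rep(spec$voxel_size_mm, 3), spec$tr_seconds)
      RNifti::qform(img) <- structure(aff, code = 2L)
      RNifti::sform(img) <- structure(aff, code = 2L)
      RNifti::writeNifti(img, path)
      entry$sets[[i]] <- list(bold = basename(path),
                              state_sequence = set$ground_truth$state_sequence,
                              dwell_realized = set$ground_truth$dwell_realized)
    }
    gt_json$subjects[[length(gt_json$subjects) + 1]] <- entry
  }
  jsonlite::write_json(gt_json, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# frames-by-grid matrix whose rows reshape to full volumes
apply_unmask_frames <- function(run) {
  pos <- mask_linear_positions(run$mask)
  n <- prod(dim(run$mask))
  out <- matrix(0, n_frames(run), n)
  for (t in seq_len(n_frames(run))) out[t, pos] <- run$data[, t]
  out
}

#' Score pipeline output against planted ground truth
#'
#' Reports the detected state count; the best-pairing (Hungarian on Dice)
#' agreement between stability maps binarized at `cut` and the planted seed
#' parcels; absolute dwell-fraction errors of the paired states; and the
#' window-assignment accuracy against the majority planted state per window
#' instance (unassigned instances count as errors).
#'
#' @param fit a [fit_states()] result on simulated data.
#' @param ground_truth the matching [make_ground_truth()] /
#'   [simulate_bold()] ground truth (with `state_sequence`).
#' @param cut binarization threshold on stability values.
#' @return list with `n_detected`, `n_planted`, `matched_dice`,
#'   `dwell_errors`, `window_accuracy`, `fraction_unassigned`, `pairs`.
#' @export
evaluate_recovery <- function(fit, ground_truth, cut = 0.5) {
  gt <- ground_truth
  n_planted <- nrow(gt$seed_parcels)
  n_detected <- length(fit$states)
  if (n_detected == 0) {
    return(list(n_detected = 0L, n_planted = n_planted,
                matched_dice = numeric(0), dwell_errors = numeric(0),
                window_accuracy = 0,
                fraction_unassigned = 1, pairs = NULL))
  }
  det_bin <- t(vapply(fit$states, function(s) {
    as.integer(s$stability > cut)
  }, integer(ncol(gt$seed_parcels))))
  Dmat <- matrix(0, n_detected, n_planted)
  for (i in seq_len(n_detected)) {
    for (j in seq_len(n_planted)) {
      Dmat[i, j] <- if (sum(det_bin[i, ]) == 0) 0 else
        dice(det_bin[i, ], gt$seed_parcels[j, ])
    }
  }
  s <- max(n_detected, n_planted)
  cost <- matrix(0, s, s)
  cost[seq_len(n_detected), seq_len(n_planted)] <- max(Dmat) - Dmat
  assign_col <- hungarian_solve(cost)
  pairs <- do.call(rbind, lapply(seq_len(n_detected), function(i) {
    j <- assign_col[i]
    if (j <= n_planted) data.frame(detected = i, planted = j,
                                   dice = Dmat[i, j]) else NULL
  }))
  dwell_det <- vapply(fit$states, function(st) st$dwell_fraction, numeric(1))
  dwell_true <- if (is.null(gt$dwell_realized)) {
    rep(NA_real_, n_planted)
  } else gt$dwell_realized
  dwell_errors <- abs(dwell_det[pairs$detected] - dwell_true[pairs$planted])
  # majority planted state per window instance
  win_major <- vapply(seq_len(nrow(fit$assignment)), function(r) {
    st <- fit$assignment$start_frame[r]
    frames <- gt$state_sequence[(st + 1):(st + fit$params$W)]
    as.integer(names(which.max(table(frames))))
  }, integer(1))
  det_rank <- fit$assignment$state_rank
  planted_of_rank <- rep(NA_integer_, n_detected)
  planted_of_rank[pairs$detected] <- pairs$planted
  predicted <- ifelse(det_rank > 0, planted_of_rank[pmax(det_rank, 1)],
                      NA_integer_)
  window_accuracy <- mean(!is.na(predicted) & predicted == win_major)
  list(n_detected = n_detected, n_planted = n_planted,
       matched_dice = pairs$dice, dwell_errors = dwell_errors,
       window_accuracy = window_accuracy,
       fraction_unassigned = mean(det_rank < 0), pairs = pairs)
}
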