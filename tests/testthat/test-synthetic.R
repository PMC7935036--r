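test_that("spec validation enforces dwell targets and state counts", {
  expect_error(synthetic_spec(dwell_targets = c(0.7, 0.4)), "sum to 1")
  expect_error(synthetic_spec(n_states = 0, dwell_targets = numeric(0)), "n_states")
  expect_error(synthetic_spec(k_true = 1), "k_true")
  expect_error(synthetic_spec(dwell_targets = c(1, 0)), "positive")
  spec <- synthetic_spec()
  expect_s3_class(spec, "synthetic_spec")
})

test_that("planted ground truth is deterministic, covering, and spatially separated", {
  spec <- synthetic_spec(grid_shape = c(10, 10, 10), rng_seed = 3)
  gt1 <- make_ground_truth(spec)
  gt2 <- make_ground_truth(spec)
  expect_identical(gt1$partitions, gt2$partitions)
  # each partition covers all voxels with k_true labels
  expect_equal(ncol(gt1$partitions), 1000)
  expect_true(all(apply(gt1$partitions, 1, function(l) {
    length(unique(l)) == spec$k_true
  })))
  # the seed voxel sits inside its parcel in every state
  expect_true(all(gt1$seed_parcels[, gt1$seed_row] == 1))
  # pairwise Dice between planted seed parcels below 0.3 by construction
  expect_lt(dice(gt1$seed_parcels[1, ], gt1$seed_parcels[2, ]), 0.3)
  # planted parcels are spatially contiguous (face connectivity)
  vol <- unmask_volume(gt1$seed_parcels[1, ], gt1$mask)
  lab <- extract_regions(mask_volume(vol, gt1$mask) * 0.9, gt1$mask,
                         min_region_voxels = 1)
  expect_equal(max(lab), 1)
  # different subjects draw different partitions
  gt_other <- make_ground_truth(spec, subject_index = 1L)
  expect_false(identical(gt1$partitions, gt_other$partitions))
  # single state: constant sequence after simulation
  spec1 <- synthetic_spec(n_states = 1, dwell_targets = 1,
                          grid_shape = c(8, 8, 8), n_frames = 200,
                          rng_seed = 5)
  sim1 <- simulate_bold(spec1, make_ground_truth(spec1))
  expect_equal(unique(sim1$ground_truth$state_sequence), 1L)
})

test_that("simulated runs honour the planted structure", {
  spec <- synthetic_spec(grid_shape = c(8, 8, 8), k_true = 4, n_frames = 400,
                         segment_length_frames = 100, noise_sigma = 0,
                         rng_seed = 7)
  gt <- make_ground_truth(spec)
  sim <- simulate_bold(spec, gt)
  # realized dwell equals targets up to rounding
  expect_equal(sim$ground_truth$dwell_realized, spec$dwell_targets,
               tolerance = 0.02)
  # noise-free: within a single-state window, same-parcel voxels correlate as 1
  seq1 <- sim$ground_truth$state_sequence
  t0 <- which(seq1 == 1)[1]
  len <- 0
  while (t0 + len <= length(seq1) && seq1[t0 + len] == 1) len <- len + 1
  win <- sim$run$data[, t0:(t0 + len - 1)]
  part <- gt$partitions[1, ]
  pair <- which(part == part[gt$seed_row])[1:2]
  expect_equal(abs(cor(win[pair[1], ], win[pair[2], ])), 1, tolerance = 1e-6)
  # same spec and set -> identical data; different set -> same partitions,
  # different sequence/noise
  sim_b <- simulate_bold(spec, gt)
  expect_identical(sim$run$data, sim_b$run$data)
  sim2 <- simulate_bold(spec, gt, set_index = 1L)
  expect_false(identical(sim$run$data, sim2$run$data))
  expect_identical(sim$ground_truth$partitions, sim2$ground_truth$partitions)
})

test_that("dataset writer emits NIfTI runs, mask and JSON ground truth that reload", {
  spec <- synthetic_spec(grid_shape = c(6, 6, 6), k_true = 4, n_frames = 60,
                         segment_length_frames = 30, n_subjects = 2,
                         n_sets_per_subject = 1, rng_seed = 11)
  ds <- simulate_dataset(spec)
  out <- file.path(tempdir(), "simds")
  write_dataset(ds, out)
  expect_true(file.exists(file.path(out, "mask.nii.gz")))
  expect_true(file.exists(file.path(out, "ground_truth.json")))
  run <- load_run(file.path(out, "sub-00_set-0_bold.nii.gz"),
                  file.path(out, "mask.nii.gz"))
  expect_equal(dim(run$data), c(216L, 60L))
  expect_equal(run$data, ds$subjects[[1]]$sets[[1]]$run$data,
               tolerance = 1e-5)
  gtj <- jsonlite::fromJSON(file.path(out, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(length(gtj$subjects$subject), 2)
})

test_that("recovery scoring is exact on noise-free single-state data and near chance on shuffled truth", {
  spec <- synthetic_spec(grid_shape = c(8, 8, 8), n_states = 1,
                         dwell_targets = 1, k_true = 6, n_frames = 240,
                         segment_length_frames = 120, noise_sigma = 0,
                         rng_seed = 13)
  gt <- make_ground_truth(spec)
  sim <- simulate_bold(spec, gt)
  fit <- fit_states(sim$run, gt$seed_row, W = 60, O = 10, k = 6,
                    n_replications = 2, base_seed = 3)
  rec <- evaluate_recovery(fit, sim$ground_truth)
  expect_equal(rec$n_detected, 1)
  expect_equal(rec$matched_dice, 1)
  expect_equal(rec$dwell_errors, 0)
  expect_equal(rec$window_accuracy, 1)
  # negative control: scoring against a wrong (resampled) ground truth
  wrong <- sim$ground_truth
  wrong$seed_parcels <- matrix(as.integer(seq_len(ncol(wrong$seed_parcels))
                                          %in% sample(512, 60)), nrow = 1)
  wrong$seed_parcels[1, gt$seed_row] <- 1L
  rec_wrong <- evaluate_recovery(fit, wrong)
  expect_lt(rec_wrong$matched_dice, 0.5)
  # determinism of the metrics given the seeds
  rec2 <- evaluate_recovery(fit_states(sim$run, gt$seed_row, W = 60, O = 10,
                                       k = 6, n_replications = 2,
                                       base_seed = 3),
                            sim$ground_truth)
  expect_identical(rec2$matched_dice, rec$matched_dice)
})

test_that("recovery quality degrades monotonically with noise", {
  mean_dice_at <- function(sig) {
    mean(vapply(1:10, function(s) {
      spec <- synthetic_spec(grid_shape = c(10, 10, 10), k_true = 8,
                             noise_sigma = sig, rng_seed = 300 + s)
      gt <- make_ground_truth(spec)
      sim <- simulate_bold(spec, gt)
      fit <- fit_states(sim$run, gt$seed_row, k = 8, n_replications = 3,
                        base_seed = 400 + s)
      rec <- evaluate_recovery(fit, sim$ground_truth)
      if (length(rec$matched_dice)) mean(rec$matched_dice) else 0
    }, numeric(1)))
  }
  md <- vapply(c(0, 0.3, 1.0, 3.0), mean_dice_at, numeric(1))
  expect_true(all(diff(md) <= 1e-8))
  expect_gt(md[1], 0.99)              # noise-free recovery is essentially exact
})
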