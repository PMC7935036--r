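# dynparcel

Resting-state fMRI parcellations are usually treated as static, yet the
parcel surrounding a given brain region reconfigures over time. **dynparcel**
identifies *dynamic states of parcellation* for a seed voxel: recurring
spatial configurations of the seed's parcel across short sliding time
windows, summarized as voxelwise *stability maps*. It is aimed at
researchers studying individual-level dynamic functional connectivity who
have preprocessed BOLD runs, a brain mask, and seed coordinates in MNI
space.

## Method

For a (possibly concatenated) masked BOLD run with frames standardized to
zero mean and unit variance:

1. **Sliding windows.** Windows of `W = 100` frames with `O = 10` frames of
   overlap, starting at the first frame; the last partial window is dropped.
   Windows may span session boundaries.
2. **Replicated parcellation.** Each window is clustered into `k = 12`
   parcels by k-means over voxels (features = the window's time points),
   with k-means++ initialization, replicated 5 times per window under
   distinct seeds. The number of window-parcellation instances is always
   `windows x replications`.
3. **Seed binarization and similarity.** Each parcellation is reduced to the
   binary map of the seed's parcel. All pairs of maps are compared with the
   Dice coefficient, `2|A∩B| / (|A|+|B|)`.
4. **State detection.** Average-linkage hierarchical clustering on the
   distance `1 − Dice`, cut at `1 − 0.3`, groups the maps into candidate
   states; states are kept only if they hold strictly more than 10% of all
   instances (their *dwell time* is the retained fraction). Remaining maps
   are reported unassigned.
5. **Stability maps.** Each state's member maps are averaged voxelwise: the
   probability of each voxel joining the seed's parcel while the state is
   active. States are ranked by decreasing dwell time (primary, secondary,
   ...). Maps can be split into spatially contiguous regions (components
   above stability 0.5, at least 50 voxels).

The evaluation battery matches states across split-half replication sets
with the Hungarian method on Pearson correlation (unmatched states score
0), compares dwell times of matched states, and runs deterministic and
chance fingerprinting over pooled subject maps. A synthetic-data module
plants Voronoi parcellations that switch between recurring states, so every
stage can be validated against ground truth without any external dataset.

## Worked example

```r
library(dynparcel)

spec <- synthetic_spec(rng_seed = 42)   # 12x12x12 grid, 2 states, 60/40 dwell
gt   <- make_ground_truth(spec)
sim  <- simulate_bold(spec, gt)

fit <- fit_states(sim$run, gt$seed_row, base_seed = 7)
print(fit)
#> <dynparcel_fit> 2 state(s) from 55 seed-parcel maps
#>   state 1: dwell 0.618 (34 maps), within-state Dice mean 0.82 min 0.39
#>   state 2: dwell 0.382 (21 maps), within-state Dice mean 0.68 min 0.16
#>   unassigned instances: 0.0%

rec <- evaluate_recovery(fit, sim$ground_truth)
rec$matched_dice     # 1 1      — binarized stability maps equal the planted parcels
rec$dwell_errors     # 0.018 0.018 — dwell recovered to ~2 percentage points
rec$window_accuracy  # 0.93     — window instances assigned to the correct state
```

The run holds 55 window-parcellation instances (11 windows x 5
replications). Both planted states are detected: the primary state occupies
61.8% of instances against a planted 60% dwell, and each state's stability
map, thresholded at 0.5, reproduces the planted seed parcel exactly
(Dice 1).

A command-line front end (`inst/cli/dynparcel.R`) exposes `fit`, `eval`,
`fingerprint`, `simulate` and `regions` subcommands over NIfTI/TSV/JSON
files; see the script header for usage.

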