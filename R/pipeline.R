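#' Fit dynamic states of parcellation for one seed
#'
#' End-to-end state detection on one (possibly concatenated) run: sliding
#' windows, replicated k-means parcellation, seed binarization, Dice matrix,
#' average-linkage clustering cut at `1 - dice_threshold`, dwell filtering,
#' stability maps, and dwell-ranked state labels.
#'
#' @param run a [bold_run()] (already preprocessed/standardized).
#' @param seed_row 1-based row of the seed voxel in the masked data (see
#'   [mni_to_voxel()]).
#' @param W,O window length and overlap in frames.
#' @param k parcels per window.
#' @param n_replications k-means replications per window.
#' @param base_seed integer seed driving all k-means initializations.
#' @param dice_threshold,dwell_threshold,linkage see [state_params()].
#' @param forbid_spanning drop windows spanning run boundaries.
#' @return object of class `dynparcel_fit`: `states` (ranked list with
#'   `rank`, `dwell_fraction`, `n_members`, `mean_dice`, `min_dice`,
#'   `stability`), `assignment` (data frame `window_index`,
#'   `replication_index`, `start_frame`, `state_rank`; `-1` = unassigned),
#'   `n_maps`, `params`, `mask`, `affine`, `seed_row`.
#' @export
fit_states <- function(run, seed_row, W = 100, O = 10, k = 12,
                       n_replications = 5, base_seed = 1,
                       dice_threshold = 0.3, dwell_threshold = 0.10,
                       linkage = "average", forbid_spanning = FALSE) {
  sp <- state_params(dice_threshold, dwell_threshold, linkage)
  sliding <- run_sliding_parcellation(run, k = k,
                                      n_replications = n_replications,
                                      base_seed = base_seed, W = W, O = O,
                                      forbid_spanning = forbid_spanning)
  maps <- t(vapply(sliding$parcellations, function(p) {
    binarize_seed_parcel(p, seed_row)
  }, integer(n_voxels(run))))
  D <- dice_matrix(maps)
  labels <- cluster_states(D, sp)
  filtered <- filter_states(labels, sp)
  dice_summary <- state_dice_summary(D, filtered)
  states <- lapply(seq_along(filtered$states), function(i) {
    s <- filtered$states[[i]]
    s$stability <- compute_stability_map(maps[s$member_indices, , drop = FALSE])
    s$mean_dice <- dice_summary$mean_dice[i]
    s$min_dice <- dice_summary$min_dice[i]
    s
  })
  states <- sort_and_label_states(states)
  rank_of_id <- stats::setNames(
    vapply(states, function(s) s$rank, integer(1)),
    vapply(states, function(s) as.character(s$state_id), character(1)))
  state_rank <- ifelse(filtered$assignment < 0, -1L,
                       rank_of_id[as.character(filtered$assignment)])
  assignment <- data.frame(
    window_index = vapply(sliding$parcellations,
                          function(p) p$window_index, integer(1)),
    replication_index = vapply(sliding$parcellations,
                               function(p) p$replication_index, integer(1)),
    start_frame = vapply(sliding$parcellations,
                         function(p) p$start, integer(1)),
    state_rank = as.integer(state_rank))
  structure(list(states = states, assignment = assignment,
                 n_maps = nrow(maps),
                 params = list(W = W, O = O, k = k,
                               n_replications = n_replications,
                               base_seed = base_seed,
                               dice_threshold = dice_threshold,
                               dwell_threshold = dwell_threshold,
                               linkage = linkage),
                 mask = run$mask, affine = run$affine, seed_row = seed_row),
            class = "dynparcel_fit")
}

#' @export
print.dynparcel_fit <- function(x, ...) {
  cat(sprintf("<dynparcel_fit> %d state(s) from %d seed-parcel maps\n",
              length(x$states), x$n_maps))
  for (s in x$states) {
    cat(sprintf("  state %d: dwell %.3f (%d maps), within-state Dice mean %.2f min %.2f\n",
                s$rank, s$dwell_fraction, s$n_members, s$mean_dice, s$min_dice))
  }
  unassigned <- mean(x$assignment$state_rank < 0)
  cat(sprintf("  unassigned instances: %.1f%%\n", 100 * unassigned))
  invisible(x)
}

#' Stability maps of a fit as a matrix
#'
#' @param fit a [fit_states()] result.
#' @return matrix, one row per state in rank order.
#' @export
stability_matrix <- function(fit) {
  if (length(fit$states) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = sum(fit$mask != 0)))
  }
  t(vapply(fit$states, function(s) s$stability,
           numeric(length(fit$states[[1]]$stability))))
}

#' Write a fit to disk (NIfTI maps + TSV assignment + JSON summary)
#'
#' Stability maps are written one file per state as
#' `{subject}_{seed}_state-{rank}.nii.gz`, the assignment table as TSV and a
#' JSON summary with parameters and per-state dwell statistics.
#'
#' @param fit a [fit_states()] result.
#' @param dir output directory (created if needed).
#' @param subject,seed_name labels used in file names.
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir, subject = "sub-01", seed_name = "seed") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in fit$states) {
    save_map(s$stability, fit$mask, fit$affine,
             file.path(dir, sprintf("%s_%s_state-%d.nii.gz",
                                    subject, seed_name, s$rank)))
  }
  utils::write.table(fit$assignment,
                     file.path(dir, sprintf("%s_%s_assignment.tsv",
                                            subject, seed_name)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    subject = subject, seed = seed_name, params = fit$params,
    n_maps = fit$n_maps, seed_row = fit$seed_row,
    states = lapply(fit$states, function(s) {
      list(rank = s$rank, state_id = s$state_id, n_members = s$n_members,
           dwell_fraction = s$dwell_fraction, mean_dice = s$mean_dice,
           min_dice = s$min_dice)
    }))
  jsonlite::write_json(summary,
                       file.path(dir, sprintf("%s_%s_states.json",
                                              subject, seed_name)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a written fit back (maps + summary)
#'
#' @param dir directory written by [write_fit()].
#' @param subject,seed_name labels used at write time.
#' @param mask 3D mask array of the analysis.
#' @return list with `stability` (matrix, rank order), `dwell_fractions`,
#'   `summary`.
#' @export
read_fit <- function(dir, subject, seed_name, mask) {
  summary <- jsonlite::fromJSON(
    file.path(dir, sprintf("%s_%s_states.json", subject, seed_name)),
    simplifyDataFrame = FALSE)
  ranks <- vapply(summary$states, function(s) s$rank, numeric(1))
  stab <- t(vapply(sort(ranks), function(r) {
    load_map(file.path(dir, sprintf("%s_%s_state-%d.nii.gz",
                                    subject, seed_name, r)), mask)
  }, numeric(sum(mask != 0))))
  dwell <- vapply(summary$states[order(ranks)],
                  function(s) s$dwell_fraction, numeric(1))
  list(stability = stab, dwell_fractions = dwell, summary = summary)
}

#' Split-half reproducibility report for two fits
#'
#' Hungarian matching of the two sets' stability maps by Pearson
#' correlation, per-state reproducibility scores (0 for unmatched set-1
#' states) and the dwell comparison of matched states.
#'
#' @param fit1,fit2 [fit_states()] results (or `stability`/`dwell` lists
#'   from [read_fit()]).
#' @return list with `match`, `scores`, `dwell_table`.
#' @export
split_half_report <- function(fit1, fit2) {
  m1 <- if (inherits(fit1, "dynparcel_fit")) stability_matrix(fit1) else fit1$stability
  m2 <- if (inherits(fit2, "dynparcel_fit")) stability_matrix(fit2) else fit2$stability
  d1 <- if (inherits(fit1, "dynparcel_fit")) {
    vapply(fit1$states, function(s) s$dwell_fraction, numeric(1))
  } else fit1$dwell_fractions
  d2 <- if (inherits(fit2, "dynparcel_fit")) {
    vapply(fit2$states, function(s) s$dwell_fraction, numeric(1))
  } else fit2$dwell_fractions
  if (nrow(m1) == 0 || nrow(m2) == 0) {
    warning("a replication set has no retained states; zero matches")
    return(list(match = NULL, scores = numeric(max(nrow(m1), 0)),
                dwell_table = NULL))
  }
  match <- hungarian_match(m1, m2)
  list(match = match,
       scores = reproducibility_scores(match),
       dwell_table = compare_dwell_times(match, d1, d2))
}

#' Pool state maps of many fits for fingerprinting
#'
#' @param fits_by_subject named list: per subject, a list of fits (one per
#'   replication set).
#' @return list with `maps` (matrix), `subject`, `set`, `rank`.
#' @export
pool_state_maps <- function(fits_by_subject) {
  maps <- list(); subject <- character(); set <- integer(); rank <- integer()
  subs <- names(fits_by_subject)
  if (is.null(subs)) subs <- as.character(seq_along(fits_by_subject))
  for (i in seq_along(fits_by_subject)) {
    for (j in seq_along(fits_by_subject[[i]])) {
      fit <- fits_by_subject[[i]][[j]]
      M <- if (inherits(fit, "dynparcel_fit")) stability_matrix(fit) else fit$stability
      if (nrow(M) == 0) next
      for (r in seq_len(nrow(M))) {
        maps[[length(maps) + 1]] <- M[r, ]
        subject <- c(subject, subs[i])
        set <- c(set, j)
        rank <- c(rank, r)
      }
    }
  }
  list(maps = do.call(rbind, maps), subject = subject, set = set, rank = rank)
}

#' Fit dynamic states directly from NIfTI files
#'
#' Convenience driver: loads one or more runs, applies optional censoring,
#' standardization and Gaussian smoothing, concatenates them, resolves the
#' seed, and calls [fit_states()].
#'
#' @param bold_paths character vector of 4D NIfTI paths (one replication
#'   set's sessions, concatenated in the given order).
#' @param mask_path 3D binary mask NIfTI path.
#' @param seed_mni length-3 MNI mm coordinate of the seed.
#' @param censor_paths optional per-run censor TSVs (0/1 per frame).
#' @param do_standardize standardize voxel rows to zero mean, unit variance.
#' @param fwhm_mm Gaussian smoothing kernel FWHM in mm (0 = none; the
#'   reference preprocessing used 6 mm).
#' @param tr_seconds TR override in seconds.
#' @param ... further arguments passed to [fit_states()].
#' @return a [fit_states()] result.
#' @export
fit_from_files <- function(bold_paths, mask_path, seed_mni,
                           censor_paths = NULL, do_standardize = TRUE,
                           fwhm_mm = 6, tr_seconds = NULL, ...) {
  runs <- lapply(seq_along(bold_paths), function(i) {
    run <- load_run(bold_paths[i], mask_path, tr_seconds = tr_seconds)
    if (!is.null(censor_paths)) {
      run <- apply_censor(run, read_censor_tsv(censor_paths[i]))
    }
    run
  })
  run <- concatenate_runs(runs)
  if (fwhm_mm > 0) run <- smooth_run(run, fwhm_mm)
  if (do_standardize) run <- standardize(run)
  seed <- mni_to_voxel(run$affine, run$mask, seed_mni)
  fit_states(run, seed$row, ...)
}
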