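#' Binarize a window parcellation at the seed voxel
#'
#' The seed-based parcellation: 1 for every voxel sharing the seed's parcel
#' in this window, 0 elsewhere. The seed voxel itself is always 1.
#'
#' @param parcellation a [parcellate_window()] result, or an integer label
#'   vector.
#' @param seed_row 1-based row index of the seed voxel in the masked data.
#' @return integer 0/1 vector over in-mask voxels.
#' @export
binarize_seed_parcel <- function(parcellation, seed_row) {
  labels <- if (inherits(parcellation, "window_parcellation")) {
    parcellation$labels
  } else {
    as.integer(parcellation)
  }
  if (seed_row < 1 || seed_row > length(labels)) {
    stop("seed row index out of range", call. = FALSE)
  }
  as.integer(labels == labels[seed_row])
}

#' Dice coefficient between two binary maps
#'
#' `2 |A intersect B| / (|A| + |B|)`, in `[0, 1]`.
#'
#' @param a,b equal-length 0/1 (or logical) vectors.
#' @return scalar Dice score.
#' @export
dice <- function(a, b) {
  if (length(a) != length(b)) stop("maps differ in length", call. = FALSE)
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) stop("Dice undefined for two empty maps", call. = FALSE)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Pairwise Dice matrix of seed-parcel maps
#'
#' @param maps binary matrix, one row per seed-parcel map, or a list of 0/1
#'   vectors.
#' @return symmetric N x N matrix in `[0, 1]` with unit diagonal.
#' @export
dice_matrix <- function(maps) {
  M <- as_map_matrix(maps)
  if (nrow(M) < 2) stop("need at least 2 maps", call. = FALSE)
  sizes <- rowSums(M)
  if (any(sizes == 0)) stop("empty seed-parcel map", call. = FALSE)
  inter <- tcrossprod(M)
  D <- 2 * inter / outer(sizes, sizes, "+")
  diag(D) <- 1
  D
}

as_map_matrix <- function(maps) {
  M <- if (is.list(maps)) do.call(rbind, maps) else as.matrix(maps)
  storage.mode(M) <- "double"
  M[M != 0] <- 1
  M
}

#' State-detection parameters
#'
#' @param dice_threshold minimum Dice similarity for maps in one state; the
#'   average-linkage dendrogram is cut at distance `1 - dice_threshold`.
#' @param dwell_threshold a state is retained only if its member count is
#'   strictly greater than `dwell_threshold` times the number of maps.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list of class `state_params`.
#' @export
state_params <- function(dice_threshold = 0.3, dwell_threshold = 0.10,
                         linkage = "average") {
  if (!(dice_threshold > 0 && dice_threshold <= 1)) {
    stop("dice_threshold must be in (0, 1]", call. = FALSE)
  }
  if (!(dwell_threshold >= 0 && dwell_threshold < 1)) {
    stop("dwell_threshold must be in [0, 1)", call. = FALSE)
  }
  structure(list(dice_threshold = dice_threshold,
                 dwell_threshold = dwell_threshold, linkage = linkage),
            class = "state_params")
}

#' Cluster seed-parcel maps into candidate states
#'
#' Agglomerative clustering (average linkage by default) on the distance
#' `1 - Dice`; the dendrogram is cut at height `1 - dice_threshold`, so maps
#' whose (linkage-averaged) Dice similarity reaches the threshold share a
#' state.
#'
#' @param D Dice matrix from [dice_matrix()].
#' @param params a [state_params()].
#' @return integer vector of cluster labels, one per map.
#' @export
cluster_states <- function(D, params = state_params()) {
  hc <- stats::hclust(stats::as.dist(1 - D), method = params$linkage)
  stats::cutree(hc, h = 1 - params$dice_threshold)
}

#' Dwell-time filter of candidate states
#'
#' Keeps clusters whose member count strictly exceeds
#' `dwell_threshold * total`; each retained state's dwell fraction is
#' `members / total` where `total` counts all window-replication instances.
#' Maps belonging to dropped clusters are reported as unassigned (state id
#' `-1`).
#'
#' @param labels cluster labels from [cluster_states()].
#' @param params a [state_params()].
#' @return list with `states` (list of `state_id`, `member_indices`,
#'   `n_members`, `dwell_fraction`, ordered by decreasing size) and
#'   `assignment` (per-map retained state id, `-1` if unassigned).
#' @export
filter_states <- function(labels, params = state_params()) {
  total <- length(labels)
  counts <- table(labels)
  keep_ids <- as.integer(names(counts)[counts > params$dwell_threshold * total])
  keep_ids <- keep_ids[order(-counts[as.character(keep_ids)], keep_ids)]
  states <- lapply(keep_ids, function(id) {
    members <- which(labels == id)
    list(state_id = id, member_indices = members,
         n_members = length(members),
         dwell_fraction = length(members) / total)
  })
  assignment <- ifelse(labels %in% keep_ids, labels, -1L)
  list(states = states, assignment = as.integer(assignment), total = total)
}

#' Within-state Dice summary
#'
#' Reports, per retained state, the realized minimum and mean pairwise Dice
#' between member maps — the post-hoc check that the dendrogram cut honoured
#' the intended similarity floor.
#'
#' @param D Dice matrix.
#' @param states result of [filter_states()].
#' @return data frame with columns `state_id`, `n_members`, `min_dice`,
#'   `mean_dice`.
#' @export
state_dice_summary <- function(D, states) {
  rows <- lapply(states$states, function(s) {
    m <- s$member_indices
    if (length(m) == 1) {
      mn <- 1; av <- 1
    } else {
      sub <- D[m, m]
      vals <- sub[upper.tri(sub)]
      mn <- min(vals); av <- mean(vals)
    }
    data.frame(state_id = s$state_id, n_members = s$n_members,
               min_dice = mn, mean_dice = av)
  })
  if (length(rows) == 0) {
    return(data.frame(state_id = integer(), n_members = integer(),
                      min_dice = numeric(), mean_dice = numeric()))
  }
  do.call(rbind, rows)
}
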