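#' Stability map of one dynamic state
#'
#' Voxelwise arithmetic mean of the state's binary seed-parcel maps: the
#' probability of each voxel being assigned to the seed's parcel while the
#' state is active. The seed voxel is 1 in every member, hence exactly 1 in
#' the map.
#'
#' @param member_maps binary matrix (rows = member maps) or list of 0/1
#'   vectors.
#' @return numeric vector in `[0, 1]` over in-mask voxels.
#' @export
compute_stability_map <- function(member_maps) {
  M <- as_map_matrix(member_maps)
  if (nrow(M) < 1) stop("state has no member maps", call. = FALSE)
  colMeans(M)
}

#' Sort states by dwell time and assign ranks
#'
#' States are ordered by decreasing dwell fraction (primary, secondary,
#' tertiary, ...). Ties are broken by larger mean within-state Dice, then by
#' smaller original state id, so the ordering is deterministic.
#'
#' @param states list of state descriptors, each with `dwell_fraction`,
#'   `state_id` and optionally `mean_dice`.
#' @return the same list reordered, with a `rank` field added (1 = primary).
#' @export
sort_and_label_states <- function(states) {
  if (length(states) == 0) return(states)
  dwell <- vapply(states, function(s) s$dwell_fraction, numeric(1))
  meand <- vapply(states, function(s) {
    if (is.null(s$mean_dice)) 0 else s$mean_dice
  }, numeric(1))
  ids <- vapply(states, function(s) s$state_id, numeric(1))
  ord <- order(-dwell, -meand, ids)
  states <- states[ord]
  for (i in seq_along(states)) states[[i]]$rank <- i
  states
}

#' Split a stability map into contiguous regions
#'
#' The map is thresholded (`values > stability_cut`), connected components
#' are found on the voxel grid under the chosen neighbourhood, components
#' smaller than `min_region_voxels` are discarded, and survivors are
#' labelled `1..m` by decreasing size (ties by first voxel in the package
#' voxel order).
#'
#' @param values stability values over in-mask voxels.
#' @param mask 3D mask array.
#' @param stability_cut threshold on the stability score (default 0.5).
#' @param min_region_voxels minimum component size kept (default 50).
#' @param connectivity `"face"` (6-neighbourhood, default) or `"corner"`
#'   (26-neighbourhood).
#' @return integer 3D array of region labels (0 = background).
#' @export
extract_regions <- function(values, mask, stability_cut = 0.5,
                            min_region_voxels = 50,
                            connectivity = c("face", "corner")) {
  connectivity <- match.arg(connectivity)
  if (!(stability_cut > 0 && stability_cut < 1)) {
    stop("stability_cut must be in (0, 1)", call. = FALSE)
  }
  if (min_region_voxels < 1) stop("min_region_voxels must be >= 1", call. = FALSE)
  mask <- check_mask(mask)
  active <- unmask_volume(as.numeric(values > stability_cut), mask) != 0
  label_components(active, connectivity, min_region_voxels)
}

# connected-component labelling on a 3D logical array via igraph
label_components <- function(active, connectivity, min_size) {
  d <- dim(active)
  out <- array(0L, dim = d)
  n_active <- sum(active)
  if (n_active == 0) return(out)
  ids <- array(0L, dim = d)
  ids[active] <- seq_len(n_active)
  offsets <- if (connectivity == "face") {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
    g[g[, 1] > 0 | (g[, 1] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 3] > 0))), ,
      drop = FALSE]
  }
  edges <- list()
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    a_lo <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
    b_lo <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
    c_lo <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
    src <- ids[a_lo, b_lo, c_lo, drop = FALSE]
    dst <- ids[a_lo + o[1], b_lo + o[2], c_lo + o[3], drop = FALSE]
    both <- src > 0 & dst > 0
    if (any(both)) edges[[length(edges) + 1]] <- cbind(src[both], dst[both])
  }
  comp <- if (length(edges) == 0) {
    seq_len(n_active)
  } else {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n_active - igraph::vcount(g)))
    igraph::components(g)$membership
  }
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_size)
  if (length(keep) == 0) return(out)
  first_voxel <- vapply(keep, function(cid) {
    min(order_positions_of(ids, comp, cid))
  }, numeric(1))
  keep <- keep[order(-sizes[keep], first_voxel)]
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  lab_active <- relabel[comp]
  out[active] <- lab_active[ids[active]]
  out
}

# C-order rank of the voxels of one component (for deterministic tie-breaks)
order_positions_of <- function(ids, comp, cid) {
  d <- dim(ids)
  lin <- which(ids > 0)
  lin <- lin[comp[ids[lin]] == cid]
  ar <- arrayInd(lin, d)
  (ar[, 1] - 1) * d[2] * d[3] + (ar[, 2] - 1) * d[3] + ar[, 3]
}

#' Combine per-state region volumes into one atlas
#'
#' Assigns disjoint label ranges per state: regions of the first volume keep
#' their labels, later volumes are offset by the running maximum. Overlaps
#' (which cannot occur for regions from disjoint states) keep the earlier
#' label.
#'
#' @param region_volumes list of integer label arrays from
#'   [extract_regions()], ordered by state rank.
#' @return integer 3D label array.
#' @export
combine_region_atlases <- function(region_volumes) {
  if (length(region_volumes) == 0) stop("no region volumes", call. = FALSE)
  out <- array(0L, dim = dim(region_volumes[[1]]))
  offset <- 0L
  for (vol in region_volumes) {
    put <- vol > 0 & out == 0
    out[put] <- vol[put] + offset
    offset <- offset + max(0L, max(vol))
  }
  out
}
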