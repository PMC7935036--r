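#' Enumerate sliding windows over a time series
#'
#' Windows of `W` frames start at frame 0 and advance by `W - O` frames
#' (`O` frames of overlap between consecutive windows). A final window that
#' would not fit entirely inside the series is dropped.
#'
#' @param n_frames total number of frames.
#' @param W window length in frames.
#' @param O overlap between consecutive windows in frames (`0 <= O < W`).
#' @return list of class `window_spec` with `W`, `O` and 0-based `starts`.
#' @export
enumerate_windows <- function(n_frames, W, O) {
  if (O < 0 || O >= W) stop("overlap must satisfy 0 <= O < W", call. = FALSE)
  if (n_frames < W) {
    stop(sprintf("series of %d frames is shorter than window length %d",
                 n_frames, W), call. = FALSE)
  }
  starts <- seq.int(0L, n_frames - W, by = W - O)
  structure(list(W = as.integer(W), O = as.integer(O),
                 starts = as.integer(starts)),
            class = "window_spec")
}

#' Extract one time window from a run
#'
#' @param run a [bold_run()] or a voxel-by-time matrix.
#' @param start 0-based start frame.
#' @param W window length in frames.
#' @return voxel-by-`W` matrix of contiguous columns `[start, start + W)`.
#' @export
extract_window <- function(run, start, W) {
  x <- if (inherits(run, "bold_run")) run$data else as.matrix(run)
  if (start < 0 || start + W > ncol(x)) {
    stop(sprintf("window [%d, %d) out of range for %d frames",
                 start, start + W, ncol(x)), call. = FALSE)
  }
  x[, (start + 1):(start + W), drop = FALSE]
}

# k-means++ seeding: first center uniform, later centers with probability
# proportional to squared distance to the nearest chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  picks <- integer(k)
  picks[1] <- sample.int(n, 1L)
  if (k > 1) {
    rx2 <- rowSums(x^2)
    d2 <- pmax(0, rx2 - 2 * drop(x %*% x[picks[1], ]) + sum(x[picks[1], ]^2))
    for (j in 2:k) {
      tot <- sum(d2)
      picks[j] <- if (tot > 0) {
        sample.int(n, 1L, prob = d2 / tot)
      } else {
        sample(setdiff(seq_len(n), picks[seq_len(j - 1)]), 1L)
      }
      d2 <- pmax(0, pmin(d2, rx2 - 2 * drop(x %*% x[picks[j], ]) +
                           sum(x[picks[j], ]^2)))
    }
  }
  x[picks, , drop = FALSE]
}

# Lloyd iterations tolerant of empty clusters; fallback for the rare case
# where stats::kmeans refuses an initialization (it errors on empty clusters)
lloyd_kmeans <- function(x, centers, max_iter = 300, tol = 1e-4) {
  k <- nrow(centers)
  rx2 <- rowSums(x^2)
  labels <- integer(nrow(x))
  for (it in seq_len(max_iter)) {
    d2 <- outer(rx2, rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
    labels <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- labels == j
      if (any(members)) new_centers[j, ] <- colMeans(x[members, , drop = FALSE])
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift <= tol) break
  }
  labels
}

#' Parcellate one window with replicated k-means
#'
#' Voxels are the observations (features are the window's time points);
#' initial centers are drawn with the k-means++ rule, then refined with
#' Lloyd iterations. The result is deterministic given `rng_seed`.
#'
#' @param window_matrix voxel-by-time matrix of one window.
#' @param k number of parcels.
#' @param rng_seed integer seed for the initialization stream.
#' @param max_iter maximum k-means iterations.
#' @return list of class `window_parcellation` with integer `labels` in
#'   `1..k` (one per voxel, not re-compacted if a cluster empties),
#'   `k`, and `rng_seed`.
#' @export
parcellate_window <- function(window_matrix, k, rng_seed, max_iter = 300) {
  x <- as.matrix(window_matrix)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(x)) {
    stop(sprintf("k = %d exceeds the %d voxels", k, nrow(x)), call. = FALSE)
  }
  if (ncol(x) < 2) stop("window must have at least 2 frames", call. = FALSE)
  labels <- with_rng_seed(rng_seed, {
    if (k == 1) {
      rep(1L, nrow(x))
    } else {
      fit <- NULL
      for (attempt in 1:5) {
        centers <- kmeanspp_centers(x, k)
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(x, centers = centers,
                                         iter.max = max_iter,
                                         algorithm = "Lloyd")),
          error = function(e) NULL
        )
        if (!is.null(fit)) break
      }
      if (is.null(fit)) lloyd_kmeans(x, centers, max_iter) else fit$cluster
    }
  })
  structure(list(labels = as.integer(labels), k = as.integer(k),
                 rng_seed = as.integer(rng_seed)),
            class = "window_parcellation")
}

# evaluate expr under a local RNG state seeded with `seed`
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-(window, replication) seed scheme
replication_seed <- function(base_seed, window_index, n_replications,
                             replication_index) {
  as.integer((base_seed + window_index * n_replications + replication_index) %%
               .Machine$integer.max)
}

#' Replicated sliding-window parcellation of a run
#'
#' Runs [parcellate_window()] on every sliding window, `n_replications`
#' times per window with distinct deterministic seeds
#' (`base_seed + window_index * n_replications + replication_index`,
#' both indices 0-based). The output always contains exactly
#' `length(starts) * n_replications` parcellations.
#'
#' @param run a [bold_run()].
#' @param window_spec a [enumerate_windows()] result (or NULL to build one
#'   from `W` and `O` over the whole run).
#' @param k number of parcels per window.
#' @param n_replications k-means replications per window.
#' @param base_seed integer base seed.
#' @param W,O window length and overlap, used when `window_spec` is NULL.
#' @param forbid_spanning drop windows that span a run boundary inside a
#'   concatenation (off by default: windows may mix runs).
#' @param max_iter maximum k-means iterations.
#' @return list of class `sliding_parcellation`: `parcellations` (list of
#'   `window_parcellation`, each annotated with `window_index`,
#'   `replication_index`, `start`), `window_spec`, `k`, `n_replications`,
#'   `base_seed`.
#' @export
run_sliding_parcellation <- function(run, window_spec = NULL, k = 12,
                                     n_replications = 5, base_seed = 1,
                                     W = 100, O = 10,
                                     forbid_spanning = FALSE,
                                     max_iter = 300) {
  if (n_replications < 1) stop("n_replications must be >= 1", call. = FALSE)
  if (is.null(window_spec)) window_spec <- enumerate_windows(n_frames(run), W, O)
  starts <- window_spec$starts
  if (forbid_spanning && length(run$boundaries) > 1) {
    inner <- run$boundaries[-1]
    spans <- vapply(starts, function(s) {
      any(inner > s & inner < s + window_spec$W)
    }, logical(1))
    starts <- starts[!spans]
  }
  out <- vector("list", length(starts) * n_replications)
  pos <- 1L
  for (w in seq_along(starts)) {
    win <- extract_window(run, starts[w], window_spec$W)
    for (r in seq_len(n_replications)) {
      seed <- replication_seed(base_seed, w - 1L, n_replications, r - 1L)
      p <- parcellate_window(win, k, seed, max_iter = max_iter)
      p$window_index <- w - 1L
      p$replication_index <- r - 1L
      p$start <- starts[w]
      out[[pos]] <- p
      pos <- pos + 1L
    }
  }
  structure(list(parcellations = out, window_spec = window_spec,
                 starts_used = starts, k = as.integer(k),
                 n_replications = as.integer(n_replications),
                 base_seed = base_seed),
            class = "sliding_parcellation")
}
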