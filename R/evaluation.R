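#' Pearson correlation between two spatial maps
#'
#' Computed over all in-mask voxels; maps are never thresholded for scoring.
#'
#' @param map_a,map_b equal-length numeric vectors, each non-constant.
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson <- function(map_a, map_b) {
  if (length(map_a) != length(map_b)) stop("maps differ in length", call. = FALSE)
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0) {
    stop("Pearson undefined for a constant map", call. = FALSE)
  }
  stats::cor(map_a, map_b)
}

# Hungarian algorithm (shortest augmenting paths with potentials) for a
# square cost matrix; returns the column assigned to each row (minimization)
hungarian_solve <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)          # p[j+1]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j + 1] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) assignment[p[j + 1]] <- j
  assignment
}

#' Match two sets of state maps with the Hungarian method
#'
#' Finds the one-to-one pairing between set-1 and set-2 maps that maximizes
#' the total Pearson correlation (rectangular assignment when the sets
#' differ in size). Set-1 states without a counterpart are reported as
#' unmatched and score 0 downstream. Correlation ties are resolved
#' deterministically (the solver scans columns in order).
#'
#' @param maps_set1,maps_set2 matrices with one state map per row (equal
#'   column counts), or lists of map vectors.
#' @return list of class `match_result`: `pairs` (data frame `set1`, `set2`,
#'   `r`), `unmatched_set1`, `n1`, `n2`, `correlations` (full n1 x n2 Pearson
#'   matrix).
#' @export
hungarian_match <- function(maps_set1, maps_set2) {
  M1 <- to_dense_matrix(maps_set1)
  M2 <- to_dense_matrix(maps_set2)
  if (nrow(M1) == 0 || nrow(M2) == 0) stop("empty map set", call. = FALSE)
  R <- stats::cor(t(M1), t(M2))
  R <- matrix(R, nrow = nrow(M1), ncol = nrow(M2))
  n1 <- nrow(M1); n2 <- nrow(M2)
  s <- max(n1, n2)
  cost <- matrix(0, s, s)
  cost[seq_len(n1), seq_len(n2)] <- max(R) - R
  assign_col <- hungarian_solve(cost)
  pairs <- do.call(rbind, lapply(seq_len(n1), function(i) {
    j <- assign_col[i]
    if (j <= n2) data.frame(set1 = i, set2 = j, r = R[i, j]) else NULL
  }))
  if (is.null(pairs)) {
    pairs <- data.frame(set1 = integer(), set2 = integer(), r = numeric())
  }
  structure(list(pairs = pairs,
                 unmatched_set1 = setdiff(seq_len(n1), pairs$set1),
                 n1 = n1, n2 = n2, correlations = R),
            class = "match_result")
}

to_dense_matrix <- function(maps) {
  M <- if (is.list(maps)) do.call(rbind, maps) else as.matrix(maps)
  storage.mode(M) <- "double"
  M
}

#' Per-state reproducibility scores from a matching
#'
#' One score per set-1 state, in rank order: the Pearson r of its matched
#' set-2 state, or 0 when no counterpart exists.
#'
#' @param match a [hungarian_match()] result.
#' @return numeric vector of length `n1`.
#' @export
reproducibility_scores <- function(match) {
  scores <- numeric(match$n1)
  if (nrow(match$pairs) > 0) scores[match$pairs$set1] <- match$pairs$r
  scores
}

#' Between-subject similarity distribution
#'
#' Pearson r for every pair of state maps from different subjects, pooled
#' over state ranks and replication sets.
#'
#' @param maps_by_subject named list, one matrix of state maps (rows) per
#'   subject.
#' @return data frame with columns `subject_a`, `subject_b`, `map_a`,
#'   `map_b`, `r`.
#' @export
between_subject_scores <- function(maps_by_subject) {
  if (length(maps_by_subject) < 2) stop("need at least 2 subjects", call. = FALSE)
  subs <- names(maps_by_subject)
  if (is.null(subs)) subs <- as.character(seq_along(maps_by_subject))
  out <- list()
  for (a in seq_along(subs)) {
    for (b in seq_along(subs)) {
      if (a >= b) next
      R <- stats::cor(t(to_dense_matrix(maps_by_subject[[a]])),
                      t(to_dense_matrix(maps_by_subject[[b]])))
      R <- as.matrix(R)
      idx <- expand.grid(map_a = seq_len(nrow(R)), map_b = seq_len(ncol(R)))
      out[[length(out) + 1]] <- data.frame(
        subject_a = subs[a], subject_b = subs[b],
        map_a = idx$map_a, map_b = idx$map_b,
        r = R[cbind(idx$map_a, idx$map_b)])
    }
  }
  do.call(rbind, out)
}

#' Deterministic fingerprinting over a pool of state maps
#'
#' For each map in the pool, the best match is the most correlated map among
#' all other maps (the query itself is excluded; by default maps from the
#' query's own replication set remain candidates). A query succeeds when its
#' best match belongs to the same subject. Ties go to the lowest map index.
#'
#' @param maps matrix of state maps, one row per map.
#' @param subject subject label per map.
#' @param set replication-set label per map (used only when
#'   `exclude_same_set = TRUE`).
#' @param exclude_same_set also exclude candidates from the query's own
#'   subject-and-set (sensitivity analysis; off by default).
#' @return list of class `fingerprint_result`: `outcomes` (data frame
#'   `query`, `best_match`, `query_subject`, `match_subject`, `r`,
#'   `success`) and `accuracy`.
#' @export
deterministic_fingerprint <- function(maps, subject, set = NULL,
                                      exclude_same_set = FALSE) {
  M <- to_dense_matrix(maps)
  n <- nrow(M)
  if (n < 2) stop("fingerprinting needs a pool of at least 2 maps", call. = FALSE)
  if (length(subject) != n) stop("one subject label per map", call. = FALSE)
  R <- stats::cor(t(M))
  diag(R) <- -Inf
  if (exclude_same_set) {
    if (is.null(set)) stop("`set` labels required", call. = FALSE)
    same <- outer(subject, subject, "==") & outer(set, set, "==")
    R[same] <- -Inf
  }
  best <- max.col(R, ties.method = "first")
  outcomes <- data.frame(
    query = seq_len(n), best_match = best,
    query_subject = subject, match_subject = subject[best],
    r = R[cbind(seq_len(n), best)],
    success = subject == subject[best])
  structure(list(outcomes = outcomes, accuracy = mean(outcomes$success)),
            class = "fingerprint_result")
}

#' Chance-level fingerprinting accuracy
#'
#' Per iteration and per subject: one of the subject's maps is drawn
#' uniformly, then a second map is drawn uniformly from the whole pool
#' excluding the first; the draw succeeds when both maps belong to that
#' subject. With `m` maps per subject and `S` subjects the expected accuracy
#' is `(m - 1) / (S * m - 1)`.
#'
#' @param subject subject label per pooled map.
#' @param n_iter number of iterations (the evaluation protocol uses 1000).
#' @param rng_seed integer seed; fixed seed gives identical accuracy.
#' @return list with `accuracy`, `n_draws`, `successes`.
#' @export
chance_fingerprint <- function(subject, n_iter = 1000, rng_seed = 1) {
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  subject <- as.character(subject)
  subs <- unique(subject)
  n <- length(subject)
  successes <- with_rng_seed(rng_seed, {
    hits <- 0L
    for (it in seq_len(n_iter)) {
      for (s in subs) {
        own <- which(subject == s)
        first <- if (length(own) == 1) own else own[sample.int(length(own), 1)]
        second <- sample.int(n - 1, 1)
        if (second >= first) second <- second + 1L
        if (subject[second] == s) hits <- hits + 1L
      }
    }
    hits
  })
  n_draws <- n_iter * length(subs)
  list(accuracy = successes / n_draws, n_draws = n_draws,
       successes = successes)
}

#' Dwell times of spatially matched states
#'
#' Pairs the dwell fractions of matched states only; states without a
#' spatial counterpart are excluded, mirroring the split-half dwell-time
#' comparison protocol.
#'
#' @param match a [hungarian_match()] result.
#' @param dwell_set1,dwell_set2 dwell fractions per state, in the rank order
#'   used for matching.
#' @return data frame with columns `rank_set1`, `rank_set2`, `dwell_set1`,
#'   `dwell_set2`, `r`.
#' @export
compare_dwell_times <- function(match, dwell_set1, dwell_set2) {
  p <- match$pairs
  data.frame(rank_set1 = p$set1, rank_set2 = p$set2,
             dwell_set1 = dwell_set1[p$set1],
             dwell_set2 = dwell_set2[p$set2],
             r = p$r)
}
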