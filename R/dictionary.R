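# Training-phase motion extraction.
#
# Every example is segmented with four window sizes (0.5/1/1.5/2 s by
# default), each tiled three times at start offsets of 0%, 25% and 50% of the
# window size. All windows are resampled to a common base length, flattened,
# and clustered per activity with k-means. Small clusters are pruned (only
# often-repeating motions are of interest), overlapping survivors within a
# recording are resolved longest-first, and the surviving cluster centers of
# all activities are clustered once more into the motion dictionary, keeping
# provenance from every dictionary motion back to the windows that formed it.

#' Multi-scale sliding-window segmentation of a recording
#'
#' For each window size `w` (in frames: `round(w * frame_rate)`, half-up) and
#' each increment fraction `f`, non-overlapping windows are tiled from start
#' offset `round(f * frames)` for as long as they fit. Window content is
#' resampled to `base_len` frames and flattened. Sizes that do not fit the
#' recording contribute no windows.
#'
#' @param recording A `cav_recording`.
#' @param sizes_s Window sizes in seconds.
#' @param increments Start-offset fractions of the window size.
#' @param base_len Canonical frame count for the window vectors.
#' @return A `cav_windows` list: `meta` (data.frame with `recording_id`,
#'   `start_frame` 0-based, `length_frames`, `increment`) and `X` (one
#'   flattened window vector per row, `36 * base_len` columns).
#' @export
segment_windows <- function(recording, sizes_s = c(0.5, 1, 1.5, 2),
                            increments = c(0, 0.25, 0.5), base_len = 15L) {
  L <- nrow(recording$frames)
  m <- recording$frames
  meta <- list()
  vecs <- list()
  for (w in sizes_s) {
    frames_w <- as.integer(rnd(w * recording$frame_rate))
    if (frames_w < 1L || frames_w > L) next
    # within-window resampling indices are the same for every start
    ridx <- if (base_len == 1L) 1L
            else rnd((seq_len(base_len) - 1) * (frames_w - 1) / (base_len - 1)) + 1L
    for (f in increments) {
      offset <- as.integer(rnd(f * frames_w))
      if (offset > L - frames_w) next
      starts <- seq.int(offset, L - frames_w, by = frames_w)
      rows <- m[rep.int(starts, rep.int(base_len, length(starts))) +
                  rep.int(ridx, length(starts)), , drop = FALSE]
      block <- matrix(t(rows), length(starts), 36L * base_len, byrow = TRUE)
      vecs[[length(vecs) + 1L]] <- block
      meta[[length(meta) + 1L]] <-
        data.frame(recording_id = recording$recording_id,
                   start_frame = as.integer(starts),
                   length_frames = frames_w, increment = f)
    }
  }
  if (!length(meta)) {
    warning(sprintf("recording '%s' (%d frames) is shorter than the smallest window; no windows extracted",
                    recording$recording_id, L), call. = FALSE)
    return(structure(list(meta = data.frame(recording_id = character(),
                                            start_frame = integer(),
                                            length_frames = integer(),
                                            increment = numeric()),
                          X = matrix(numeric(), 0L, 36L * base_len)),
                     class = "cav_windows"))
  }
  structure(list(meta = do.call(rbind, meta),
                 X = do.call(rbind, vecs)),
            class = "cav_windows")
}

bind_windows <- function(window_sets) {
  window_sets <- Filter(function(w) nrow(w$meta) > 0L, window_sets)
  if (!length(window_sets))
    stop("no windows extracted from any recording", call. = FALSE)
  structure(list(meta = do.call(rbind, lapply(window_sets, `[[`, "meta")),
                 X = do.call(rbind, lapply(window_sets, `[[`, "X"))),
            class = "cav_windows")
}

#' Cluster one activity's windows with k-means
#'
#' Euclidean k-means (k-means++ seeding, best of `n_init` restarts) over the
#' flattened window vectors. `k` is reduced with a warning when it exceeds
#' the number of windows.
#'
#' @param windows A `cav_windows` set (all windows of one activity).
#' @param k Number of clusters.
#' @param seed Integer seed (set locally for determinism).
#' @param n_init Number of restarts.
#' @return List of motion clusters, each with `members` (row indices into
#'   `windows`), `centroid`, and `radius` (max member-to-centroid distance).
#' @export
cluster_activity_windows <- function(windows, k, seed = 1L, n_init = 10L) {
  n <- nrow(windows$X)
  if (n < 1L) stop("cannot cluster an empty window set", call. = FALSE)
  if (k > n) {
    warning(sprintf("k = %d exceeds the %d available windows; reduced", k, n),
            call. = FALSE)
    k <- n
  }
  set.seed(seed)
  fit <- cav_kmeans(windows$X, k, n_init = n_init)
  lapply(seq_len(fit$k), function(j) {
    members <- which(fit$cluster == j)
    centroid <- fit$centers[j, ]
    d <- sqrt(rowSums((windows$X[members, , drop = FALSE] -
                         matrix(centroid, length(members), length(centroid),
                                byrow = TRUE))^2))
    list(members = members, centroid = as.numeric(centroid),
         radius = if (length(d)) max(d) else 0)
  })
}

#' Drop sparsely populated motion clusters
#'
#' Only motions that repeat often are of interest: clusters with fewer than
#' `min_members` windows (default: five or fewer) are removed.
#'
#' @param clusters List of motion clusters.
#' @param min_members Minimum member count to keep a cluster.
#' @return Filtered cluster list (warns when empty).
#' @export
prune_clusters <- function(clusters, min_members = 6L) {
  kept <- Filter(function(cl) length(cl$members) >= min_members, clusters)
  if (!length(kept) && length(clusters))
    warning("all clusters dropped by pruning", call. = FALSE)
  kept
}

#' Resolve overlapping retained windows within one recording
#'
#' Windows are processed in descending length (ties: earlier start first,
#' then lower increment) and kept greedily when their half-open frame
#' interval `[start, start + length)` intersects no already-kept window, so
#' larger windows win over the smaller ones they overlap.
#'
#' @param meta Data frame of one recording's retained windows with columns
#'   `start_frame`, `length_frames`, `increment` (any extra columns, e.g. a
#'   cluster tag, are carried through).
#' @return The kept rows, sorted by `start_frame`.
#' @export
resolve_overlaps <- function(meta) {
  if (!nrow(meta)) return(meta)
  ord <- order(-meta$length_frames, meta$start_frame, meta$increment)
  kept_start <- integer(0)
  kept_end <- integer(0)
  keep <- logical(nrow(meta))
  for (i in ord) {
    s <- meta$start_frame[i]
    e <- s + meta$length_frames[i]
    if (!any(s < kept_end & e > kept_start)) {
      keep[i] <- TRUE
      kept_start <- c(kept_start, s)
      kept_end <- c(kept_end, e)
    }
  }
  out <- meta[keep, , drop = FALSE]
  out[order(out$start_frame), , drop = FALSE]
}

#' Build the motion dictionary from all activities' surviving clusters
#'
#' The surviving first-level cluster centers of every activity are clustered
#' once more with k-means so that near-duplicate motions shared between
#' activities collapse into a single dictionary entry. Provenance maps every
#' first-level cluster (and therefore every retained training window) to
#' exactly one motion ID. A motion's radius is the maximum, over its
#' contributing clusters, of (center distance + cluster radius), so it bounds
#' the distance from the dictionary centroid to any contributing window.
#'
#' @param per_activity_clusters Named list (by activity) of pruned cluster
#'   lists as returned by [cluster_activity_windows()].
#' @param k2 Dictionary size; `NULL` uses `ceiling(k2_fraction * n_centers)`.
#' @param k2_fraction Fraction used when `k2` is `NULL`.
#' @param seed Integer seed.
#' @param n_init Number of k-means restarts.
#' @param base_len Canonical window frame count (stored for matching).
#' @return A `cav_dictionary`: `centroids` (V x d matrix), `radius` (length
#'   V), `provenance` (data.frame `activity`, `cluster`, `motion_id`), and
#'   `base_len`. Motion IDs are contiguous integers starting at 0.
#' @export
build_dictionary <- function(per_activity_clusters, k2 = NULL,
                             k2_fraction = 0.75, seed = 1L, n_init = 10L,
                             base_len = 15L) {
  acts <- names(per_activity_clusters)
  centers <- list()
  radii <- numeric(0)
  activity <- character(0)
  local_idx <- integer(0)
  for (a in acts) {
    for (j in seq_along(per_activity_clusters[[a]])) {
      cl <- per_activity_clusters[[a]][[j]]
      centers[[length(centers) + 1L]] <- cl$centroid
      radii <- c(radii, cl$radius)
      activity <- c(activity, a)
      local_idx <- c(local_idx, j)
    }
  }
  n_centers <- length(centers)
  if (n_centers < 1L)
    stop("no surviving clusters to build a dictionary from", call. = FALSE)
  X <- do.call(rbind, centers)
  if (is.null(k2)) k2 <- as.integer(ceiling(k2_fraction * n_centers))
  if (k2 > n_centers) {
    warning(sprintf("dictionary k = %d exceeds the %d cluster centers; reduced",
                    k2, n_centers), call. = FALSE)
    k2 <- n_centers
  }
  set.seed(seed)
  fit <- cav_kmeans(X, k2, n_init = n_init)
  # collapse numerically identical second-level centers, if any
  key <- apply(round(fit$centers, 12L), 1L, paste, collapse = ",")
  uid <- match(key, unique(key))
  V <- length(unique(key))
  centroids <- matrix(0, V, ncol(X))
  for (v in seq_len(V)) centroids[v, ] <- fit$centers[which(uid == v)[1L], ]
  assign_v <- uid[fit$cluster]
  radius <- numeric(V)
  for (i in seq_len(n_centers)) {
    v <- assign_v[i]
    r <- euclid(centroids[v, ], X[i, ]) + radii[i]
    radius[v] <- max(radius[v], r)
  }
  structure(list(
    centroids = centroids,
    radius = radius,
    provenance = data.frame(activity = activity, cluster = local_idx,
                            motion_id = assign_v - 1L),
    base_len = as.integer(base_len)), class = "cav_dictionary")
}

#' @export
print.cav_dictionary <- function(x, ...) {
  cat(sprintf("<cav_dictionary> %d motions (base length %d frames) from %d first-level clusters across %d activities\n",
              nrow(x$centroids), x$base_len, nrow(x$provenance),
              length(unique(x$provenance$activity))))
  invisible(x)
}

dictionary_size <- function(dictionary) nrow(dictionary$centroids)
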