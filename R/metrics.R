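# Dataset-profiling metrics.
#
# Complexity of one recording: the sum, over whole-second circular time
# shifts s = 1..floor(duration), of the Euclidean distance between the
# flattened recording and its copy rotated by s seconds. Repetitive or
# constant signals score low (high self-similarity at some shift).
#
# Variation of a set: the mean pairwise Euclidean distance between the
# length-normalized (time-resampled) examples. Homogeneous sets score low.

euclid <- function(a, b) sqrt(sum((a - b)^2))

rotate_rows <- function(m, k) {
  L <- nrow(m)
  k <- ((k %% L) + L) %% L
  if (k == 0L) return(m)
  m[c((k + 1L):L, 1L:k), , drop = FALSE]
}

#' Activity complexity of a recording
#'
#' Sums the Euclidean distance between the recording and circularly
#' time-rotated copies of itself at every whole-second shift
#' `s = 1..floor(duration)`; a rotation by `s` seconds moves the first
#' `round(s * frame_rate)` frames to the end. Acts as an (inverse)
#' autocorrelation profile: constant or perfectly periodic signals score 0
#' at the matching shifts.
#'
#' @param recording A `cav_recording` of duration at least 2 s.
#' @return List with `complexity` and `normalized`
#'   (complexity / duration in seconds).
#' @export
activity_complexity <- function(recording) {
  dur <- duration_seconds(recording)
  if (dur < 2) stop("too short for the complexity metric (duration < 2 s)",
                    call. = FALSE)
  m <- recording$frames
  flat <- flatten_frames(m)
  shifts <- seq_len(floor(dur))
  total <- 0
  for (s in shifts) {
    shifted <- rotate_rows(m, rnd(s * recording$frame_rate))
    total <- total + euclid(flat, flatten_frames(shifted))
  }
  list(complexity = total, normalized = total / dur)
}

#' Variation of a set of recordings
#'
#' Each recording is first normalized to a common canonical frame count by
#' nearest-index resampling; the Variation is then the mean Euclidean distance
#' over all unordered distinct pairs of flattened normalized recordings.
#'
#' @param recordings List of at least two `cav_recording` objects.
#' @param canonical_len Common frame count; defaults to the set's minimum
#'   recording length.
#' @return List with `variation` and `normalized` (variation / mean duration
#'   in seconds of the set).
#' @export
set_variation <- function(recordings, canonical_len = NULL) {
  n <- length(recordings)
  if (n < 2L) stop("variation requires at least two recordings", call. = FALSE)
  lens <- vapply(recordings, function(r) nrow(r$frames), 0L)
  if (is.null(canonical_len)) canonical_len <- min(lens)
  flats <- vapply(recordings,
                  function(r) flatten_frames(resample_frames(r$frames, canonical_len)),
                  numeric(36L * canonical_len))
  d <- stats::dist(t(flats))
  mean_dur <- mean(vapply(recordings, duration_seconds, 0))
  list(variation = mean(d), normalized = mean(d) / mean_dur)
}

#' Per-activity metric profile of a dataset
#'
#' @param dataset A `cav_dataset`.
#' @param canonical_len Optional canonical frame count for Variation
#'   (default: per-activity minimum length).
#' @return Data frame with one row per activity: mean Complexity over its
#'   examples, Variation of the example set, and length-normalized variants.
#'   Activities with a single example get `NA` Variation; recordings shorter
#'   than 2 s are skipped for Complexity.
#' @export
dataset_metrics <- function(dataset, canonical_len = NULL) {
  labels <- dataset$activity_set
  rows <- lapply(labels, function(lab) {
    recs <- Filter(function(r) r$label == lab, dataset$recordings)
    comp <- vapply(recs, function(r) {
      if (duration_seconds(r) < 2) return(NA_real_)
      activity_complexity(r)$complexity
    }, 0)
    comp_norm <- comp / vapply(recs, duration_seconds, 0)
    if (length(recs) >= 2L) {
      v <- set_variation(recs, canonical_len)
    } else {
      v <- list(variation = NA_real_, normalized = NA_real_)
    }
    data.frame(activity = lab,
               n_examples = length(recs),
               mean_complexity = mean(comp, na.rm = TRUE),
               mean_complexity_normalized = mean(comp_norm, na.rm = TRUE),
               variation = v$variation,
               variation_normalized = v$normalized)
  })
  do.call(rbind, rows)
}
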