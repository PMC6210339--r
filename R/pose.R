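#' @keywords internal
"_PACKAGE"

# Nine-segment body model: torso plus left/right upper arm, forearm, thigh and
# shank. Each segment's orientation is a unit quaternion (w, x, y, z), so a
# pose is a length-36 numeric vector and a recording an L x 36 matrix.

N_SEGMENTS <- 9L
QUAT_COMPONENTS <- c("w", "x", "y", "z")

#' Default body-segment labels
#'
#' The package's fixed nine-segment body model: the torso plus the left and
#' right upper arm, forearm, thigh and shank. Labels are configurable in the
#' dataset manifest; the count and order are not.
#'
#' @return Character vector of nine segment labels.
#' @export
cav_segments <- function() {
  c("torso",
    "upper_arm_l", "upper_arm_r",
    "forearm_l", "forearm_r",
    "thigh_l", "thigh_r",
    "shank_l", "shank_r")
}

pose_colnames <- function(segments = cav_segments()) {
  as.vector(t(outer(segments, QUAT_COMPONENTS, paste, sep = "_")))
}

# round-half-up: all frame-count / index arithmetic uses this, not base round()
# (banker's rounding), so window counts match their closed forms exactly.
rnd <- function(x) floor(x + 0.5)

as_pose_matrix <- function(frames) {
  if (is.null(dim(frames))) {
    if (length(frames) %% (4L * N_SEGMENTS) != 0L)
      stop("pose data length must be a multiple of 36", call. = FALSE)
    frames <- matrix(frames, ncol = 4L * N_SEGMENTS, byrow = TRUE)
  }
  frames <- as.matrix(frames)
  if (ncol(frames) != 4L * N_SEGMENTS)
    stop(sprintf("pose matrix must have %d columns, got %d",
                 4L * N_SEGMENTS, ncol(frames)), call. = FALSE)
  if (!all(is.finite(frames)))
    stop("pose matrix contains non-finite values", call. = FALSE)
  storage.mode(frames) <- "double"
  frames
}

#' Canonicalize quaternion poses
#'
#' Renormalizes every segment quaternion to unit length and resolves the
#' q/-q sign ambiguity by forcing the scalar component to be non-negative
#' (hemisphere canonicalization). When w is exactly zero the sign of the first
#' nonzero vector component decides. This makes Euclidean distances between
#' poses well defined.
#'
#' @param frames A pose (length-36 vector) or an L x 36 pose matrix.
#' @return Canonicalized object of the same shape.
#' @export
canonicalize_poses <- function(frames) {
  vec <- is.null(dim(frames)) && length(frames) == 4L * N_SEGMENTS
  m <- as_pose_matrix(frames)
  for (s in seq_len(N_SEGMENTS)) {
    cols <- (4L * (s - 1L) + 1L):(4L * s)
    q <- m[, cols, drop = FALSE]
    nrm <- sqrt(rowSums(q * q))
    bad <- nrm < 1e-12
    if (any(bad))
      stop(sprintf("zero-norm quaternion at frame %d, segment %d",
                   which(bad)[1L], s), call. = FALSE)
    # leave already-unit rows untouched so canonicalization is a bitwise
    # no-op on canonical data (exact idempotence, exact file round-trips)
    renorm <- abs(nrm - 1) > 1e-9
    if (any(renorm)) q[renorm, ] <- q[renorm, , drop = FALSE] / nrm[renorm]
    # hemisphere: w >= 0; tie at w == 0 broken by first nonzero of (x, y, z)
    flip <- q[, 1L] < 0
    tie <- q[, 1L] == 0
    if (any(tie)) {
      for (i in which(tie)) {
        nz <- q[i, 2:4][q[i, 2:4] != 0]
        if (length(nz) && nz[1L] < 0) flip[i] <- TRUE
      }
    }
    q[flip, ] <- -q[flip, , drop = FALSE]
    m[, cols] <- q
  }
  if (vec) as.vector(m[1L, ]) else m
}

#' Resample a pose sequence to a fixed length by nearest-index decimation
#'
#' Picks `target_len` frames at indices `round(i * (L - 1) / (target_len - 1))`
#' (0-based, half-up rounding) so the first and last frames are always kept.
#' No interpolation is performed: sub-sampling keeps genuine observed poses.
#'
#' @param frames L x 36 pose matrix.
#' @param target_len Positive integer number of output frames.
#' @return A `target_len` x 36 pose matrix.
#' @export
resample_frames <- function(frames, target_len) {
  m <- as_pose_matrix(frames)
  L <- nrow(m)
  if (L < 1L) stop("cannot resample an empty pose sequence", call. = FALSE)
  target_len <- as.integer(target_len)
  if (target_len < 1L) stop("target_len must be >= 1", call. = FALSE)
  if (target_len == 1L) return(m[1L, , drop = FALSE])
  idx <- rnd((seq_len(target_len) - 1) * (L - 1) / (target_len - 1)) + 1L
  m[idx, , drop = FALSE]
}

#' Flatten a pose sequence to a single vector
#'
#' Frame-major order: frame 1's 36 components, then frame 2's, and so on.
#' Euclidean distance between two flattened equal-length sequences is the
#' distance used throughout clustering, matching and the dataset metrics.
#'
#' @param frames L x 36 pose matrix.
#' @return Numeric vector of length 36 * L.
#' @export
flatten_frames <- function(frames) {
  as.vector(t(as_pose_matrix(frames)))
}

#' Construct a labeled activity recording
#'
#' @param frames L x 36 pose matrix (or length-36k vector), one row per frame.
#' @param frame_rate Frames per second (positive).
#' @param label Activity label.
#' @param subject_id Subject identifier.
#' @param recording_id Unique recording identifier.
#' @param segments Optional segment labels (length 9).
#' @param canonicalize Canonicalize quaternions (default TRUE).
#' @return A `cav_recording` object.
#' @export
cav_recording <- function(frames, frame_rate, label, subject_id, recording_id,
                          segments = cav_segments(), canonicalize = TRUE) {
  m <- as_pose_matrix(frames)
  if (nrow(m) < 1L) stop("recording must contain at least one frame", call. = FALSE)
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("frame_rate must be a positive scalar", call. = FALSE)
  if (length(segments) != N_SEGMENTS)
    stop("segments must have length 9", call. = FALSE)
  if (canonicalize) m <- canonicalize_poses(m)
  colnames(m) <- pose_colnames(segments)
  structure(
    list(frames = m,
         frame_rate = as.numeric(frame_rate),
         label = as.character(label),
         subject_id = as.character(subject_id),
         recording_id = as.character(recording_id),
         segments = as.character(segments)),
    class = "cav_recording")
}

#' @export
print.cav_recording <- function(x, ...) {
  cat(sprintf("<cav_recording> %s: '%s' by %s — %d frames @ %g Hz (%.2f s)\n",
              x$recording_id, x$label, x$subject_id,
              nrow(x$frames), x$frame_rate, duration_seconds(x)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording A `cav_recording`.
#' @return Numeric scalar, `nrow(frames) / frame_rate`.
#' @export
duration_seconds <- function(recording) {
  nrow(recording$frames) / recording$frame_rate
}

#' Bundle recordings into a labeled dataset
#'
#' @param recordings List of `cav_recording` objects with unique ids.
#' @param activity_set Optional ordered label set; defaults to sorted unique
#'   labels present in the recordings.
#' @return A `cav_dataset` object.
#' @export
cav_dataset <- function(recordings, activity_set = NULL) {
  if (!length(recordings)) {
    recordings <- list()
  }
  for (r in recordings) {
    if (!inherits(r, "cav_recording"))
      stop("all recordings must be cav_recording objects", call. = FALSE)
  }
  ids <- vapply(recordings, `[[`, "", "recording_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate recording_id: %s", ids[duplicated(ids)][1L]),
         call. = FALSE)
  labels <- vapply(recordings, `[[`, "", "label")
  if (is.null(activity_set)) activity_set <- sort(unique(labels))
  if (!all(labels %in% activity_set))
    stop("recording labels outside the declared activity_set", call. = FALSE)
  names(recordings) <- ids
  structure(list(recordings = recordings,
                 activity_set = as.character(activity_set)),
            class = "cav_dataset")
}

#' @export
print.cav_dataset <- function(x, ...) {
  labels <- vapply(x$recordings, `[[`, "", "label")
  cat(sprintf("<cav_dataset> %d recordings, %d activities\n",
              length(x$recordings), length(x$activity_set)))
  if (length(labels)) print(table(labels))
  invisible(x)
}

dataset_labels <- function(dataset) {
  vapply(dataset$recordings, `[[`, "", "label")
}

dataset_subjects <- function(dataset) {
  vapply(dataset$recordings, `[[`, "", "subject_id")
}

subset_dataset <- function(dataset, ids) {
  cav_dataset(dataset$recordings[ids], activity_set = dataset$activity_set)
}
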