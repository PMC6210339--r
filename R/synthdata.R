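# Synthetic multi-subject pose datasets with planted motion primitives.
#
# Each activity is a grammar over a shared pool of short motion primitives
# (smooth single-axis oscillations per body segment, 0.5 or 1 s long). An
# example is a concatenation of rendered primitive instances; a
# variation_level knob in [0, 1] scales every source of within-class
# heterogeneity: optional-step dropout, step reordering, repeat counts,
# speed, left/right mirroring, idle insertions and quaternion noise. At
# variation_level 0 every subject produces an identical recording, so the
# Variation metric of each class is exactly 0. Primitive durations sit on a
# 0.5 s grid so that, without speed variation, the multi-scale window tiling
# aligns exactly with primitive instances and the dictionary can recover the
# planted primitives.

derive_seed <- function(seed, a, s) {
  as.integer(((as.numeric(seed) %% 1e6) * 1009 + a * 101 + s * 7) %% 2147483629)
}

#' Deterministic pool of motion primitives
#'
#' Primitive `p` rotates each body segment about a fixed axis with a smooth
#' sinusoidal angle profile; amplitude, frequency and phase vary by
#' `(p, segment)` through fixed formulas, so the pool needs no RNG.
#' Durations alternate between 0.5 s and 1 s (short repeated motions).
#'
#' @param n_primitives Pool size (default 19: two signature primitives per
#'   activity for eight activities, two shared grounding primitives, and one
#'   near-still rest primitive).
#' @return List of primitive specs: `primitive_id`, `duration_s`, and
#'   per-segment `axis` (unit 3-vector), `amplitude` (rad), `frequency` (Hz),
#'   `phase`.
#' @export
default_primitive_pool <- function(n_primitives = 19L) {
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  pool <- lapply(seq_len(n_primitives), function(p) {
    segs <- lapply(seq_len(N_SEGMENTS), function(j) {
      active <- ((p + j) %% 3L) == 0L
      list(axis = axes[[((p * j) %% 3L) + 1L]],
           amplitude = if (active) 0.9 else 0.15,
           frequency = 0.5 + 0.25 * ((p + j) %% 4L),
           phase = 2 * pi * ((p * j) %% 7L) / 7)
    })
    list(primitive_id = p,
         duration_s = if (p %% 2L == 1L) 0.5 else 1.0,
         segments = segs)
  })
  # the last pool entry is a universal rest posture (near-still sway): real
  # recordings open with the subject at rest, which every activity shares
  pool[[n_primitives]]$duration_s <- 1.0
  pool[[n_primitives]]$segments <- lapply(
    pool[[n_primitives]]$segments, function(s) {
      s$amplitude <- 0.05
      s$frequency <- 0.25
      s
    })
  pool
}

#' Render a primitive into canonical pose frames
#'
#' Produces `round(duration_s / speed * frame_rate)` frames; the angle
#' profile is evaluated over the primitive's own duration so speed changes
#' the frame count, not the shape. Mirroring swaps each left/right segment
#' pair and negates the y and z quaternion components (reflection through
#' the sagittal plane); applying it twice is the identity.
#'
#' @param spec Primitive spec from [default_primitive_pool()].
#' @param frame_rate Frames per second.
#' @param speed Speed multiplier (> 0); 2 halves the frame count.
#' @param mirrored Left/right mirror flag.
#' @return L x 36 canonical pose matrix.
#' @export
render_primitive <- function(spec, frame_rate, speed = 1, mirrored = FALSE) {
  n <- max(1L, as.integer(rnd(spec$duration_s / speed * frame_rate)))
  u <- if (n == 1L) 0 else (seq_len(n) - 1L) / (n - 1L) * spec$duration_s
  m <- matrix(0, n, 4L * N_SEGMENTS)
  for (j in seq_len(N_SEGMENTS)) {
    sg <- spec$segments[[j]]
    angle <- sg$amplitude * sin(2 * pi * sg$frequency * u + sg$phase)
    cols <- (4L * (j - 1L) + 1L):(4L * j)
    m[, cols[1L]] <- cos(angle / 2)
    m[, cols[2L]] <- sin(angle / 2) * sg$axis[1L]
    m[, cols[3L]] <- sin(angle / 2) * sg$axis[2L]
    m[, cols[4L]] <- sin(angle / 2) * sg$axis[3L]
  }
  if (mirrored) m <- mirror_frames(m)
  canonicalize_poses(m)
}

# left/right pairs in the nine-segment order (torso has no pair)
MIRROR_PAIRS <- list(c(2L, 3L), c(4L, 5L), c(6L, 7L), c(8L, 9L))

mirror_frames <- function(m) {
  out <- m
  for (pair in MIRROR_PAIRS) {
    a <- (4L * (pair[1L] - 1L) + 1L):(4L * pair[1L])
    b <- (4L * (pair[2L] - 1L) + 1L):(4L * pair[2L])
    out[, a] <- m[, b]
    out[, b] <- m[, a]
  }
  for (j in seq_len(N_SEGMENTS)) {
    cols <- (4L * (j - 1L) + 1L):(4L * j)
    out[, cols[3L]] <- -out[, cols[3L]]
    out[, cols[4L]] <- -out[, cols[4L]]
  }
  out
}

idle_frames <- function(duration_s, frame_rate) {
  n <- max(1L, as.integer(rnd(duration_s * frame_rate)))
  pose <- rep(c(1, 0, 0, 0), N_SEGMENTS)
  matrix(pose, n, 4L * N_SEGMENTS, byrow = TRUE)
}

#' Build the grammars of a synthetic activity set
#'
#' Activity `a` combines a grounding primitive shared within its activity
#' group (emulating, e.g., "motions while sitting" shared by several
#' activities) with its own two signature primitives as mandatory steps; its
#' neighbor's signature and a second grounding bout are optional steps that
#' appear only as variation, so activities sharing motions can be confused.
#' All knob magnitudes scale linearly with `variation_level`; at 0 every
#' example of an activity is identical.
#'
#' @param n_activities Number of activities.
#' @param variation_level Within-class heterogeneity knob in \[0, 1\].
#' @param pool Primitive pool; needs at least `n_activities + 2` primitives.
#' @return Named list of grammars (label, steps, knobs).
#' @export
build_activity_grammars <- function(n_activities = 8L, variation_level = 0.2,
                                    pool = default_primitive_pool()) {
  v <- variation_level
  stopifnot(v >= 0, v <= 1)
  if (length(pool) < 2L * n_activities + 2L)
    stop("primitive pool too small for the requested activities", call. = FALSE)
  shared_ids <- c(2L * n_activities + 1L, 2L * n_activities + 2L)
  # baseline repeats chosen so each step lasts about `target_s` seconds
  reps_for <- function(pid, target_s)
    max(1L, as.integer(rnd(target_s / pool[[pid]]$duration_s)))
  grammars <- lapply(seq_len(n_activities), function(a) {
    shared <- shared_ids[(a > n_activities / 2) + 1L]
    sig_a <- a                   # first signature
    sig_b <- n_activities + a    # second signature
    neighbor <- (a %% n_activities) + 1L
    step <- function(pid, target_s, optional = FALSE) {
      lo <- reps_for(pid, target_s)
      list(primitive_id = as.integer(pid), optional = optional,
           repeat_range = c(lo, lo + 2L))
    }
    steps <- list(
      step(shared, 2),
      step(sig_a, 3),
      step(sig_b, 3),
      step(sig_a, 2),
      step(neighbor, 1, optional = TRUE),
      step(shared, 1, optional = TRUE))
    list(label = sprintf("activity%d", a),
         steps = steps,
         mirror_prob = 0.5 * v,
         repeat_spread = v,           # fraction of each repeat range in play
         speed_spread = 0.25 * v,     # speeds drawn from 1 +/- spread
         reorder_prob = 0.3 * v,
         idle_rate = 0.5 * v,         # per-junction idle-insertion prob
         include_prob = 0.5 * v,      # optional steps appear as variation
         noise_sd = 0.02 * v)
  })
  names(grammars) <- vapply(grammars, `[[`, "", "label")
  grammars
}

#' Generate one synthetic activity example
#'
#' Samples step presence, order, repeats, speed and per-step left/right
#' mirroring from the grammar's knobs (using R's current RNG state),
#' concatenates the rendered primitive instances with optional idle
#' insertions, adds quaternion-component Gaussian noise, and
#' re-canonicalizes. With every knob at zero the output is fully
#' deterministic. Mirroring is decided per step, not per example, mirroring
#' how subjects choose a hand per action; an example with some mirrored
#' steps therefore still shares its remaining motions with its class.
#'
#' @param grammar One grammar from [build_activity_grammars()].
#' @param subject_id Subject identifier.
#' @param recording_id Recording identifier.
#' @param frame_rate Frames per second.
#' @param pool Primitive pool the grammar indexes into.
#' @return List `recording` (a `cav_recording`) and `truth` (data frame of
#'   realized primitive instances with 0-based frame spans).
#' @export
generate_example <- function(grammar, subject_id, recording_id,
                             frame_rate = 30, pool = default_primitive_pool()) {
  steps <- grammar$steps
  # optional-step dropout
  keep <- vapply(steps, function(st)
    !st$optional || stats::runif(1) < grammar$include_prob, TRUE)
  steps <- steps[keep]
  # adjacent swaps
  if (length(steps) > 1L) {
    for (i in seq_len(length(steps) - 1L)) {
      if (stats::runif(1) < grammar$reorder_prob) {
        steps[c(i, i + 1L)] <- steps[c(i + 1L, i)]
      }
    }
  }
  blocks <- list()
  truth <- list()
  cursor <- 0L
  push <- function(frames, pid, speed, mir) {
    blocks[[length(blocks) + 1L]] <<- frames
    truth[[length(truth) + 1L]] <<-
      data.frame(primitive_id = pid, start_frame = cursor,
                 end_frame = cursor + nrow(frames), speed = speed,
                 mirrored = mir)
    cursor <<- cursor + nrow(frames)
  }
  for (st in steps) {
    reps_max <- st$repeat_range[1L] +
      rnd(grammar$repeat_spread * diff(st$repeat_range))
    reps <- if (reps_max > st$repeat_range[1L])
      sample(st$repeat_range[1L]:reps_max, 1L) else st$repeat_range[1L]
    speed <- if (grammar$speed_spread > 0)
      stats::runif(1, 1 - grammar$speed_spread, 1 + grammar$speed_spread)
    else 1
    # hand/side choice is made per step, as in real activity variation
    # ("using the right or left hand to ..."): a varied example still shares
    # its other steps with the rest of its class
    mirrored <- stats::runif(1) < grammar$mirror_prob
    for (r in seq_len(reps)) {
      push(render_primitive(pool[[st$primitive_id]], frame_rate,
                            speed = speed, mirrored = mirrored),
           st$primitive_id, speed, mirrored)
    }
    if (stats::runif(1) < grammar$idle_rate) {
      dur <- sample(c(0.5, 1), 1L)
      push(idle_frames(dur, frame_rate), NA_integer_, 1, FALSE)
    }
  }
  frames <- do.call(rbind, blocks)
  if (grammar$noise_sd > 0) {
    frames <- frames + matrix(stats::rnorm(length(frames),
                                           sd = grammar$noise_sd),
                              nrow(frames))
  }
  rec <- cav_recording(frames, frame_rate, grammar$label, subject_id,
                       recording_id)
  list(recording = rec, truth = do.call(rbind, truth))
}

#' Generate a full synthetic multi-subject dataset
#'
#' Emulates a study where each of `n_subjects` performs each activity once.
#' Each (activity, subject) recording is generated from its own RNG
#' substream derived from `seed`, so the dataset is fully reproducible and
#' insensitive to generation order. Subjects alternate between two strata
#' (reported in `subject_attrs`, usable for stratified holdout).
#'
#' @param n_activities Number of activity classes.
#' @param n_subjects Number of subjects.
#' @param variation_level Heterogeneity knob in \[0, 1\].
#' @param frame_rate Frames per second.
#' @param seed Integer master seed.
#' @param pool Primitive pool.
#' @return List with `dataset` (a `cav_dataset`), `truth` (per-recording
#'   realized primitive spans), `planted` (matrix of planted primitive
#'   base-length vectors given `base_len`), `subject_attrs`.
#' @export
generate_dataset <- function(n_activities = 8L, n_subjects = 15L,
                             variation_level = 0.2, frame_rate = 30,
                             seed = 1L, pool = default_primitive_pool()) {
  grammars <- build_activity_grammars(n_activities, variation_level, pool)
  recordings <- list()
  truth <- list()
  for (a in seq_len(n_activities)) {
    for (s in seq_len(n_subjects)) {
      set.seed(derive_seed(seed, a, s))
      rid <- sprintf("act%02d_sub%02d", a, s)
      ex <- generate_example(grammars[[a]], sprintf("subj%02d", s), rid,
                             frame_rate, pool)
      recordings[[rid]] <- ex$recording
      truth[[rid]] <- ex$truth
    }
  }
  subjects <- sprintf("subj%02d", seq_len(n_subjects))
  attrs <- stats::setNames(ifelse(seq_len(n_subjects) %% 2L == 1L, "f", "m"),
                           subjects)
  ds <- cav_dataset(unname(recordings),
                    activity_set = sprintf("activity%d", seq_len(n_activities)))
  list(dataset = ds, truth = truth,
       planted = planted_primitive_vectors(pool, frame_rate),
       subject_attrs = attrs)
}

#' Base-length vectors of the planted primitives
#'
#' @param pool Primitive pool.
#' @param frame_rate Frames per second used at generation.
#' @param base_len Canonical window frame count (defaults to the 0.5 s
#'   window at this frame rate, matching the training default).
#' @return Matrix with one flattened, resampled primitive per row.
#' @export
planted_primitive_vectors <- function(pool, frame_rate,
                                      base_len = as.integer(rnd(0.5 * frame_rate))) {
  t(vapply(pool, function(spec)
    flatten_frames(resample_frames(render_primitive(spec, frame_rate),
                                   base_len)),
    numeric(36L * base_len)))
}
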