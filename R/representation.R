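# Per-example activity representations.
#
# A training example becomes a sequence of dictionary motion IDs (via the
# provenance of its overlap-resolved retained windows); an observation is
# encoded by greedy multi-scale matching against the dictionary. Each
# example is then summarized by (a) a tf-idf-weighted motion histogram with a
# stop list over the most frequent motions and (b) a smoothed first-order
# transition matrix plus initial-motion probabilities.

#' Motion-ID sequence constructor
#'
#' @param recording_id Recording identifier.
#' @param ids Integer motion IDs (0-based dictionary IDs).
#' @param start_frames Parallel 0-based start frames, strictly increasing.
#' @return A `cav_motion_seq`.
#' @export
motion_sequence <- function(recording_id, ids, start_frames) {
  ids <- as.integer(ids)
  start_frames <- as.integer(start_frames)
  if (length(ids) != length(start_frames))
    stop("ids and start_frames must be parallel", call. = FALSE)
  if (length(start_frames) > 1L && any(diff(start_frames) <= 0L))
    stop("start_frames must be strictly increasing", call. = FALSE)
  structure(list(recording_id = as.character(recording_id),
                 ids = ids, start_frames = start_frames),
            class = "cav_motion_seq")
}

#' Encode a training example through dictionary provenance
#'
#' The recording's retained, overlap-resolved windows (already tagged with
#' their first-level cluster) are mapped to motion IDs via the dictionary's
#' provenance and ordered by start frame. This is exact: no matching
#' threshold is involved for training examples.
#'
#' @param resolved Data frame of the recording's overlap-resolved windows
#'   with columns `start_frame`, `activity`, `cluster`.
#' @param dictionary A `cav_dictionary`.
#' @param recording_id Recording identifier.
#' @return A `cav_motion_seq` (empty, with a warning, when the recording has
#'   no retained windows).
#' @export
encode_training_example <- function(resolved, dictionary, recording_id) {
  if (!nrow(resolved)) {
    warning(sprintf("recording '%s' has no retained windows; empty motion sequence",
                    recording_id), call. = FALSE)
    return(motion_sequence(recording_id, integer(0), integer(0)))
  }
  key <- paste(resolved$activity, resolved$cluster)
  prov_key <- paste(dictionary$provenance$activity,
                    dictionary$provenance$cluster)
  idx <- match(key, prov_key)
  if (anyNA(idx))
    stop("window cluster missing from dictionary provenance", call. = FALSE)
  ids <- dictionary$provenance$motion_id[idx]
  ord <- order(resolved$start_frame)
  motion_sequence(recording_id, ids[ord], resolved$start_frame[ord])
}

#' Encode an observation by greedy dictionary matching
#'
#' A left-to-right scan over the observation: at each cursor position the
#' window sizes are tried longest-first; a size matches when the nearest
#' dictionary centroid lies within `tau` times that motion's radius. On a
#' match the motion ID is emitted and the cursor jumps to the window's end;
#' otherwise it advances by `round(step_fraction * smallest window)` frames.
#' The scan stops when the smallest window no longer fits.
#'
#' @param recording A `cav_recording`.
#' @param dictionary A `cav_dictionary`.
#' @param sizes_s Window sizes in seconds (as used in training).
#' @param tau Match threshold multiplier on the motion radius; `Inf` disables
#'   the threshold so every attempted window matches its nearest centroid.
#' @param step_fraction Cursor advance fraction on a failed match.
#' @return A `cav_motion_seq` (possibly empty).
#' @export
encode_observation <- function(recording, dictionary,
                               sizes_s = c(0.5, 1, 1.5, 2),
                               tau = 1.0, step_fraction = 0.25) {
  L <- nrow(recording$frames)
  frames_all <- unique(as.integer(rnd(sizes_s * recording$frame_rate)))
  frames_all <- sort(frames_all[frames_all >= 1L], decreasing = TRUE)
  if (!length(frames_all))
    return(motion_sequence(recording$recording_id, integer(0), integer(0)))
  smallest <- min(frames_all)
  step <- max(1L, as.integer(rnd(step_fraction * smallest)))
  ids <- integer(0)
  starts <- integer(0)
  cursor <- 0L
  while (cursor + smallest <= L) {
    matched <- FALSE
    for (fw in frames_all) {
      if (cursor + fw > L) next
      content <- recording$frames[(cursor + 1L):(cursor + fw), , drop = FALSE]
      v <- flatten_frames(resample_frames(content, dictionary$base_len))
      d2 <- rowSums((dictionary$centroids -
                       matrix(v, nrow(dictionary$centroids), length(v),
                              byrow = TRUE))^2)
      nearest <- which.min(d2)
      if (is.infinite(tau) || sqrt(d2[nearest]) <= tau * dictionary$radius[nearest]) {
        ids <- c(ids, nearest - 1L)
        starts <- c(starts, cursor)
        cursor <- cursor + fw
        matched <- TRUE
        break
      }
    }
    if (!matched) cursor <- cursor + step
  }
  motion_sequence(recording$recording_id, ids, starts)
}

#' Motion occurrence histogram
#'
#' @param seq A `cav_motion_seq` (or integer vector of motion IDs).
#' @param vocab_size Dictionary size V.
#' @return Integer count vector of length V (index i counts motion ID i - 1).
#' @export
motion_histogram <- function(seq, vocab_size) {
  ids <- if (inherits(seq, "cav_motion_seq")) seq$ids else as.integer(seq)
  if (length(ids) && (min(ids) < 0L || max(ids) >= vocab_size))
    stop("motion ID outside the dictionary vocabulary", call. = FALSE)
  tabulate(ids + 1L, nbins = vocab_size)
}

#' Fit the tf-idf model and stop list on the training corpus
#'
#' Documents are training examples, terms are dictionary motions.
#' `idf(t) = ln(N / df(t))` with `df(t)` the number of examples containing
#' motion t; motions never seen get idf 0 (treated as ubiquitous). The stop
#' list holds the `floor(stop_fraction * V)` most often occurring motions,
#' ranked by document frequency (ties: larger total corpus count, then the
#' lower motion ID) — a stop list targets motions common to most examples,
#' not motions concentrated in one class. It is fixed at training time and
#' reused for observations.
#'
#' @param histograms Matrix of training histograms (one row per example,
#'   V columns).
#' @param stop_fraction Stop-list fraction of the vocabulary.
#' @return A `cav_tfidf` list: `idf`, `doc_freq`, `n_docs`, `stop_ids`
#'   (0-based motion IDs), `keep` (logical length V).
#' @export
fit_tfidf <- function(histograms, stop_fraction = 0.05) {
  histograms <- rbind(histograms)
  N <- nrow(histograms)
  if (N < 1L) stop("tf-idf needs at least one histogram", call. = FALSE)
  V <- ncol(histograms)
  df <- colSums(histograms > 0)
  idf <- ifelse(df == 0, 0, log(N / pmax(df, 1)))
  total <- colSums(histograms)
  n_stop <- floor(stop_fraction * V)
  stop_ids <- integer(0)
  if (n_stop >= 1L) {
    ord <- order(-df, -total, seq_len(V))
    stop_ids <- sort(ord[seq_len(n_stop)] - 1L)
  }
  keep <- !(seq_len(V) - 1L) %in% stop_ids
  structure(list(idf = as.numeric(idf), doc_freq = as.integer(df),
                 n_docs = N, stop_ids = stop_ids, keep = keep),
            class = "cav_tfidf")
}

#' Apply log-normalized tf-idf weighting and the stop list
#'
#' `weight(t) = (1 + ln(count(t))) * idf(t)` for positive counts, 0
#' otherwise; stop-list coordinates are removed from the result.
#'
#' @param counts Count vector of length V.
#' @param model A `cav_tfidf`.
#' @return Weighted vector over the non-stop vocabulary, named by motion ID.
#' @export
apply_tfidf <- function(counts, model) {
  V <- length(model$idf)
  if (length(counts) != V)
    stop("histogram length does not match the tf-idf vocabulary", call. = FALSE)
  w <- ifelse(counts > 0, (1 + log(pmax(counts, 1))) * model$idf, 0)
  out <- w[model$keep]
  names(out) <- (seq_len(V) - 1L)[model$keep]
  out
}

#' Smoothed transition matrix and initial-motion probabilities
#'
#' First-order Markov statistics of a motion-ID sequence with additive
#' smoothing `alpha`:
#' `trans[a, b] = (n(a -> b) + alpha) / (n(a -> .) + alpha * V)` and
#' `init[a] = (count(a) + alpha) / (n + alpha * V)` (a smoothed marginal
#' frequency standing in for the first-motion probability). Both are strictly
#' positive, rows of `trans` and `init` sum to one, and an empty sequence
#' yields the uniform distribution.
#'
#' @param seq A `cav_motion_seq` or integer ID vector.
#' @param vocab_size Dictionary size V.
#' @param alpha Smoothing constant (> 0).
#' @return List with `trans` (V x V row-stochastic matrix) and `init`
#'   (length-V probability vector); index i corresponds to motion ID i - 1.
#' @export
transition_matrix <- function(seq, vocab_size, alpha = 0.5) {
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  ids <- if (inherits(seq, "cav_motion_seq")) seq$ids else as.integer(seq)
  V <- as.integer(vocab_size)
  counts <- matrix(0, V, V)
  if (length(ids) >= 2L) {
    from <- ids[-length(ids)] + 1L
    to <- ids[-1L] + 1L
    for (i in seq_along(from))
      counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  trans <- (counts + alpha) / (rowSums(counts) + alpha * V)
  occ <- motion_histogram(ids, V)
  init <- (occ + alpha) / (length(ids) + alpha * V)
  list(trans = trans, init = init)
}
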