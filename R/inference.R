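# Classification: each observation is compared to every training example by
# two measures — histDiff, the Euclidean distance between tf-idf-weighted
# motion histograms, and seqProb, the probability of the observed motion-ID
# sequence under the example's initial + transition probabilities. They are
# aggregated as cost = histDiff / seqProb; the per-example costs of each
# activity are averaged and the activity with the lowest cost wins.

#' Euclidean distance between weighted motion histograms
#'
#' @param h1,h2 Weighted histogram vectors on the same (non-stop) vocabulary
#'   coordinates.
#' @return Nonnegative scalar.
#' @export
hist_diff <- function(h1, h2) {
  if (length(h1) != length(h2))
    stop("histogram dimension mismatch", call. = FALSE)
  sqrt(sum((h1 - h2)^2))
}

#' Log sequence probability of a motion sequence under a representation
#'
#' First-order Markov chain score:
#' `log Pr = log init[m1] + sum_i log trans[m_(i-1), m_i]`. Smoothing during
#' training keeps every term positive, so the result is finite for any
#' sequence over the vocabulary.
#'
#' @param seq A `cav_motion_seq` or integer vector of motion IDs (0-based).
#' @param rep A training representation (element of `model$representations`).
#' @return Log probability (<= 0).
#' @export
seq_prob <- function(seq, rep) {
  ids <- if (inherits(seq, "cav_motion_seq")) seq$ids else as.integer(seq)
  if (!length(ids)) stop("empty motion sequence has no probability", call. = FALSE)
  lp <- log(rep$init[ids[1L] + 1L])
  if (length(ids) > 1L) {
    from <- ids[-length(ids)] + 1L
    to <- ids[-1L] + 1L
    lp <- lp + sum(log(rep$trans[cbind(from, to)]))
  }
  lp
}

#' Cost of an observation against one training representation
#'
#' `cost = histDiff / seqProb`, computed in the log domain
#' (`exp(log histDiff - log seqProb)`) to survive seqProb underflow; a zero
#' histogram difference gives cost 0 regardless of seqProb, and overflow is
#' reported as `Inf` (with the finite `log_cost` retained).
#'
#' @param obs_hist Observation's weighted histogram.
#' @param obs_seq Observation's motion sequence.
#' @param rep A training representation.
#' @return List `hist_diff`, `log_seq_prob`, `cost`, `log_cost`.
#' @export
observation_cost <- function(obs_hist, obs_seq, rep) {
  hd <- hist_diff(obs_hist, rep$hist)
  lsp <- seq_prob(obs_seq, rep)
  if (hd == 0) {
    log_cost <- -Inf
  } else {
    log_cost <- log(hd) - lsp
  }
  list(hist_diff = hd, log_seq_prob = lsp,
       cost = exp(log_cost), log_cost = log_cost)
}

logsumexp <- function(x) {
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Classify an observation with a trained model
#'
#' The observation is encoded against the model's dictionary, weighted with
#' the training tf-idf model and stop list, and scored against every training
#' representation. Each activity's example costs are averaged (in the log
#' domain, for numerical stability) and the activity with the lowest average
#' cost is predicted; ties break toward the lexicographically smallest label.
#'
#' When the observation matches no dictionary motion, the
#' `"fallback-nearest"` policy re-encodes it with the match threshold
#' disabled; the `"strict"` policy raises an error.
#'
#' @param recording A `cav_recording` observation.
#' @param model A `cav_model`.
#' @return A `cav_classification`: `predicted_label`, `activity_costs`
#'   (named, linear scale, may be `Inf`), `activity_log_costs`,
#'   `per_example_costs`, and the encoded `seq`.
#' @export
classify <- function(recording, model) {
  if (!length(model$representations)) stop("untrained model", call. = FALSE)
  cfg <- model$config
  obs_seq <- encode_observation(recording, model$dictionary,
                                sizes_s = cfg$sizes_s, tau = cfg$tau,
                                step_fraction = cfg$step_fraction)
  if (!length(obs_seq$ids)) {
    if (cfg$empty_policy == "strict")
      stop(sprintf("observation '%s' matched no dictionary motion",
                   recording$recording_id), call. = FALSE)
    message(sprintf("observation '%s' matched no motion at tau = %g; falling back to nearest-centroid encoding",
                    recording$recording_id, cfg$tau))
    obs_seq <- encode_observation(recording, model$dictionary,
                                  sizes_s = cfg$sizes_s, tau = Inf,
                                  step_fraction = cfg$step_fraction)
  }
  if (!length(obs_seq$ids))
    stop(sprintf("observation '%s' is shorter than the smallest window",
                 recording$recording_id), call. = FALSE)
  V <- dictionary_size(model$dictionary)
  obs_hist <- apply_tfidf(motion_histogram(obs_seq, V), model$tfidf)
  labels <- vapply(model$representations, `[[`, "", "label")
  breakdowns <- lapply(model$representations, function(rep)
    observation_cost(obs_hist, obs_seq, rep))
  log_costs <- vapply(breakdowns, `[[`, 0, "log_cost")
  activity_log_costs <- vapply(sort(unique(labels)), function(a) {
    lc <- log_costs[labels == a]
    logsumexp(lc) - log(length(lc))  # log of the arithmetic mean cost
  }, 0)
  predicted <- names(activity_log_costs)[which.min(activity_log_costs)]
  structure(list(
    predicted_label = predicted,
    activity_costs = exp(activity_log_costs),
    activity_log_costs = activity_log_costs,
    per_example_costs = split(vapply(breakdowns, `[[`, 0, "cost"), labels),
    seq = obs_seq), class = "cav_classification")
}

#' @export
print.cav_classification <- function(x, ...) {
  cat(sprintf("<cav_classification> predicted '%s'\n", x$predicted_label))
  print(round(x$activity_log_costs, 3))
  invisible(x)
}

#' Accuracy as a multiple of chance
#'
#' For a K-class problem with balanced classes, chance accuracy is
#' `100 / K` percent; the chance ratio is `accuracy / (100 / K)`.
#'
#' @param accuracy_pct Overall accuracy in percent.
#' @param n_classes Number of classes K.
#' @return `accuracy_pct / (100 / n_classes)`.
#' @export
chance_ratio <- function(accuracy_pct, n_classes) {
  accuracy_pct / (100 / n_classes)
}
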