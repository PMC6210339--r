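#' Training and inference configuration
#'
#' Collects every tunable of the pipeline in one validated object so that any
#' model or report can record exactly how it was produced.
#'
#' @param sizes_s Window sizes in seconds for multi-scale segmentation.
#' @param increments Segmentation start offsets as fractions of the window
#'   size; each (size, increment) pass tiles non-overlapping windows.
#' @param base_len Canonical frame count every window is resampled to before
#'   clustering (default 15, i.e. the 0.5 s window at 30 Hz).
#' @param k_activity Per-activity k-means cluster count; `NULL` (default)
#'   uses the `ceiling(sqrt(W / 2))` heuristic for `W` windows.
#' @param k2_fraction Dictionary-level k as a fraction of the number of
#'   surviving first-level cluster centers.
#' @param min_members Minimum members for a cluster to survive pruning
#'   (default 6: clusters with five windows or fewer are dropped).
#' @param n_init Number of k-means++ restarts.
#' @param tau Match threshold at inference: a window matches a dictionary
#'   motion when its distance to the centroid is at most `tau` times the
#'   motion's learned radius.
#' @param step_fraction Cursor advance, as a fraction of the smallest window,
#'   when no size matches during observation encoding.
#' @param alpha Additive (Laplace) smoothing for transition matrices and
#'   initial-motion probabilities; keeps every sequence probability positive.
#' @param stop_fraction Fraction of the vocabulary placed on the stop list
#'   (most frequent motions; size is `floor(stop_fraction * V)`).
#' @param empty_policy What to do when an observation matches no motion:
#'   `"fallback-nearest"` re-encodes with the threshold disabled,
#'   `"strict"` raises an error.
#' @param seed Integer seed driving all pipeline randomness.
#' @return A `cav_config` list.
#' @export
cav_config <- function(sizes_s = c(0.5, 1, 1.5, 2),
                       increments = c(0, 0.25, 0.5),
                       base_len = 15L,
                       k_activity = NULL,
                       k2_fraction = 0.75,
                       min_members = 6L,
                       n_init = 10L,
                       tau = 1.0,
                       step_fraction = 0.25,
                       alpha = 0.5,
                       stop_fraction = 0.05,
                       empty_policy = c("fallback-nearest", "strict"),
                       seed = 1L) {
  stopifnot(length(sizes_s) >= 1L, all(sizes_s > 0),
            all(increments >= 0), all(increments < 1),
            base_len >= 1L,
            is.null(k_activity) || k_activity >= 1L,
            k2_fraction > 0, k2_fraction <= 1,
            min_members >= 1L, n_init >= 1L,
            tau > 0, step_fraction > 0, alpha > 0,
            stop_fraction >= 0, stop_fraction < 1)
  structure(list(
    sizes_s = sort(as.numeric(sizes_s)),
    increments = as.numeric(increments),
    base_len = as.integer(base_len),
    k_activity = if (is.null(k_activity)) NULL else as.integer(k_activity),
    k2_fraction = as.numeric(k2_fraction),
    min_members = as.integer(min_members),
    n_init = as.integer(n_init),
    tau = as.numeric(tau),
    step_fraction = as.numeric(step_fraction),
    alpha = as.numeric(alpha),
    stop_fraction = as.numeric(stop_fraction),
    empty_policy = match.arg(empty_policy),
    seed = as.integer(seed)), class = "cav_config")
}

#' Load a configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file whose keys are `cav_config()` arguments.
#' @return A `cav_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cav_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  do.call(cav_config, vals)
}
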