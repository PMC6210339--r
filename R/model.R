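# End-to-end training: windows -> per-activity clusters -> pruning ->
# overlap resolution -> motion dictionary -> per-example representations.

#' Train a dictionary-of-motions activity model
#'
#' Runs the full training phase on a labeled dataset: multi-scale window
#' segmentation of every example, per-activity k-means clustering of the
#' window vectors, pruning of sparse clusters, longest-first overlap
#' resolution within each recording, construction of the global motion
#' dictionary (second-level k-means over all surviving cluster centers, with
#' provenance), and finally per-example representations: tf-idf-weighted
#' motion histograms (with stop list) and smoothed transition matrices.
#'
#' @param dataset A `cav_dataset` with at least one recording per activity.
#' @param config A `cav_config`.
#' @param window_cache Optional named list (by recording id) of precomputed
#'   [segment_windows()] results for this config; used by the evaluation
#'   protocols to avoid re-segmenting unchanged recordings at every fold.
#'   Segmentation is a deterministic per-recording operation, so sharing it
#'   across folds leaks nothing between training and test sets.
#' @return A `cav_model` with elements `dictionary`, `tfidf`,
#'   `representations` (one per training example), `activity_set`, `config`.
#' @export
train_model <- function(dataset, config = cav_config(), window_cache = NULL) {
  if (!length(dataset$recordings)) stop("empty training dataset", call. = FALSE)
  labels <- dataset_labels(dataset)
  per_activity <- list()
  retained_meta <- list()  # per recording: windows surviving pruning
  for (a in dataset$activity_set) {
    recs <- dataset$recordings[labels == a]
    if (!length(recs)) next
    wsets <- lapply(recs, function(rec) {
      cached <- window_cache[[rec$recording_id]]
      if (!is.null(cached)) cached
      else segment_windows(rec, sizes_s = config$sizes_s,
                           increments = config$increments,
                           base_len = config$base_len)
    })
    wsets <- Filter(function(w) nrow(w$meta) > 0L, wsets)
    if (!length(wsets)) next
    windows <- bind_windows(wsets)
    W <- nrow(windows$X)
    k <- if (is.null(config$k_activity)) max(1L, as.integer(ceiling(sqrt(W / 2))))
         else config$k_activity
    a_seed <- config$seed + match(a, dataset$activity_set)
    clusters <- cluster_activity_windows(windows, k, seed = a_seed,
                                         n_init = config$n_init)
    pruned <- prune_clusters(clusters, config$min_members)
    if (!length(pruned)) next
    per_activity[[a]] <- pruned
    for (j in seq_along(pruned)) {
      rows <- windows$meta[pruned[[j]]$members, , drop = FALSE]
      rows$activity <- a
      rows$cluster <- j
      retained_meta[[length(retained_meta) + 1L]] <- rows
    }
  }
  if (!length(per_activity))
    stop("no motion clusters survived pruning; dataset too small for the configured windows",
         call. = FALSE)
  retained <- do.call(rbind, retained_meta)
  dictionary <- build_dictionary(per_activity, k2 = NULL,
                                 k2_fraction = config$k2_fraction,
                                 seed = config$seed, n_init = config$n_init,
                                 base_len = config$base_len)
  V <- dictionary_size(dictionary)
  seqs <- lapply(dataset$recordings, function(rec) {
    mine <- retained[retained$recording_id == rec$recording_id, , drop = FALSE]
    resolved <- resolve_overlaps(mine)
    suppressWarnings(
      encode_training_example(resolved, dictionary, rec$recording_id))
  })
  hists <- t(vapply(seqs, motion_histogram, integer(V), vocab_size = V))
  tfidf <- fit_tfidf(hists, config$stop_fraction)
  representations <- lapply(seq_along(seqs), function(i) {
    rec <- dataset$recordings[[i]]
    tm <- transition_matrix(seqs[[i]], V, config$alpha)
    list(recording_id = rec$recording_id,
         label = rec$label,
         counts = hists[i, ],
         hist = apply_tfidf(hists[i, ], tfidf),
         trans = tm$trans,
         init = tm$init,
         seq = seqs[[i]])
  })
  structure(list(dictionary = dictionary,
                 tfidf = tfidf,
                 representations = representations,
                 activity_set = dataset$activity_set,
                 config = config),
            class = "cav_model")
}

#' @export
print.cav_model <- function(x, ...) {
  cat(sprintf("<cav_model> %d motions, %d training examples, %d activities\n",
              dictionary_size(x$dictionary), length(x$representations),
              length(x$activity_set)))
  invisible(x)
}

#' Serialize a trained model to JSON
#'
#' @param model A `cav_model`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  payload <- list(
    dictionary = list(centroids = model$dictionary$centroids,
                      radius = model$dictionary$radius,
                      provenance = model$dictionary$provenance,
                      base_len = model$dictionary$base_len),
    tfidf = list(idf = model$tfidf$idf, doc_freq = model$tfidf$doc_freq,
                 n_docs = model$tfidf$n_docs, stop_ids = model$tfidf$stop_ids,
                 keep = model$tfidf$keep),
    representations = lapply(model$representations, function(r)
      list(recording_id = r$recording_id, label = r$label,
           counts = r$counts, hist = as.numeric(r$hist),
           hist_ids = as.integer(names(r$hist)),
           trans = r$trans, init = r$init,
           seq_ids = r$seq$ids, seq_starts = r$seq$start_frames)),
    activity_set = model$activity_set,
    config = unclass(model$config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model written by [write_model()]
#'
#' @param path Model JSON file.
#' @return A `cav_model`.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- p$config
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  cfg <- lapply(cfg, unlist)
  config <- do.call(cav_config, cfg)
  num_vec <- function(x) as.numeric(unlist(x))
  int_vec <- function(x) as.integer(unlist(x))
  row_matrix <- function(rows) do.call(rbind, lapply(rows, num_vec))
  prov <- p$dictionary$provenance
  dictionary <- structure(list(
    centroids = row_matrix(p$dictionary$centroids),
    radius = num_vec(p$dictionary$radius),
    provenance = data.frame(
      activity = vapply(prov, function(e) as.character(e$activity), ""),
      cluster = vapply(prov, function(e) as.integer(e$cluster), 0L),
      motion_id = vapply(prov, function(e) as.integer(e$motion_id), 0L)),
    base_len = as.integer(p$dictionary$base_len)), class = "cav_dictionary")
  tfidf <- structure(list(idf = num_vec(p$tfidf$idf),
                          doc_freq = int_vec(p$tfidf$doc_freq),
                          n_docs = as.integer(p$tfidf$n_docs),
                          stop_ids = int_vec(p$tfidf$stop_ids),
                          keep = as.logical(unlist(p$tfidf$keep))),
                     class = "cav_tfidf")
  reps <- lapply(p$representations, function(r) {
    h <- num_vec(r$hist)
    names(h) <- as.character(int_vec(r$hist_ids))
    list(recording_id = r$recording_id, label = r$label,
         counts = int_vec(r$counts),
         hist = h,
         trans = row_matrix(r$trans),
         init = num_vec(r$init),
         seq = motion_sequence(r$recording_id, int_vec(r$seq_ids),
                               int_vec(r$seq_starts)))
  })
  structure(list(dictionary = dictionary, tfidf = tfidf,
                 representations = reps,
                 activity_set = as.character(p$activity_set),
                 config = config), class = "cav_model")
}
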