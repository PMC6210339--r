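# Evaluation protocols: leave-one-out cross-validation (full retrain per
# fold), repeated random subject holdout, and a variation-narrowed split that
# trains on the most homogeneous subset of each activity.

#' Build a confusion matrix from true/predicted label pairs
#'
#' @param truth,predicted Character vectors of equal length.
#' @param labels Ordered label set for the rows/columns.
#' @return A `cav_confusion`: `counts`, row-normalized `percentages`
#'   (rows sum to 100; empty rows stay 0), and `overall_accuracy` in percent.
#' @export
confusion_matrix <- function(truth, predicted, labels = sort(unique(truth))) {
  counts <- table(factor(truth, levels = labels),
                  factor(predicted, levels = labels))
  counts <- matrix(as.integer(counts), length(labels), length(labels),
                   dimnames = list(truth = labels, predicted = labels))
  rs <- rowSums(counts)
  pct <- counts * 0
  nz <- rs > 0
  pct[nz, ] <- 100 * counts[nz, , drop = FALSE] / rs[nz]
  structure(list(labels = labels, counts = counts, percentages = pct,
                 overall_accuracy = 100 * sum(diag(counts)) / sum(counts)),
            class = "cav_confusion")
}

#' @export
print.cav_confusion <- function(x, ...) {
  cat(sprintf("<cav_confusion> overall accuracy %.2f%% (%.2f-times chance for %d classes)\n",
              x$overall_accuracy,
              chance_ratio(x$overall_accuracy, length(x$labels)),
              length(x$labels)))
  print(round(x$percentages, 2))
  invisible(x)
}

build_window_cache <- function(dataset, config) {
  suppressWarnings(lapply(dataset$recordings, segment_windows,
                          sizes_s = config$sizes_s,
                          increments = config$increments,
                          base_len = config$base_len))
}

train_and_score <- function(train_ds, test_recs, config, window_cache = NULL) {
  model <- train_model(train_ds, config, window_cache = window_cache)
  vapply(test_recs, function(rec)
    suppressMessages(classify(rec, model))$predicted_label, "")
}

#' Leave-one-out cross-validation
#'
#' Rotates through the dataset, at each fold retraining the full pipeline
#' (dictionary included, so there is no information leakage) on all remaining
#' examples and classifying the held-out one. Activities with fewer than two
#' examples are excluded with a warning.
#'
#' @param dataset A `cav_dataset`.
#' @param config A `cav_config`.
#' @param progress Print fold progress (default FALSE).
#' @return A `cav_confusion` over all folds.
#' @export
evaluate_loocv <- function(dataset, config = cav_config(), progress = FALSE) {
  labels <- dataset_labels(dataset)
  tab <- table(labels)
  singletons <- names(tab)[tab < 2L]
  if (length(singletons)) {
    warning(sprintf("excluding single-example activities: %s",
                    paste(singletons, collapse = ", ")), call. = FALSE)
    keep <- !(labels %in% singletons)
    dataset <- cav_dataset(dataset$recordings[keep],
                           activity_set = setdiff(dataset$activity_set,
                                                  singletons))
    labels <- dataset_labels(dataset)
  }
  n <- length(dataset$recordings)
  if (n < 2L) stop("need at least two recordings for cross-validation",
                   call. = FALSE)
  cache <- build_window_cache(dataset, config)
  predicted <- character(n)
  for (i in seq_len(n)) {
    if (progress) message(sprintf("fold %d/%d", i, n))
    train_ds <- cav_dataset(dataset$recordings[-i],
                            activity_set = dataset$activity_set)
    predicted[i] <- train_and_score(train_ds, dataset$recordings[i], config,
                                    window_cache = cache)
  }
  confusion_matrix(labels, predicted, dataset$activity_set)
}

#' Repeated random subject holdout
#'
#' In each repeat, a fraction of the subjects is drawn for training (without
#' replacement; stratified on an optional subject attribute such as gender,
#' keeping proportions equal between the splits) and the remaining subjects'
#' recordings are classified. Percentage confusion matrices are averaged
#' cell-wise over repeats.
#'
#' @param dataset A `cav_dataset` with at least two subjects.
#' @param config A `cav_config`.
#' @param train_fraction Fraction of subjects used for training.
#' @param repeats Number of random splits.
#' @param seed Integer seed for the splits.
#' @param subject_attrs Optional named character vector (subject -> stratum).
#' @return A `cav_confusion` whose `percentages` and `overall_accuracy` are
#'   means over repeats (`counts` holds the summed counts).
#' @export
evaluate_subject_holdout <- function(dataset, config = cav_config(),
                                     train_fraction = 2 / 3, repeats = 20L,
                                     seed = 1L, subject_attrs = NULL) {
  subjects <- unique(dataset_subjects(dataset))
  if (length(subjects) < 2L) stop("need at least two subjects", call. = FALSE)
  set.seed(seed)
  pick_train <- function() {
    if (is.null(subject_attrs)) {
      sample(subjects, max(1L, round(train_fraction * length(subjects))))
    } else {
      unlist(lapply(split(subjects, subject_attrs[subjects]), function(g)
        sample(g, max(1L, round(train_fraction * length(g))))),
        use.names = FALSE)
    }
  }
  cache <- build_window_cache(dataset, config)
  pct_sum <- NULL
  count_sum <- NULL
  acc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    train_subj <- pick_train()
    is_train <- dataset_subjects(dataset) %in% train_subj
    train_ds <- cav_dataset(dataset$recordings[is_train],
                            activity_set = dataset$activity_set)
    test_recs <- dataset$recordings[!is_train]
    predicted <- train_and_score(train_ds, test_recs, config,
                                 window_cache = cache)
    cm <- confusion_matrix(vapply(test_recs, `[[`, "", "label"), predicted,
                           dataset$activity_set)
    pct_sum <- if (is.null(pct_sum)) cm$percentages else pct_sum + cm$percentages
    count_sum <- if (is.null(count_sum)) cm$counts else count_sum + cm$counts
    acc[r] <- cm$overall_accuracy
  }
  structure(list(labels = dataset$activity_set,
                 counts = count_sum,
                 percentages = pct_sum / repeats,
                 overall_accuracy = mean(acc),
                 per_repeat_accuracy = acc),
            class = "cav_confusion")
}

#' Select each activity's most homogeneous example subset
#'
#' Greedy backward elimination on the Variation metric: repeatedly drop the
#' example with the largest mean distance to the rest until `fraction` of
#' the examples remain. Used to emulate training on the narrowest range of
#' variation.
#'
#' @param recordings List of `cav_recording` of one activity.
#' @param fraction Fraction to keep (at least 2 recordings are kept).
#' @return Character vector of selected recording IDs.
#' @export
narrowest_variation_subset <- function(recordings, fraction = 2 / 3) {
  n <- length(recordings)
  target <- max(2L, as.integer(rnd(fraction * n)))
  if (target >= n) return(vapply(recordings, `[[`, "", "recording_id"))
  lens <- vapply(recordings, function(r) nrow(r$frames), 0L)
  canonical <- min(lens)
  flats <- vapply(recordings,
                  function(r) flatten_frames(resample_frames(r$frames, canonical)),
                  numeric(36L * canonical))
  d <- as.matrix(stats::dist(t(flats)))
  alive <- seq_len(n)
  while (length(alive) > target) {
    mean_d <- rowMeans(d[alive, alive, drop = FALSE])
    alive <- alive[-which.max(mean_d)]
  }
  vapply(recordings[alive], `[[`, "", "recording_id")
}

#' Variation-narrowed split evaluation
#'
#' Trains on the `train_fraction` of each activity's examples with the
#' narrowest range of variation (per [narrowest_variation_subset()], or a
#' custom selector) and classifies the remaining, more varied examples.
#'
#' @param dataset A `cav_dataset`.
#' @param config A `cav_config`.
#' @param train_fraction Fraction of each activity's examples to train on.
#' @param selector Function `(recordings, fraction) -> recording ids` picking
#'   the training subset per activity.
#' @return A `cav_confusion` on the held-out examples.
#' @export
evaluate_narrowed_split <- function(dataset, config = cav_config(),
                                    train_fraction = 2 / 3,
                                    selector = narrowest_variation_subset) {
  labels <- dataset_labels(dataset)
  train_ids <- unlist(lapply(dataset$activity_set, function(a) {
    selector(dataset$recordings[labels == a], train_fraction)
  }), use.names = FALSE)
  is_train <- names(dataset$recordings) %in% train_ids
  train_ds <- cav_dataset(dataset$recordings[is_train],
                          activity_set = dataset$activity_set)
  test_recs <- dataset$recordings[!is_train]
  if (!length(test_recs)) stop("narrowed split left no test examples",
                               call. = FALSE)
  predicted <- train_and_score(train_ds, test_recs, config)
  confusion_matrix(vapply(test_recs, `[[`, "", "label"), predicted,
                   dataset$activity_set)
}
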