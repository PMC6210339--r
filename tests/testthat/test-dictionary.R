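test_that("window tiling matches the closed form and exhaustive enumeration", {
  r <- random_recording(210, frame_rate = 30, seed = 2)
  w <- segment_windows(r, sizes_s = 0.5, increments = 0, base_len = 15)
  expect_equal(nrow(w$meta), 14)  # floor(210 / 15)
  expect_equal(w$meta$start_frame, seq(0, 195, by = 15))

  w25 <- segment_windows(r, sizes_s = 0.5, increments = 0.25, base_len = 15)
  # offset round(0.25 * 15) = 4; floor((210 - 4) / 15) = 13 windows
  expect_equal(nrow(w25$meta), 13)
  expect_equal(w25$meta$start_frame, seq(4, 184, by = 15))

  # exhaustive enumeration oracle over all sizes and increments
  for (size in c(0.5, 1, 1.5, 2)) {
    for (inc in c(0, 0.25, 0.5)) {
      fr <- floor(size * 30 + 0.5)
      off <- floor(inc * fr + 0.5)
      starts <- c()
      s <- off
      while (s + fr <= 210) { starts <- c(starts, s); s <- s + fr }
      got <- segment_windows(r, sizes_s = size, increments = inc,
                             base_len = 15)
      expect_equal(got$meta$start_frame, as.integer(starts))
      expect_equal(nrow(got$meta), floor((210 - off) / fr))
    }
  }
})

test_that("windows within one pass are disjoint, ordered, and short inputs yield none", {
  r <- random_recording(100, frame_rate = 30, seed = 3)
  w <- segment_windows(r)
  for (size in unique(w$meta$length_frames)) {
    for (inc in unique(w$meta$increment)) {
      m <- w$meta[w$meta$length_frames == size & w$meta$increment == inc, ]
      if (nrow(m) < 2) next
      expect_true(all(diff(m$start_frame) >= size))
    }
  }
  short <- random_recording(14, frame_rate = 30, seed = 4)
  expect_warning(ws <- segment_windows(short), "smallest window")
  expect_equal(nrow(ws$meta), 0)
})

test_that("window vectors hold the resampled flattened content", {
  r <- random_recording(60, frame_rate = 30, seed = 6)
  w <- segment_windows(r, sizes_s = 1, increments = 0, base_len = 15)
  expect_equal(ncol(w$X), 36 * 15)
  manual <- flatten_frames(resample_frames(r$frames[1:30, ], 15))
  expect_equal(unname(w$X[1, ]), manual)
})

test_that("k-means recovers planted clusters and handles degenerate k", {
  set.seed(10)
  c1 <- rnorm(20)
  c2 <- rnorm(20) + 50
  X <- rbind(t(replicate(15, c1 + rnorm(20, sd = 0.1))),
             t(replicate(15, c2 + rnorm(20, sd = 0.1))))
  win <- structure(list(meta = data.frame(recording_id = "r",
                                          start_frame = 1:30,
                                          length_frames = 1,
                                          increment = 0),
                        X = X), class = "cav_windows")
  cl <- cluster_activity_windows(win, k = 2, seed = 1)
  cents <- do.call(rbind, lapply(cl, `[[`, "centroid"))
  d_to_c1 <- apply(cents, 1, function(v) sqrt(sum((v - c1)^2)))
  d_to_c2 <- apply(cents, 1, function(v) sqrt(sum((v - c2)^2)))
  expect_lt(min(d_to_c1), 0.5)
  expect_lt(min(d_to_c2), 0.5)

  one <- cluster_activity_windows(win, k = 1, seed = 1)
  expect_length(one, 1)
  expect_equal(one[[1]]$centroid, colMeans(X))

  same <- win
  same$X <- matrix(1, 8, 5)
  s1 <- cluster_activity_windows(same, k = 1, seed = 1)
  expect_equal(s1[[1]]$radius, 0)
  expect_warning(cluster_activity_windows(same, k = 20, seed = 1), "reduced")
})

test_that("clustering is deterministic under a fixed seed", {
  set.seed(33)
  win <- structure(list(meta = data.frame(), X = matrix(rnorm(600), 60, 10)),
                   class = "cav_windows")
  a <- cluster_activity_windows(win, k = 4, seed = 9)
  b <- cluster_activity_windows(win, k = 4, seed = 9)
  expect_equal(a, b)
})

test_that("pruning drops clusters at five members and keeps six", {
  mk <- function(n) list(members = seq_len(n), centroid = 1:3, radius = 0)
  out <- prune_clusters(list(mk(5), mk(6), mk(1)), min_members = 6)
  expect_length(out, 1)
  expect_length(out[[1]]$members, 6)
  expect_equal(prune_clusters(list(), 6), list())
  expect_warning(prune_clusters(list(mk(2)), 6), "dropped")
})

test_that("overlap resolution keeps larger windows and breaks ties once", {
  meta <- data.frame(start_frame = c(0L, 30L), length_frames = c(60L, 15L),
                     increment = c(0, 0))
  out <- resolve_overlaps(meta)
  expect_equal(nrow(out), 1)
  expect_equal(out$length_frames, 60)

  disjoint <- data.frame(start_frame = c(0L, 15L), length_frames = c(15L, 15L),
                         increment = c(0, 0))
  expect_equal(nrow(resolve_overlaps(disjoint)), 2)

  dup <- data.frame(start_frame = c(10L, 10L), length_frames = c(15L, 15L),
                    increment = c(0.5, 0.25))
  out2 <- resolve_overlaps(dup)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$increment, 0.25)  # lower increment wins the tie

  # output sorted by start regardless of processing order
  mix <- data.frame(start_frame = c(50L, 0L, 20L),
                    length_frames = c(10L, 10L, 10L),
                    increment = c(0, 0, 0))
  expect_equal(resolve_overlaps(mix)$start_frame, c(0L, 20L, 50L))
})

test_that("dictionary build merges duplicate motions with provenance to both", {
  cl <- function(centroid, radius = 0.5)
    list(members = 1:6, centroid = centroid, radius = radius)
  shared <- c(1, 2, 3)
  per_act <- list(a = list(cl(shared)), b = list(cl(shared)))
  d <- build_dictionary(per_act, k2 = 1, seed = 1, base_len = 5)
  expect_equal(nrow(d$centroids), 1)
  expect_setequal(d$provenance$activity, c("a", "b"))
  expect_equal(unique(d$provenance$motion_id), 0L)
  # radius covers centroid distance + member radius of each contributor
  expect_equal(d$radius, 0.5)

  far <- list(a = list(cl(c(0, 0, 0)), cl(c(100, 0, 0))),
              b = list(cl(c(0, 100, 0))))
  d2 <- build_dictionary(far, k2 = 3, seed = 1, base_len = 5)
  expect_equal(nrow(d2$centroids), 3)
  expect_equal(sort(d2$provenance$motion_id), 0:2)
  got <- d2$centroids[order(d2$centroids[, 1], d2$centroids[, 2]), ]
  expect_equal(got, rbind(c(0, 0, 0), c(0, 100, 0), c(100, 0, 0)),
               ignore_attr = TRUE)
  expect_warning(build_dictionary(far, k2 = 10, seed = 1, base_len = 5),
                 "reduced")
})

test_that("training pipeline is deterministic and provenance is total", {
  gen <- small_dataset(seed = 13)
  cfg <- small_config()
  m1 <- train_model(gen$dataset, cfg)
  m2 <- train_model(gen$dataset, cfg)
  expect_equal(m1$dictionary, m2$dictionary)
  expect_equal(m1$representations, m2$representations)

  # every retained window maps to exactly one motion id
  V <- nrow(m1$dictionary$centroids)
  expect_equal(sort(unique(m1$dictionary$provenance$motion_id)),
               0:(V - 1))
  for (rep in m1$representations) {
    if (length(rep$seq$ids)) {
      expect_true(all(rep$seq$ids >= 0 & rep$seq$ids < V))
      expect_true(all(diff(rep$seq$start_frames) > 0))
    }
  }
})
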