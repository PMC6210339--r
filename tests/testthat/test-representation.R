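test_that("training encoding maps retained windows through provenance", {
  dict <- structure(list(
    centroids = rbind(rep(0, 6), rep(1, 6)),
    radius = c(1, 1),
    provenance = data.frame(activity = c("a", "a"), cluster = 1:2,
                            motion_id = c(3L, 5L) - 3L),
    base_len = 1L), class = "cav_dictionary")
  resolved <- data.frame(start_frame = c(20L, 0L, 40L),
                         activity = "a", cluster = c(2L, 1L, 1L))
  seq <- encode_training_example(resolved, dict, "r1")
  expect_equal(seq$ids, c(0L, 2L, 0L))        # ordered by start frame
  expect_equal(seq$start_frames, c(0L, 20L, 40L))

  expect_warning(
    empty <- encode_training_example(resolved[0, ], dict, "r9"),
    "no retained windows")
  expect_length(empty$ids, 0)
})

test_that("histograms count ids and conserve totals", {
  expect_equal(motion_histogram(integer(0), 4), rep(0L, 4))
  h <- motion_histogram(c(3L, 3L, 1L), 6)
  expect_equal(h[4], 2L)
  expect_equal(h[2], 1L)
  expect_equal(sum(h), 3L)
  set.seed(1)
  for (i in 1:5) {
    ids <- sample(0:9, sample(0:30, 1), replace = TRUE)
    expect_equal(sum(motion_histogram(ids, 10)), length(ids))
  }
  expect_error(motion_histogram(c(0L, 7L), 5), "outside")
})

test_that("tf-idf fits document frequencies, idf, and the stop list", {
  # motion 0 in every doc -> idf 0; motion 1 in one of three -> ln 3
  H <- rbind(c(4, 1, 0, 0), c(2, 0, 1, 0), c(9, 0, 0, 0))
  m <- fit_tfidf(H, stop_fraction = 0.05)
  expect_equal(m$idf[1], 0)
  expect_equal(m$idf[2], log(3))
  expect_equal(m$idf[4], 0)      # never seen: treated as ubiquitous
  expect_equal(m$stop_ids, integer(0))  # floor(0.05 * 4) = 0

  # stop-list sizing: floor(0.05 * V)
  expect_length(fit_tfidf(matrix(1, 2, 40))$stop_ids, 2)
  expect_length(fit_tfidf(matrix(1, 2, 10))$stop_ids, 0)

  # stop list ranks by document frequency (ubiquity), not raw count: a
  # motion concentrated in one document loses to one present everywhere
  H2 <- matrix(0, 3, 40)
  H2[1, 7] <- 100                 # huge count, df 1
  H2[, 5] <- 2; H2[, 9] <- 1     # df 3 each
  m2 <- fit_tfidf(H2)
  expect_equal(m2$stop_ids, c(4L, 8L))
  # document-frequency ties break on total corpus count, then lower id
  H3 <- matrix(1, 2, 40)
  H3[, 12] <- 5
  m3 <- fit_tfidf(H3)
  expect_setequal(m3$stop_ids, c(11L, 0L))  # highest count, then lowest id
})

test_that("tf-idf weighting matches a hand computation and is monotone", {
  H <- rbind(c(2, 1, 0, 0),
             c(1, 0, 3, 0),
             c(4, 0, 0, 1))
  m <- fit_tfidf(H, stop_fraction = 0)
  w2 <- apply_tfidf(H[2, ], m)
  # hand: df = (3,1,1,1), N = 3
  expect_equal(unname(w2[1]), (1 + log(1)) * log(3 / 3))
  expect_equal(unname(w2[2]), 0)                       # count 0
  expect_equal(unname(w2[3]), (1 + log(3)) * log(3 / 1))
  w1 <- apply_tfidf(H[1, ], m)
  expect_equal(unname(w1[2]), (1 + log(1)) * log(3))   # tf term is 1 at count 1

  # monotone in count under a fixed model
  for (t in 1:4) {
    counts_lo <- c(1, 1, 1, 1)
    counts_hi <- counts_lo; counts_hi[t] <- 7
    expect_gte(apply_tfidf(counts_hi, m)[t], apply_tfidf(counts_lo, m)[t])
  }
})

test_that("stop-list application is a projection", {
  H <- matrix(rpois(80, 3), 4, 20)
  m <- fit_tfidf(H, stop_fraction = 0.1)
  expect_length(m$stop_ids, 2)
  w <- apply_tfidf(H[1, ], m)
  expect_length(w, 18)
  expect_false(any(as.character(m$stop_ids) %in% names(w)))
  # re-projecting the kept coordinates changes nothing
  expect_equal(w[names(w)], w)
})

test_that("transition matrices are smoothed, stochastic and match hand counts", {
  # deterministic alternation: probabilities approach 1 as alpha -> 0
  tm <- transition_matrix(c(1L, 2L, 1L, 2L), 3, alpha = 1e-9)
  expect_gt(tm$trans[2, 3], 0.999)
  expect_gt(tm$trans[3, 2], 0.999)

  # empty sequence: pure prior, uniform rows
  tm0 <- transition_matrix(integer(0), 4, alpha = 0.5)
  expect_equal(tm0$trans, matrix(0.25, 4, 4))
  expect_equal(tm0$init, rep(0.25, 4))

  # hand count (0-based ids a,a,b over V=2, alpha=1):
  # trans[a][a] = (1 transition + 1) / (2 sources + 2) = 0.5
  tm1 <- transition_matrix(c(0L, 0L, 1L), 2, alpha = 1)
  expect_equal(tm1$trans[1, 1], 0.5)
  expect_equal(tm1$trans[1, 2], 0.5)

  # property: rows sum to 1 and all entries positive for any seq, alpha > 0
  set.seed(8)
  for (i in 1:10) {
    V <- sample(2:6, 1)
    ids <- sample(0:(V - 1), sample(0:12, 1), replace = TRUE)
    alpha <- runif(1, 0.01, 2)
    tm <- transition_matrix(ids, V, alpha)
    expect_equal(rowSums(tm$trans), rep(1, V), tolerance = 1e-9)
    expect_equal(sum(tm$init), 1, tolerance = 1e-9)
    expect_true(all(tm$trans > 0))
    expect_true(all(tm$init > 0))
  }
  expect_error(transition_matrix(1L, 2, alpha = 0), "positive")
})

test_that("observation encoding matches concatenated dictionary content", {
  gen <- small_dataset(seed = 17)
  cfg <- small_config()
  model <- train_model(gen$dataset, cfg)
  dict <- model$dictionary
  # build an observation out of two dictionary centroids' own pose content
  fr <- 10
  unflatten <- function(v) matrix(v, ncol = 36, byrow = TRUE)
  # centroid vectors are base_len-frame pose sequences; stretch each to 2 s
  # so the greedy longest-first scan consumes exactly one window per motion
  ids_used <- c(1L, 2L)
  blocks <- lapply(ids_used, function(i)
    resample_frames(canonicalize_poses(unflatten(dict$centroids[i, ])),
                    2 * fr))
  obs <- cav_recording(do.call(rbind, blocks), fr, "x", "sx", "obs1")
  seq <- encode_observation(obs, dict, sizes_s = cfg$sizes_s, tau = Inf,
                            step_fraction = cfg$step_fraction)
  expect_equal(seq$ids[1], ids_used[1] - 1L)
  expect_equal(seq$ids[2], ids_used[2] - 1L)

  # far-from-dictionary content matches nothing at tau = 1
  far <- cav_recording(matrix(rep(c(0, 0, 1, 1), 9 * 30), 30, byrow = TRUE),
                       fr, "x", "sx", "obs2")
  seq_far <- encode_observation(far, dict, sizes_s = cfg$sizes_s, tau = 1e-6,
                                step_fraction = cfg$step_fraction)
  expect_length(seq_far$ids, 0)

  # tau = Inf always matches something at every cursor position
  seq_all <- encode_observation(far, dict, sizes_s = cfg$sizes_s, tau = Inf,
                                step_fraction = cfg$step_fraction)
  expect_gt(length(seq_all$ids), 0)
})

test_that("training and observation encodings agree on a noiseless example", {
  gen <- small_dataset(variation_level = 0, seed = 23)
  cfg <- small_config(tau = 100)
  model <- train_model(gen$dataset, cfg)
  rec <- gen$dataset$recordings[[1]]
  train_rep <- model$representations[[1]]
  obs_seq <- encode_observation(rec, model$dictionary, sizes_s = cfg$sizes_s,
                                tau = cfg$tau,
                                step_fraction = cfg$step_fraction)
  # same dominant motions in both encodings of the same recording
  expect_gt(length(intersect(obs_seq$ids, train_rep$seq$ids)), 0)
  cls <- suppressMessages(classify(rec, model))
  expect_equal(cls$predicted_label, rec$label)
})
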