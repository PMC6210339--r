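# Deterministic k-means with k-means++ seeding.
#
# Seeding is done explicitly (first center uniform, subsequent centers with
# probability proportional to squared distance to the nearest chosen center);
# each of n_init seedings is refined by Lloyd iterations via stats::kmeans
# with explicit starting centers, and the solution with the lowest total
# within-cluster sum of squares wins. All randomness goes through R's RNG, so
# results are reproducible under set.seed()/a seed argument.

kmeanspp_centers <- function(x, k, xsq = rowSums(x * x)) {
  n <- nrow(x)
  d2_to <- function(i)  # squared distances of all rows to row i
    pmax(xsq - 2 * drop(x %*% x[i, ]) + xsq[i], 0)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- d2_to(centers[1L])
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        # remaining points coincide with chosen centers; pick any unused
        pool <- setdiff(seq_len(n), centers[seq_len(j - 1L)])
        centers[j] <- pool[1L]
      } else {
        centers[j] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, d2_to(centers[j]))
    }
  }
  x[centers, , drop = FALSE]
}

#' @noRd
cav_kmeans <- function(x, k, n_init = 10L, iter_max = 50L) {
  x <- as.matrix(x)
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) k <- n_distinct
  if (k == 1L) {
    centroid <- matrix(colMeans(x), 1L)
    return(list(cluster = rep(1L, nrow(x)), centers = centroid, k = 1L))
  }
  best <- NULL
  xsq <- rowSums(x * x)
  for (i in seq_len(n_init)) {
    init <- kmeanspp_centers(x, k, xsq)
    fit <- tryCatch(
      suppressWarnings(
        stats::kmeans(x, centers = init, iter.max = iter_max,
                      algorithm = "Lloyd")),
      error = function(e) tryCatch(  # Lloyd errors on an emptied cluster
        suppressWarnings(
          stats::kmeans(x, centers = init, iter.max = iter_max,
                        algorithm = "MacQueen")),
        error = function(e) NULL))
    if (!is.null(fit) &&
        (is.null(best) || fit$tot.withinss < best$tot.withinss)) best <- fit
  }
  if (is.null(best))
    best <- suppressWarnings(stats::kmeans(x, centers = k, nstart = n_init,
                                           iter.max = iter_max))
  list(cluster = as.integer(best$cluster), centers = best$centers, k = k)
}
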