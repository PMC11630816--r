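# clustering: standardization, eps heuristic, DBSCAN, silhouette, k-means.

test_that("standardization yields zero mean / unit variance and is idempotent", {
  set.seed(3)
  x <- cbind(peak_frequency = rnorm(200, 40000, 5000),
             duration = rnorm(200, 0.5, 0.2))
  z <- standardize_features(x)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
  z2 <- standardize_features(z)
  expect_equal(unclass(z2)[, ], unclass(z)[, ], tolerance = 1e-9)
  two <- standardize_features(cbind(c(1, 2), c(5, 9)))
  expect_equal(abs(two[, 1]), rep(sqrt(0.5), 2))  # +/- sigma-units
  x[, 2] <- 1
  expect_error(standardize_features(x), "duration",
               class = "usv44_validation_error")
})

test_that("eps knee sits at the intra-blob scale, far below separation", {
  blobs <- planted_blobs(n_each = 200, sep = 12, sd = 1, seed = 4)
  est <- estimate_eps(blobs$x, k = 20)
  expect_gt(est$eps, 0)
  expect_lt(est$eps, 4)          # well below the ~17-unit blob separation
  expect_gt(est$eps, 0.2)        # at least the typical 20-NN distance scale
  expect_equal(est$range, c(0.7, 1.3) * est$eps)
  expect_error(estimate_eps(blobs$x[1:10, ], k = 20),
               class = "usv44_validation_error")
  dup <- matrix(1, nrow = 30, ncol = 2)
  expect_error(estimate_eps(dup, k = 5), "degenerate",
               class = "usv44_validation_error")
})

test_that("kth-NN distances match a brute-force oracle on a tiny fixture", {
  set.seed(8)
  x <- matrix(rnorm(60), ncol = 2)
  d <- as.matrix(dist(x))
  oracle <- apply(d, 1, function(r) sort(r)[6])  # 5th neighbor (excl. self)
  expect_equal(usv44:::knn_distance(x, 5), unname(oracle), tolerance = 1e-9)
})

test_that("DBSCAN recovers planted blobs exactly and flags isolation", {
  blobs <- planted_blobs(n_each = 500, sep = 10, sd = 1, seed = 6)
  sel <- select_eps(blobs$x, min_pts = 150)
  expect_gt(sel$eps, 0)
  expect_lt(sel$eps, 5)  # far below the inter-blob separation
  res <- dbscan_cluster(blobs$x, sel$eps, min_pts = 150)
  expect_equal(nrow(res$cluster_stats), 2)
  tab <- table(res$labels, blobs$truth)
  expect_equal(sum(res$labels == -1), 0)
  expect_equal(sum(apply(tab, 2, max)), 1000) # zero mislabels up to permutation
  # an isolated point is noise
  x2 <- rbind(blobs$x, c(100, 100))
  res2 <- dbscan_cluster(x2, sel$eps, min_pts = 150)
  expect_equal(res2$labels[1001], -1L)
  # all points identical: one cluster, no outliers
  same <- matrix(2, nrow = 40, ncol = 2)
  res3 <- dbscan_cluster(same, eps = 0.5, min_pts = 5)
  expect_equal(unique(res3$labels), 1L)
})

test_that("DBSCAN partition is input-order invariant up to relabeling", {
  blobs <- planted_blobs(n_each = 150, sep = 8, sd = 1, seed = 10)
  set.seed(1)
  perm <- sample(nrow(blobs$x))
  r1 <- dbscan_cluster(blobs$x, 1.0, min_pts = 20)
  r2 <- dbscan_cluster(blobs$x[perm, ], 1.0, min_pts = 20)
  back <- integer(length(perm)); back[perm] <- r2$labels
  tab <- table(r1$labels, back)
  expect_equal(sum(apply(tab, 1, max)), nrow(blobs$x))
})

test_that("silhouette matches cluster::silhouette and is high on blobs", {
  blobs <- planted_blobs(n_each = 80, sep = 10, sd = 1, seed = 12)
  lab <- blobs$truth
  ours <- silhouette_mean(blobs$x, lab)
  ref <- mean(cluster::silhouette(lab, dist(blobs$x))[, 3])
  expect_equal(ours, ref, tolerance = 1e-9)
  expect_gt(ours, 0.8)
  res <- dbscan_cluster(blobs$x, 1.5, min_pts = 15)
  expect_gt(res$silhouette, 0.8)
})

test_that("contour k-means separates flat-22 from flat-44 at k = 2", {
  set.seed(15)
  cts <- c(lapply(1:40, function(i) flat_contour(25000 + rnorm(1, 0, 400),
                                                 runif(1, 0.5, 1.2))),
           lapply(1:40, function(i) flat_contour(42000 + rnorm(1, 0, 400),
                                                 runif(1, 0.3, 0.8))))
  names(cts) <- sprintf("c%02d", 1:80)
  dur <- vapply(cts, function(ct) max(ct$times), numeric(1))
  pk <- vapply(cts, function(ct) mean(ct$frequencies), numeric(1))
  res <- contour_kmeans(cts, dur, pk, max_k = 4, seed = 99)
  expect_equal(res$k, 2)
  truth <- rep(1:2, each = 40)
  tab <- table(res$labels, truth)
  expect_equal(sum(apply(tab, 2, max)), 80)  # 100% purity
  # determinism under the same seed
  res2 <- contour_kmeans(cts, dur, pk, max_k = 4, seed = 99)
  expect_identical(res2$labels, res$labels)
  # label stability under more restarts
  res3 <- contour_kmeans(cts, dur, pk, max_k = 4, n_init = 25, seed = 99)
  tab3 <- table(res3$labels, res$labels)
  expect_equal(sum(apply(tab3, 2, max)), 80)
})

test_that("degenerate contours give k = 1; embedding is optional", {
  cts <- lapply(1:12, function(i) flat_contour(40000, 0.5))
  names(cts) <- sprintf("d%02d", 1:12)
  res <- contour_kmeans(cts, rep(0.5, 12), rep(40000, 12), max_k = 4,
                        seed = 1, embed = TRUE)
  expect_equal(res$k, 1)
  expect_equal(dim(res$embedding), c(12, 2))
  expect_error(contour_kmeans(cts[1:2], rep(0.5, 2), rep(40000, 2), max_k = 4),
               class = "usv44_validation_error")
})
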