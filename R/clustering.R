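# Repertoire clustering.
#
# Two independent routes mirror the two published analyses:
#   1. density-based clustering (DBSCAN) on standardized
#      (peak frequency, duration) features, with the k-distance-knee
#      heuristic for choosing epsilon and a silhouette quality check;
#   2. k-means on fixed-length resampled call contours plus duration and
#      peak frequency (equal block weights), k chosen by elbow optimization.
#
# DBSCAN is implemented here directly (classic core-point/density-reachable
# definition, region queries evaluated on demand) so the clustering route
# does not depend on packages outside the base distribution.

#' Standardize clustering features
#'
#' @param records a `call_table` (uses `peak_frequency` and `duration`), or a
#'   numeric matrix/data.frame of features.
#' @return numeric matrix with each column centered to mean 0 and scaled to
#'   unit variance; attributes `center` and `scale` retain the transform.
#' @export
standardize_features <- function(records) {
  x <- if (is.data.frame(records) && all(c("peak_frequency", "duration") %in% names(records)))
    cbind(peak_frequency = records$peak_frequency, duration = records$duration)
  else as.matrix(records)
  if (nrow(x) < 2) {
    stop_usv("need >= 2 records to standardize", class = "usv44_validation_error")
  }
  s <- apply(x, 2, stats::sd)
  zero <- which(s == 0)
  if (length(zero)) {
    stop_usv("zero-variance feature '%s'", colnames(x)[zero[1]] %||% zero[1],
             class = "usv44_validation_error")
  }
  z <- scale(x)
  out <- z[, , drop = FALSE]
  attributes(out)$center <- attr(z, "scaled:center")
  attributes(out)$scale <- attr(z, "scaled:scale")
  dimnames(out) <- dimnames(x)
  out
}

# k-th nearest-neighbor distance of every point, chunked to bound memory.
knn_distance <- function(x, k, chunk = 512L) {
  n <- nrow(x)
  out <- numeric(n)
  xt <- t(x)
  sq <- colSums(xt^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    block <- x[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), sq, "+") - 2 * block %*% xt
    d2[d2 < 0] <- 0
    out[s:e] <- apply(d2, 1, function(r) sqrt(sort(r, partial = k + 1)[k + 1]))
  }
  out
}

#' Epsilon estimate from the sorted k-distance curve
#'
#' Implements the classic heuristic: sort every point's distance to its k-th
#' nearest neighbor and take the knee (the point of maximum deviation from
#' the chord joining the curve's endpoints, a discrete maximum-curvature
#' proxy). Returned with a +/-30% bracket to scan.
#'
#' @param features standardized feature matrix.
#' @param k neighbor rank (conventionally `min_pts`).
#' @return list with `eps` (the knee), `range` (`c(0.7, 1.3) * eps`), and
#'   `k_distances` (sorted curve).
#' @export
estimate_eps <- function(features, k = 150) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n <= k) {
    stop_usv("need more than k = %d points (got %d)", k, n,
             class = "usv44_validation_error")
  }
  kd <- sort(knn_distance(features, k))
  if (max(kd) <= 0) {
    stop_usv("degenerate distances (all points identical)",
             class = "usv44_validation_error")
  }
  # distance of each curve point from the chord (x scaled to [0,1])
  xs <- seq(0, 1, length.out = n)
  ys <- (kd - kd[1]) / (kd[n] - kd[1])
  dev <- abs(ys - xs) / sqrt(2)
  knee <- kd[which.max(dev)]
  if (knee <= 0) knee <- kd[which(kd > 0)[1]]
  list(eps = knee, range = c(0.7, 1.3) * knee, k_distances = kd)
}

#' Select epsilon by scanning the knee range
#'
#' The published procedure does not stop at the k-distance knee: candidate
#' epsilon values are scanned over a range around it and epsilon is
#' *maximized* among candidates that produce the most frequently observed
#' (most relevant) number of clusters. A larger epsilon within the stable
#' range absorbs boundary points that a knee-exact epsilon would leave as
#' noise. The scan runs from below the knee up to the top of the k-distance
#' curve (beyond which every point is core-reachable), and keeps the largest
#' epsilon that preserves the modal cluster count.
#'
#' @param features standardized feature matrix.
#' @param min_pts DBSCAN core-point threshold (also the neighbor rank for
#'   the knee).
#' @param n_candidates candidate epsilons scanned across the range.
#' @return list with `eps` (selected), `knee`, `candidates`, `n_clusters`
#'   per candidate.
#' @export
select_eps <- function(features, min_pts = 150, n_candidates = 9) {
  est <- estimate_eps(features, k = min_pts)
  cand <- seq(0.7 * est$eps, max(est$k_distances), length.out = n_candidates)
  ncl <- vapply(cand, function(e)
    nrow(dbscan_cluster(features, e, min_pts)$cluster_stats), integer(1))
  ncl_pos <- ncl[ncl > 0]
  if (!length(ncl_pos)) {
    return(list(eps = est$eps, knee = est$eps, candidates = cand,
                n_clusters = ncl))
  }
  modal <- as.integer(names(which.max(table(ncl_pos))))
  eps <- max(cand[ncl == modal])
  list(eps = eps, knee = est$eps, candidates = cand, n_clusters = ncl)
}

# All neighbors of point i within eps (including i), on-demand query.
region_query <- function(x, xt, sq, i, eps2) {
  d2 <- sq + sum(x[i, ]^2) - 2 * drop(x[i, , drop = FALSE] %*% xt)
  which(d2 <= eps2 + 1e-12)
}

#' DBSCAN density clustering
#'
#' Classic density-reachability clustering: a *core point* has at least
#' `min_pts` neighbors (itself included) within `eps`; clusters are the
#' connected components of core points under the eps-neighborhood relation,
#' plus the border points reachable from them; everything else is noise
#' (label -1). Cluster labels are assigned in order of first discovery, so
#' the partition is input-order invariant up to label permutation.
#'
#' @param features standardized feature matrix (rows = calls).
#' @param eps neighborhood radius in standardized-distance units.
#' @param min_pts minimum neighborhood size of a core point (default 150,
#'   large enough to suppress incidental micro-clusters at corpus scale).
#' @param raw_features optional unstandardized feature matrix used for the
#'   per-cluster summary statistics (defaults to `features`).
#' @return a list of class `cluster_result`: `labels` (-1 = noise), `eps`,
#'   `min_pts`, `silhouette` (mean silhouette width over clustered points,
#'   `NA` if fewer than 2 clusters), and `cluster_stats` (size, mean peak
#'   frequency / first feature, mean duration / second feature).
#' @export
dbscan_cluster <- function(features, eps, min_pts = 150, raw_features = NULL) {
  x <- as.matrix(features)
  if (eps <= 0) stop_usv("eps must be > 0", class = "usv44_validation_error")
  if (min_pts < 2) stop_usv("min_pts must be >= 2", class = "usv44_validation_error")
  n <- nrow(x)
  xt <- t(x)
  sq <- colSums(xt^2)
  eps2 <- eps^2
  labels <- rep.int(0L, n)   # 0 = unvisited, -1 = noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    nb <- region_query(x, xt, sq, i, eps2)
    if (length(nb) < min_pts) {
      labels[i] <- -1L
      next
    }
    cl <- cl + 1L
    labels[i] <- cl
    seeds <- setdiff(nb, i)
    p <- 1L
    while (p <= length(seeds)) {
      j <- seeds[p]
      p <- p + 1L
      if (labels[j] == -1L) labels[j] <- cl       # border point
      if (labels[j] != 0L) next
      labels[j] <- cl
      nb_j <- region_query(x, xt, sq, j, eps2)
      if (length(nb_j) >= min_pts) {
        seeds <- c(seeds, nb_j[labels[nb_j] <= 0L])
      }
    }
  }
  raw <- if (is.null(raw_features)) x else as.matrix(raw_features)
  ids <- sort(unique(labels[labels > 0]))
  stats_df <- data.frame(
    cluster = ids,
    size = vapply(ids, function(k) sum(labels == k), integer(1)),
    mean_peak_frequency = vapply(ids, function(k) mean(raw[labels == k, 1]), numeric(1)),
    mean_duration = vapply(ids, function(k) mean(raw[labels == k, 2]), numeric(1))
  )
  sil <- if (length(ids) >= 2) silhouette_mean(x, labels) else NA_real_
  structure(list(labels = labels, eps = eps, min_pts = min_pts,
                 silhouette = sil, cluster_stats = stats_df,
                 n_noise = sum(labels == -1L)),
            class = "cluster_result")
}

#' Mean silhouette width
#'
#' Chunked O(n^2) computation equivalent to the standard definition
#' (`cluster::silhouette`), restricted to clustered points: noise labels
#' (-1, 0) are excluded, since outliers have no cluster cohesion to score.
#'
#' @param x feature matrix.
#' @param labels integer labels (-1/0 treated as noise).
#' @return mean silhouette width over clustered points, in [-1, 1].
#' @export
silhouette_mean <- function(x, labels) {
  keep <- which(labels > 0)
  x <- as.matrix(x)[keep, , drop = FALSE]
  lab <- labels[keep]
  ids <- sort(unique(lab))
  if (length(ids) < 2) return(NA_real_)
  n <- nrow(x)
  sizes <- vapply(ids, function(k) sum(lab == k), integer(1))
  xt <- t(x)
  sq <- colSums(xt^2)
  sil <- numeric(n)
  chunk <- 512L
  member <- outer(lab, ids, "==")       # n x k indicator
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    block <- x[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), sq, "+") - 2 * block %*% xt
    d <- sqrt(pmax(d2, 0))
    sums <- d %*% member                # row sums of distances per cluster
    for (r in seq_len(nrow(block))) {
      i <- s + r - 1L
      ki <- match(lab[i], ids)
      if (sizes[ki] == 1) { sil[i] <- 0; next }
      a <- sums[r, ki] / (sizes[ki] - 1)
      b <- min(sums[r, -ki] / sizes[-ki])
      sil[i] <- (b - a) / max(a, b)
    }
  }
  mean(sil)
}

#' Resample a contour to a fixed-length frequency vector
#'
#' Linear interpolation of the frequency track at `n_points` equally spaced
#' times across the contour's span.
#'
#' @param contour a [call_contour()].
#' @param n_points output length (default 32).
#' @return numeric vector of length `n_points`.
#' @export
resample_contour <- function(contour, n_points = 32) {
  if (length(contour$times) < 2) {
    stop_usv("contour needs >= 2 points", class = "usv44_validation_error")
  }
  tt <- seq(contour$times[1], contour$times[length(contour$times)],
            length.out = n_points)
  stats::approx(contour$times, contour$frequencies, xout = tt)$y
}

#' Contour-based k-means clustering with elbow optimization
#'
#' Features per call: the 32-point resampled frequency contour (one block),
#' duration (one block) and peak frequency (one block). Each column is
#' z-scored and blocks are weighted so each block contributes equal total
#' variance ("equal weights"). k is chosen as the largest second forward
#' difference of the inertia-vs-k curve over k = 1..max_k (the elbow); a
#' degenerate curve (near-zero total inertia) yields k = 1.
#'
#' @param contours named list of [call_contour()] objects.
#' @param durations,peak_frequencies per-call numeric vectors aligned with
#'   `contours`.
#' @param max_k maximum number of clusters scanned (default 4).
#' @param n_init random restarts per k (default 10).
#' @param seed RNG seed for reproducibility.
#' @param n_points contour resampling length.
#' @param embed if `TRUE`, attach 2-D principal-component coordinates of the
#'   feature matrix as a display-only embedding (cluster membership never
#'   depends on it).
#' @return list of class `kmeans_result`: `k`, `labels`, `inertia`
#'   (per candidate k), `centers`, optional `embedding`.
#' @export
contour_kmeans <- function(contours, durations, peak_frequencies, max_k = 4,
                           n_init = 10, seed = 7, n_points = 32,
                           embed = FALSE) {
  n <- length(contours)
  if (n < max_k) {
    stop_usv("need at least max_k = %d calls with contours (got %d)", max_k, n,
             class = "usv44_validation_error")
  }
  bad <- which(vapply(contours, function(ct) length(ct$times) < 2, logical(1)))
  if (length(bad)) {
    stop_usv("contour '%s' has < 2 points", names(contours)[bad[1]] %||% bad[1],
             class = "usv44_validation_error")
  }
  cmat <- t(vapply(contours, resample_contour, numeric(n_points),
                   n_points = n_points))
  zcol <- function(m) {
    s <- apply(m, 2, stats::sd)
    s[s == 0] <- 1
    sweep(sweep(m, 2, colMeans(m)), 2, s, "/")
  }
  blocks <- list(contour = zcol(cmat),
                 duration = zcol(cbind(durations)),
                 peak_frequency = zcol(cbind(peak_frequencies)))
  feats <- do.call(cbind, lapply(blocks, function(b) b / sqrt(ncol(b))))
  set.seed(seed)
  k_max_eff <- min(max_k, nrow(unique(feats)))
  inertia <- numeric(k_max_eff)
  fits <- vector("list", k_max_eff)
  for (k in seq_len(k_max_eff)) {
    fits[[k]] <- suppressWarnings(
      stats::kmeans(feats, centers = k, nstart = n_init, iter.max = 50))
    inertia[k] <- fits[[k]]$tot.withinss
  }
  k_best <- if (inertia[1] < 1e-8 * n) 1L else if (k_max_eff < 3) k_max_eff else {
    d2 <- diff(diff(inertia))  # second forward difference at k = 2..max_k-1
    which.max(d2) + 1L
  }
  fit <- fits[[k_best]]
  out <- list(k = k_best, labels = fit$cluster, inertia = inertia,
              centers = fit$centers)
  if (embed) {
    pc <- stats::prcomp(feats, rank. = 2)
    out$embedding <- pc$x[, 1:2, drop = FALSE]
  }
  structure(out, class = "kmeans_result")
}
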