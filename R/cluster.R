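#' Euclidean pairwise distances
#'
#' @param points Numeric matrix (rows = points) or data frame of coordinates.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(points) {
  as.matrix(stats::dist(as.matrix(points), method = "euclidean"))
}

#' Cutoff distance from a percentile of all pairwise distances
#'
#' `dc` is the stated percentile of the multiset of the n(n-1)/2 distinct
#' pairwise distances (linear-interpolation percentile convention).
#'
#' @param dmat Distance matrix from [pairwise_distances()].
#' @param percentile Percentile in percent (typically 0.5-4).
#' @return The cutoff distance `dc`.
#' @export
dc_from_percentile <- function(dmat, percentile) {
  d <- dmat[upper.tri(dmat)]
  if (!length(d)) stop("need at least two points")
  stats::quantile(d, percentile / 100, names = FALSE, type = 7)
}

#' Local density by neighbour count
#'
#' The local density of a point is the number of other points strictly
#' closer to it than the cutoff distance `dc` (a hard count, not a kernel).
#'
#' @param dmat Distance matrix.
#' @param dc Cutoff distance.
#' @return Integer vector `rho`, one count per point, each in `[0, n-1]`.
#' @export
local_density <- function(dmat, dc) {
  cnt <- rowSums(dmat < dc)
  as.integer(cnt - as.integer(dc > 0))  # remove self-count when 0 < dc
}

# Strict higher-density order: j precedes i when rho_j > rho_i, ties broken
# by point index. Integer densities make ties common; the chain-assignment
# rule requires a total order.
higher_density <- function(rho, i) {
  rho > rho[i] | (rho == rho[i] & seq_along(rho) < i)
}

#' Separation delta and nearest denser neighbour
#'
#' For each point, `delta` is the distance to the nearest point of higher
#' density (ties in density broken by point index); the global density
#' maximum instead takes the maximum distance to any point and has no
#' neighbour.
#'
#' @param dmat Distance matrix.
#' @param rho Densities from [local_density()].
#' @return A list: `delta` (numeric), `nearest_higher` (integer index,
#'   `NA` for the global maximum).
#' @export
delta_and_neighbor <- function(dmat, rho) {
  n <- length(rho)
  delta <- numeric(n)
  nh <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    h <- which(higher_density(rho, i))
    if (!length(h)) {
      # the unique global density maximum: by convention its separation is
      # the largest pairwise distance in the data, so its gamma score tops
      # every other point
      delta[i] <- max(dmat)
    } else {
      j <- h[which.min(dmat[i, h])]
      delta[i] <- dmat[i, j]
      nh[i] <- j
    }
  }
  list(delta = delta, nearest_higher = nh)
}

#' Assign every point to the cluster of its nearest denser neighbour
#'
#' Points are processed in decreasing density (index-broken ties); centers
#' label themselves, every other point inherits the label of its nearest
#' neighbour of higher density, so one pass labels all points.
#'
#' @param dmat Distance matrix.
#' @param rho Densities.
#' @param centers Integer indices of the cluster centers.
#' @return Integer labels, `labels[centers[k]] == k`.
#' @export
assign_clusters <- function(dmat, rho, centers) {
  n <- length(rho)
  nh <- delta_and_neighbor(dmat, rho)$nearest_higher
  ord <- order(-rho, seq_len(n))
  labels <- rep(NA_integer_, n)
  labels[centers] <- seq_along(centers)
  for (i in ord) {
    if (!is.na(labels[i])) next
    labels[i] <- if (is.na(nh[i])) {
      # global density maximum not selected as a center: nearest center wins
      labels[centers[which.min(dmat[i, centers])]]
    } else labels[nh[i]]
  }
  labels
}

# Choose the number of centers: largest multiplicative gap in the sorted
# gamma sequence among the top ranks, then shrink while any cluster holds
# less than min_cluster_share of the points (a cluster cannot build on a few
# percent of the data).
select_k_by_gap <- function(gamma_sorted, max_candidates = 10L) {
  # only positive-gamma ranks can host a center (rho >= 1, delta > 0)
  m <- min(max_candidates, sum(gamma_sorted > 0))
  if (m < 2L) return(max(m, 1L))
  g <- gamma_sorted[seq_len(m)]
  ratio <- g[-m] / g[-1]
  k <- which.max(ratio)
  if (k == 1L || length(ratio) == 1L) return(k)
  # a multi-cluster break must be unambiguous: the winning multiplicative
  # gap has to dominate every other gap by at least a factor of two,
  # otherwise the sorted-score sequence shows no structural break and a
  # single cluster is reported
  if (ratio[k] < 2 * max(ratio[-k])) return(1L)
  k
}

#' Select cluster centers from the gamma score
#'
#' Candidate centers are the points with the largest `gamma = rho * delta^2`.
#' The candidate count is set at the largest multiplicative gap
#' `gamma_(k)/gamma_(k+1)` among the top ranks; any resulting cluster holding
#' less than `min_cluster_share` of the points triggers re-selection with one
#' fewer center, down to a single cluster.
#'
#' @param dmat Distance matrix.
#' @param rho Densities.
#' @param delta Separations from [delta_and_neighbor()].
#' @param min_cluster_share Minimum fraction of points per cluster.
#' @param max_candidates Number of top-gamma ranks examined for the gap.
#' @return Integer vector of center indices.
#' @export
select_centers <- function(dmat, rho, delta, min_cluster_share = 0.05,
                           max_candidates = 10L) {
  n <- length(rho)
  gamma <- rho * delta^2
  ord <- order(-gamma, seq_len(n))
  if (n < 10L) {
    warning("fewer than 10 points; a single cluster is assumed")
    return(ord[1L])
  }
  k <- select_k_by_gap(gamma[ord], max_candidates)
  repeat {
    centers <- ord[seq_len(k)]
    if (k == 1L) return(centers)
    labels <- assign_clusters(dmat, rho, centers)
    shares <- tabulate(labels, nbins = k) / n
    if (all(shares >= min_cluster_share)) return(centers)
    k <- k - 1L
  }
}

#' Density-peak clustering at one cutoff percentile
#'
#' Full single-dc pipeline: distances, `dc`, densities `rho`, separations
#' `delta`, scores `gamma = rho * delta^2`, center selection and label
#' assignment.
#'
#' @param points Numeric matrix/data frame of 2-D coordinates.
#' @param dc_percentile Percentile of pairwise distances defining `dc`.
#' @param min_cluster_share Minimum fraction of points per cluster.
#' @return A `density_result` list: `rho`, `delta`, `nearest_higher`,
#'   `gamma`, `dc`, `dc_percentile`, `centers`, `labels`, `n_clusters`.
#' @export
density_peak_cluster <- function(points, dc_percentile = 2,
                                 min_cluster_share = 0.05) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 1L) {
    return(structure(list(rho = 0L, delta = 0, nearest_higher = NA_integer_,
                          gamma = 0, dc = NA_real_,
                          dc_percentile = dc_percentile, centers = 1L,
                          labels = 1L, n_clusters = 1L),
                     class = "density_result"))
  }
  dmat <- pairwise_distances(points)
  dc <- dc_from_percentile(dmat, dc_percentile)
  rho <- local_density(dmat, dc)
  dn <- delta_and_neighbor(dmat, rho)
  centers <- select_centers(dmat, rho, dn$delta, min_cluster_share)
  labels <- assign_clusters(dmat, rho, centers)
  structure(list(rho = rho, delta = dn$delta,
                 nearest_higher = dn$nearest_higher,
                 gamma = rho * dn$delta^2, dc = dc,
                 dc_percentile = dc_percentile, centers = centers,
                 labels = labels, n_clusters = length(centers)),
            class = "density_result")
}

#' Sweep the cutoff percentile and keep the richest clustering
#'
#' Runs [density_peak_cluster()] at each percentile and returns the result
#' with the largest cluster count, deliberately disadvantaging the
#' single-cluster hypothesis. Ties go to the percentile closest to 2% (the
#' typical choice), then to the smaller percentile.
#'
#' @param points 2-D coordinates.
#' @param percentiles Percentiles swept (default 0.5, 1, 2, 4).
#' @param min_cluster_share Minimum fraction of points per cluster.
#' @return The winning `density_result`, with a `sweep` data frame attribute
#'   (`percentile`, `dc`, `n_clusters` at every swept value).
#' @export
dc_sweep <- function(points, percentiles = c(0.5, 1, 2, 4),
                     min_cluster_share = 0.05) {
  runs <- lapply(percentiles, function(p)
    density_peak_cluster(points, p, min_cluster_share))
  diag_tab <- data.frame(
    percentile = percentiles,
    dc = vapply(runs, function(r) r$dc, numeric(1)),
    n_clusters = vapply(runs, function(r) r$n_clusters, integer(1)))
  best_n <- max(diag_tab$n_clusters)
  cand <- which(diag_tab$n_clusters == best_n)
  pick <- cand[order(abs(percentiles[cand] - 2), percentiles[cand])][1L]
  out <- runs[[pick]]
  attr(out, "sweep") <- diag_tab
  out
}

#' Cluster one cell's events in the log amplitude / log decay plane
#'
#' Builds the clustering input from the retained events (natural logs of
#' amplitude and decay; the log base cannot change the cluster structure
#' since `dc` is a distance percentile), runs the dc sweep, and attaches
#' per-cluster medians of the three event parameters.
#'
#' @param events Retained event table with `amplitude_pA`, `decay_ms`,
#'   `rise_10_90_ms`.
#' @param percentiles,min_cluster_share Passed to [dc_sweep()].
#' @return The `density_result`, with `cluster_medians` (data frame: cluster,
#'   n, median amplitude/rise/decay) and the event labels.
#' @export
cluster_cell <- function(events, percentiles = c(0.5, 1, 2, 4),
                         min_cluster_share = 0.05) {
  if (!nrow(events)) stop("no events to cluster")
  if (any(events$amplitude_pA <= 0) || any(events$decay_ms <= 0))
    stop("amplitude and decay must be positive before taking logs")
  pts <- cbind(log(events$amplitude_pA), log(events$decay_ms))
  res <- dc_sweep(pts, percentiles, min_cluster_share)
  med <- do.call(rbind, lapply(seq_len(res$n_clusters), function(k) {
    e <- events[res$labels == k, , drop = FALSE]
    data.frame(cluster = k, n = nrow(e),
               median_amplitude_pA = stats::median(e$amplitude_pA),
               median_rise_10_90_ms = stats::median(e$rise_10_90_ms),
               median_decay_ms = stats::median(e$decay_ms))
  }))
  res$cluster_medians <- med
  res
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("density_result: %d cluster(s) at dc percentile %g (dc = %.4g)\n",
              x$n_clusters, x$dc_percentile, x$dc))
  if (!is.null(x$cluster_medians)) print(x$cluster_medians, row.names = FALSE)
  invisible(x)
}
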