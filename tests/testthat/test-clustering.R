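two_blob_points <- function(seed, n_each = 250, sep = log(4), sd_log = 0.2) {
  set.seed(seed)
  rbind(cbind(rnorm(n_each, 0, sd_log), rnorm(n_each, 0, sd_log)),
        cbind(rnorm(n_each, sep, sd_log), rnorm(n_each, sep, sd_log)))
}

test_that("pairwise distances are Euclidean and match brute force", {
  expect_equal(pairwise_distances(rbind(c(0, 0), c(3, 4)))[1, 2], 5)
  expect_equal(pairwise_distances(rbind(c(1, 1), c(1, 1)))[1, 2], 0)
  set.seed(81)
  pts <- matrix(runif(100), 50, 2)
  ref <- brute_density_peaks(pts, 2)
  expect_equal(pairwise_distances(pts), ref$d, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("dc percentile uses the off-diagonal distance multiset", {
  # three collinear points at 0, 1, 3: distances {1, 2, 3}
  d <- pairwise_distances(cbind(c(0, 1, 3), 0))
  expect_equal(dc_from_percentile(d, 50), 2)
  expect_equal(dc_from_percentile(d, 100), 3)
  set.seed(82)
  pts <- matrix(runif(400), 200, 2)
  d <- pairwise_distances(pts)
  expect_equal(dc_from_percentile(d, 2),
               unname(quantile(sort(d[upper.tri(d)]), 0.02, type = 7)))
})

test_that("rho and delta reproduce the hand-worked collinear example", {
  pts <- cbind(c(0, 1, 2), 0)
  d <- pairwise_distances(pts)
  rho <- local_density(d, 1.5)
  expect_identical(rho, c(1L, 2L, 1L))
  dn <- delta_and_neighbor(d, rho)
  expect_equal(dn$delta, c(1, 2, 1))
  expect_identical(dn$nearest_higher, c(2L, NA, 2L))
  # dc below every distance: all densities zero
  expect_identical(local_density(d, 0.5), c(0L, 0L, 0L))
})

test_that("identical points fall back to the index tie order", {
  pts <- matrix(1, 5, 2)
  d <- pairwise_distances(pts)
  rho <- local_density(d, dc_from_percentile(d, 50))
  dn <- delta_and_neighbor(d, rho)
  expect_identical(sum(is.na(dn$nearest_higher)), 1L)
  expect_identical(which(is.na(dn$nearest_higher)), 1L)
  expect_equal(dn$delta[-1], rep(0, 4))
})

test_that("rho, delta, gamma and labels equal the brute-force oracle", {
  set.seed(83)
  for (i in 1:20) {
    n <- sample(20:120, 1)
    pts <- if (i %% 2) matrix(runif(2 * n), n, 2) else
      two_blob_points(1000 + i, n_each = ceiling(n / 2))[1:n, , drop = FALSE]
    pct <- sample(c(0.5, 1, 2, 4), 1)
    got <- density_peak_cluster(pts, pct)
    ref <- brute_density_peaks(pts, pct)
    expect_identical(got$rho, ref$rho)
    expect_equal(got$delta, ref$delta, tolerance = 1e-12)
    expect_equal(got$gamma, ref$gamma, tolerance = 1e-12)
    ref_labels <- brute_assign(ref$nh, got$centers, ref$d)
    expect_identical(got$labels, ref_labels)
  }
})

test_that("labels are permutation-invariant up to renaming", {
  pts <- two_blob_points(84, n_each = 150)
  base <- dc_sweep(pts)
  perm <- sample(nrow(pts))
  permuted <- dc_sweep(pts[perm, ])
  # cluster partitions must coincide after renaming
  tab <- table(base$labels[perm], permuted$labels)
  expect_identical(base$n_clusters, permuted$n_clusters)
  expect_identical(sum(apply(tab, 1, max)), nrow(pts))
})

test_that("uniform rescaling of both axes leaves the clustering unchanged", {
  pts <- two_blob_points(85, n_each = 150)
  a <- dc_sweep(pts)
  b <- dc_sweep(pts * 7.3)    # e.g. a change of log base
  expect_identical(a$labels, b$labels)
  expect_identical(a$centers, b$centers)
})

test_that("a handful of stray points cannot found a cluster", {
  set.seed(86)
  pts <- rbind(cbind(rnorm(496, 0, 0.2), rnorm(496, 0, 0.2)),
               cbind(rnorm(4, 6, 0.01), rnorm(4, 6, 0.01)))
  res <- dc_sweep(pts)  # 0.8% of points sit far away
  expect_identical(res$n_clusters, 1L)
})

test_that("cluster counts recover the generating structure", {
  one <- vapply(1:20, function(s) {
    gt <- generate_event_schedule(
      population_spec(rate = 300 / 180, sigma_log_amplitude = 0.3,
                      sigma_log_decay = 0.3), 200, seed = s)
    dc_sweep(cbind(log(gt$amplitude_pA), log(gt$decay_ms)))$n_clusters
  }, integer(1))
  expect_gte(mean(one == 1L), 0.95)

  pops <- list(
    population_spec(median_amplitude = 30, median_decay = 1,
                    sigma_log_amplitude = 0.2, sigma_log_decay = 0.2,
                    rate = 250 / 180),
    population_spec(median_amplitude = 120, median_decay = 4,
                    sigma_log_amplitude = 0.2, sigma_log_decay = 0.2,
                    rate = 250 / 180))
  two_ok <- vapply(1:20, function(s) {
    gt <- generate_event_schedule(pops, 200, seed = 500 + s)
    r <- dc_sweep(cbind(log(gt$amplitude_pA), log(gt$decay_ms)))
    if (r$n_clusters != 2L) return(FALSE)
    tab <- table(gt$population, r$labels)
    max(sum(diag(tab)), sum(diag(tab[, 2:1]))) / nrow(gt) >= 0.95
  }, logical(1))
  expect_gte(mean(two_ok), 0.95)
})

test_that("degenerate inputs take the single-cluster path", {
  r1 <- density_peak_cluster(matrix(c(1, 2), 1, 2))
  expect_identical(r1$n_clusters, 1L)
  expect_identical(r1$labels, 1L)
  expect_warning(r2 <- density_peak_cluster(matrix(runif(10), 5, 2)),
                 "fewer than 10")
  expect_identical(r2$n_clusters, 1L)
})

test_that("cluster_cell logs both axes and reports per-cluster medians", {
  gt <- generate_event_schedule(
    list(population_spec(median_amplitude = 30, median_decay = 1,
                         sigma_log_amplitude = 0.15, sigma_log_decay = 0.15,
                         rate = 2),
         population_spec(median_amplitude = 120, median_decay = 4,
                         sigma_log_amplitude = 0.15, sigma_log_decay = 0.15,
                         rate = 2)), 150, seed = 87)
  ev <- schedule_to_events(gt)
  res <- cluster_cell(ev)
  expect_identical(res$n_clusters, 2L)
  med <- res$cluster_medians[order(res$cluster_medians$median_amplitude_pA), ]
  expect_equal(med$median_amplitude_pA, c(30, 120), tolerance = 0.1)
  expect_equal(med$median_decay_ms, c(1, 4), tolerance = 0.1)
  expect_error(cluster_cell(ev[0, ]), "no events")
  ev$amplitude_pA[1] <- -1
  expect_error(cluster_cell(ev), "positive")
})
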