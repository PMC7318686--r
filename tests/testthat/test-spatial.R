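test_that("distance to cloud matches geometry and the brute-force oracle", {
  cloud <- data.frame(x = 0, y = 0, z = 0)
  expect_equal(distance_to_cloud(data.frame(x = 0, y = 0, z = 0), cloud), 0)
  expect_equal(distance_to_cloud(data.frame(x = 3, y = 4, z = 0), cloud), 5)
  probes <- withr::with_seed(1, data.frame(x = stats::rnorm(50, 0, 10),
                                           y = stats::rnorm(50, 0, 10),
                                           z = stats::rnorm(50, 0, 10)))
  big <- withr::with_seed(2, data.frame(x = stats::rnorm(500, 0, 15),
                                        y = stats::rnorm(500, 0, 15),
                                        z = stats::rnorm(500, 0, 15)))
  fast <- distance_to_cloud(probes, big)
  brute <- vapply(seq_len(nrow(probes)), function(i) {
    min(sqrt((big$x - probes$x[i])^2 + (big$y - probes$y[i])^2 +
               (big$z - probes$z[i])^2))
  }, numeric(1))
  expect_equal(fast, brute, tolerance = 1e-12)
  expect_error(distance_to_cloud(probes, big[0, ]), "empty")
})

test_that("distance-dynamics correlation detects perfect and absent relations", {
  d <- seq(2, 20, length.out = 30)
  o2 <- 0.1 + 0.02 * d
  res <- dynamics_distance_correlation(d, o2, n_perm = 1999, seed = 1)
  expect_equal(res$R2, 1)
  expect_equal(res$p_perm, 1 / 2000)
  expect_equal(res$slope, 0.02, tolerance = 1e-10)
  # duplication leaves R2 unchanged
  dup <- dynamics_distance_correlation(rep(d, 2), rep(o2, 2),
                                       n_perm = 99, seed = 1)
  expect_equal(dup$R2, 1)
  # independence: R2 near zero
  o2n <- withr::with_seed(3, stats::runif(200, 0.1, 0.7))
  dn <- withr::with_seed(4, stats::runif(200, 2, 20))
  expect_lt(dynamics_distance_correlation(dn, o2n, n_perm = 99,
                                          seed = 1)$R2, 0.05)
  expect_error(dynamics_distance_correlation(rep(1, 10),
                                             stats::runif(10)),
               "zero variance")
})

test_that("spatial clustering test detects segregated classes", {
  # two tight, distant spheres
  a <- withr::with_seed(5, matrix(stats::rnorm(60, 0, 1), ncol = 3))
  b <- withr::with_seed(6, matrix(stats::rnorm(60, 0, 1), ncol = 3) + 50)
  coords <- data.frame(x = c(a[, 1], b[, 1]), y = c(a[, 2], b[, 2]),
                       z = c(a[, 3], b[, 3]))
  classes <- rep(c("J", "alpha"), each = 20)
  res <- spatial_class_clustering_test(coords, classes, n_perm = 999,
                                       seed = 1)
  expect_equal(res$p_value, 1 / 1000)
  expect_lt(res$statistic, 0)
  # generator-planted clustering
  ds <- make_spatial_dataset(clustered = TRUE, n = 80, seed = 2)
  resc <- spatial_class_clustering_test(ds$coords, ds$classes,
                                        n_perm = 999, seed = 3)
  expect_lte(resc$p_value, 0.01)
})

test_that("degenerate class structures are handled", {
  coords <- data.frame(x = stats::rnorm(10), y = stats::rnorm(10),
                       z = stats::rnorm(10))
  res <- spatial_class_clustering_test(coords, rep("J", 10), n_perm = 99,
                                       seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_warning(
    spatial_class_clustering_test(coords, c(rep("J", 9), "alpha"),
                                  n_perm = 99, seed = 1),
    "excluded")
})

test_that("permutation statistics are seed-reproducible and rigid-motion invariant", {
  ds <- make_spatial_dataset(clustered = FALSE, n = 40, seed = 7)
  r1 <- spatial_class_clustering_test(ds$coords, ds$classes, n_perm = 199,
                                      seed = 11)
  r2 <- spatial_class_clustering_test(ds$coords, ds$classes, n_perm = 199,
                                      seed = 11)
  expect_identical(r1, r2)
  # rigid-body transform: rotate + translate all coordinates
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  moved <- as.data.frame(as.matrix(ds$coords) %*% t(R) + 5)
  names(moved) <- c("x", "y", "z")
  r3 <- spatial_class_clustering_test(moved, ds$classes, n_perm = 199,
                                      seed = 11)
  expect_equal(r3$statistic, r1$statistic, tolerance = 1e-10)
  expect_equal(r3$p_value, r1$p_value)
})

test_that("the k-means partition variant agrees on compact segregation", {
  # The ARI statistic asks whether classes coincide with a *contiguous*
  # spatial partition, so it is exercised on compact blobs; the
  # distance-based test above covers non-contiguous clustering.
  set.seed(1)
  cc <- rbind(matrix(stats::rnorm(45, 0, 2), ncol = 3),
              matrix(stats::rnorm(45, 0, 2) + 20, ncol = 3),
              matrix(stats::rnorm(45, 0, 2) - 20, ncol = 3))
  coords <- data.frame(x = cc[, 1], y = cc[, 2], z = cc[, 3])
  classes <- rep(c("Jprime", "J", "alpha"), each = 15)
  res <- spatial_class_kmeans_test(coords, classes, n_perm = 499,
                                   seed = 2)
  expect_lte(res$p_value, 0.01)
  expect_gt(res$statistic, 0.9)
})
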