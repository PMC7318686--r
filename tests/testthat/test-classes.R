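test_that("class-count selection finds one class for a single Gaussian", {
  v <- withr::with_seed(8, stats::rnorm(100, 0.4, 0.03))
  expect_equal(select_class_count(v, seed = 8)$k_best, 1)
})

test_that("three well-separated components are recovered across seeds", {
  hits <- vapply(1:20, function(s) {
    v <- withr::with_seed(s, {
      cl <- sample(1:3, 150, replace = TRUE)
      pmin(pmax(c(0.21, 0.40, 0.65)[cl] + stats::rnorm(150, 0, 0.04),
                0.01), 0.99)
    })
    select_class_count(v, seed = s)$k_best == 3
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("exactly duplicated components do not inflate the class count", {
  # two "components" at the same location are one Gaussian
  v <- withr::with_seed(9, stats::rnorm(120, 0.4, 0.05))
  expect_equal(select_class_count(v, seed = 9)$k_best, 1)
  expect_error(select_class_count(v[1:5]), "at least 10")
})

test_that("k-means recovers exact clusters with midpoint boundaries", {
  expect_warning(m <- kmeans_classes(c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9),
                                     k = 2), "ambiguous")
  expect_equal(m$centers, c(0.1, 0.9))
  expect_equal(m$boundaries, 0.5)
  expect_equal(m$sizes, c(3, 3))
  expect_error(kmeans_classes(c(0.1, 0.1), k = 3), "distinct")
})

test_that("k-means classes are deterministic and permutation-invariant", {
  v <- withr::with_seed(3, stats::runif(60, 0, 1))
  m1 <- kmeans_classes(v, 3, seed = 42)
  m2 <- kmeans_classes(v, 3, seed = 42)
  expect_identical(m1$centers, m2$centers)
  perm <- withr::with_seed(4, sample(seq_along(v)))
  m3 <- kmeans_classes(v[perm], 3, seed = 42)
  expect_equal(m3$centers, m1$centers, tolerance = 1e-12)
  expect_identical(m1$assignments[perm], m3$assignments)
})

test_that("boundaries strictly separate assignments and sizes are conserved", {
  v <- withr::with_seed(5, stats::runif(80))
  m <- kmeans_classes(v, 3, seed = 1)
  expect_equal(sum(m$sizes), length(v))
  for (i in seq_along(v)) {
    j <- match(m$assignments[i], m$labels)
    if (j > 1) expect_gte(v[i], m$boundaries[j - 1])
    if (j < m$k) expect_lte(v[i], m$boundaries[j])
  }
})

test_that("mixture centers are recovered within sampling error across seeds", {
  centers <- c(0.21, 0.40, 0.65)
  sig <- 0.04
  for (s in 1:20) {
    draw <- withr::with_seed(100 + s, {
      cl <- sample(1:3, 150, replace = TRUE)
      list(cl = cl, v = centers[cl] + stats::rnorm(150, 0, sig))
    })
    m <- kmeans_classes(draw$v, 3, seed = s)
    for (j in 1:3) {
      n_j <- sum(draw$cl == j)
      expect_lt(abs(m$centers[j] - centers[j]), 3 * sig / sqrt(n_j) + 0.02)
    }
  }
})

test_that("labels follow the motional taxonomy rules", {
  v_low <- withr::with_seed(6, c(stats::rnorm(30, 0.21, 0.03),
                                 stats::rnorm(30, 0.40, 0.03),
                                 stats::rnorm(30, 0.60, 0.03)))
  m3 <- kmeans_classes(v_low, 3, seed = 1)
  expect_equal(m3$labels, c("Jprime", "J", "alpha"))
  v_high <- withr::with_seed(7, c(stats::rnorm(30, 0.40, 0.03),
                                  stats::rnorm(30, 0.60, 0.03),
                                  stats::rnorm(30, 0.85, 0.03)))
  m3h <- kmeans_classes(v_high, 3, seed = 1)
  expect_equal(m3h$labels, c("J", "alpha", "omega"))
  expect_warning(kmeans_classes(v_low, 2, seed = 1), "ambiguous")
})

test_that("out-of-range values are clipped for clustering only and flagged", {
  v <- c(-0.05, 0.2, 0.4, 0.6, 1.1)
  expect_warning(m <- kmeans_classes(v, 2, seed = 1), "ambiguous")
  expect_equal(m$clipped, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_true(all(m$centers >= 0 & m$centers <= 1))
})

test_that("class composition reports MLI vs V fractions and enrichment", {
  # all-valine probes: every class 100% V, zero enrichment
  v <- c(0.1, 0.12, 0.5, 0.52)
  expect_warning(m <- kmeans_classes(v, 2, seed = 1), "ambiguous")
  probes <- suppressWarnings(methyl_probes(1:4, "VAL", "g1"))
  comp <- suppressWarnings(class_composition(m, probes))
  expect_true(all(comp$frac_V == 1))
  expect_true(all(comp$enrich_MLI == 0))
})

test_that("planted composition is recovered within the binomial envelope", {
  n <- 200
  draw <- withr::with_seed(21, {
    cl <- sample(1:3, n, replace = TRUE, prob = c(1, 1, 1))
    p_mli <- ifelse(cl == 1, 0.75, 0.5)
    mli <- stats::runif(n) < p_mli
    list(cl = cl,
         v = pmin(pmax(c(0.21, 0.40, 0.65)[cl] + stats::rnorm(n, 0, 0.04),
                       0.01), 0.99),
         type = ifelse(mli, "ILE", "VAL"))
  })
  probes <- methyl_probes(1:n, draw$type,
                          ifelse(draw$type == "ILE", "d1", "g1"))
  m <- kmeans_classes(draw$v, 3, seed = 2)
  comp <- class_composition(m, probes)
  jp <- comp[comp$class == "Jprime", ]
  ci <- 3 * sqrt(0.75 * 0.25 / jp$n)
  expect_lt(abs(jp$frac_MLI - 0.75), ci + 0.05)
  expect_gt(jp$enrich_MLI, 0)
})
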