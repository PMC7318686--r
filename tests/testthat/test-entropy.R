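test_that("cone entropy has the exact closed form at zero order", {
  s <- cone_entropy(0)
  expect_identical(s$S_kB, log(2 * pi))
  expect_equal(s$S_J_mol_K, log(2 * pi) * 8.31446261815324)
})

test_that("cone entropy is continuous, strictly decreasing and divergent at 1", {
  grid <- seq(0, 0.999, length.out = 400)
  s <- cone_entropy(grid)$S_kB
  expect_true(all(diff(s) < 0))
  expect_true(all(is.finite(s)))
  # continuous at zero (the slope is infinite there, but the value is not)
  expect_lt(abs(cone_entropy(1e-8)$S_kB - log(2 * pi)), 1e-3)
  expect_lt(s[length(s)], -2)         # heading to -Inf
  expect_gt(cone_entropy(0.21)$S_kB, cone_entropy(0.36)$S_kB)
  expect_gt(cone_entropy(0.36)$S_kB, cone_entropy(0.55)$S_kB)
  expect_error(cone_entropy(1), "diverges")
  expect_error(cone_entropy(-0.1), ">= 0")
})

test_that("ensemble entropy is additive and skips invalid entries", {
  two0 <- quick_set(c(0, 0))
  e <- suppressWarnings(ensemble_entropy(two0))
  expect_equal(e$total_kB, 2 * log(2 * pi))
  # union additivity over disjoint probes
  a <- quick_set(c(0.2, 0.3), start_res = 1)
  b <- quick_set(c(0.5, 0.6), start_res = 10)
  ab <- quick_set(c(0.2, 0.3, 0.5, 0.6))
  expect_equal(ensemble_entropy(ab)$total_kB,
               ensemble_entropy(a)$total_kB + ensemble_entropy(b)$total_kB)
  # rigid entries are excluded, not clipped
  withbad <- quick_set(c(0.3, 1.05))
  expect_warning(e2 <- ensemble_entropy(withbad), "skipped")
  expect_equal(e2$n_probes, 1)
  expect_equal(e2$n_skipped, 1)
  expect_error(suppressWarnings(ensemble_entropy(quick_set(1.2))),
               "no entries")
})

test_that("a membrane-like ensemble carries more entropy than a soluble-like one", {
  mem <- withr::with_seed(31, pmin(pmax(stats::rnorm(60, 0.36, 0.1),
                                        0.01), 0.95))
  sol <- withr::with_seed(32, pmin(pmax(stats::rnorm(60, 0.55, 0.1),
                                        0.01), 0.95))
  expect_gt(ensemble_entropy(quick_set(mem))$mean_kB,
            ensemble_entropy(quick_set(sol))$mean_kB)
})

test_that("ensemble totals match the analytic mixture expectation", {
  # oracle: expected cone entropy under a truncated 3-class mixture by
  # numerical integration of the density
  centers <- c(0.21, 0.36, 0.55); w <- c(1, 1, 1) / 3; sig <- 0.05
  lo <- 0.02; hi <- 0.95
  dens <- function(x) {
    rowSums(vapply(1:3, function(j) {
      w[j] * stats::dnorm(x, centers[j], sig) /
        (stats::pnorm(hi, centers[j], sig) - stats::pnorm(lo, centers[j], sig))
    }, numeric(length(x))))
  }
  e_fun <- function(x) cone_entropy(x)$S_kB * dens(x)
  expected <- stats::integrate(e_fun, lo, hi, rel.tol = 1e-8)$value
  n <- 4000
  draw <- withr::with_seed(33, {
    cl <- sample(1:3, n, replace = TRUE)
    x <- centers[cl] + stats::rnorm(n, 0, sig)
    while (any(x < lo | x > hi)) {
      bad <- x < lo | x > hi
      x[bad] <- centers[cl[bad]] + stats::rnorm(sum(bad), 0, sig)
    }
    x
  })
  mean_s <- mean(cone_entropy(draw)$S_kB)
  se <- stats::sd(cone_entropy(draw)$S_kB) / sqrt(n)
  expect_lt(abs(mean_s - expected), 4 * se)
})

test_that("delta entropy tracks paired shifts in order", {
  base <- quick_set(c(0.2, 0.35, 0.5))
  expect_equal(delta_entropy(base, base)$per_probe$dS_kB, rep(0, 3))
  shifted <- quick_set(c(0.2, 0.35, 0.5) + 0.055)
  d <- delta_entropy(base, shifted)
  expect_true(all(d$per_probe$dS_kB < 0))
  # shift applied to half the probes: total equals sum over shifted pairs
  half <- quick_set(c(0.2 + 0.055, 0.35, 0.5))
  dh <- delta_entropy(base, half)
  expect_equal(dh$total_kB, dh$per_probe$dS_kB[1])
  expect_equal(dh$per_probe$dS_kB[2:3], c(0, 0))
})
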