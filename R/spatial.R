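#' Minimum distance from probes to a point cloud
#'
#' Euclidean minimum distance from each methyl carbon to any point of a
#' reference cloud (lipid or detergent atoms, or a pseudo-cloud on the
#' bilayer surfaces).
#'
#' @param probes matrix or data frame with columns x, y, z (angstrom).
#' @param cloud matrix or data frame with columns x, y, z; non-empty.
#' @return numeric vector of minimum distances, one per probe.
#' @export
distance_to_cloud <- function(probes, cloud) {
  P <- as.matrix(as.data.frame(probes)[c("x", "y", "z")])
  Q <- as.matrix(as.data.frame(cloud)[c("x", "y", "z")])
  if (nrow(Q) == 0) stop("reference cloud is empty")
  # |p - q|^2 = |p|^2 + |q|^2 - 2 p.q, minimized over q per probe
  p2 <- rowSums(P^2)
  q2 <- rowSums(Q^2)
  cross <- P %*% t(Q)
  d2 <- outer(p2, q2, "+") - 2 * cross
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Correlation of dynamics with distance to the membrane
#'
#' Ordinary least squares of O2_axis on the distance to the nearest lipid
#' atom, with a permutation p-value for the squared correlation. A flat
#' relationship (R^2 near zero) indicates that side-chain disorder is not a
#' surface-molten phenomenon but heterogeneously distributed through the
#' protein.
#'
#' @param distances per-probe distances, angstrom (>= 5).
#' @param O2_values matching O2_axis values.
#' @param n_perm number of label permutations (default 1999).
#' @param seed permutation seed.
#' @return list with `R2`, `slope`, `intercept`, `p_perm`, `n`.
#' @export
dynamics_distance_correlation <- function(distances, O2_values,
                                          n_perm = 1999, seed = 1) {
  stopifnot(length(distances) == length(O2_values))
  n <- length(distances)
  if (n < 5) stop("need at least 5 pairs")
  if (stats::sd(distances) == 0 || stats::sd(O2_values) == 0)
    stop("zero variance: R^2 undefined")
  r2_obs <- stats::cor(distances, O2_values)^2
  fit <- stats::lm(O2_values ~ distances)
  perm_ge <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      stats::cor(distances, sample(O2_values))^2 >= r2_obs
    }, logical(1)))
  })
  list(R2 = r2_obs,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_perm = (1 + perm_ge) / (n_perm + 1),
       n = n)
}

#' Permutation test for spatial clustering of motional classes
#'
#' Tests whether probes of the same motional class sit closer together in
#' the structure than expected by chance. The statistic is the mean
#' within-class pairwise distance minus the overall mean pairwise distance
#' (negative = spatially clustered); the null distribution comes from
#' permuting class labels over the fixed coordinates. One-sided toward
#' clustering, +1-smoothed p-value. Classes with fewer than 2 members are
#' excluded from the statistic with a warning.
#'
#' @param coords matrix or data frame with columns x, y, z.
#' @param classes class label per probe.
#' @param n_perm number of permutations (default 1999).
#' @param seed permutation seed.
#' @return list with `statistic` (angstrom), `p_value`, `n_perm`.
#' @export
spatial_class_clustering_test <- function(coords, classes, n_perm = 1999,
                                          seed = 1) {
  P <- as.matrix(as.data.frame(coords)[c("x", "y", "z")])
  classes <- as.character(classes)
  stopifnot(nrow(P) == length(classes))
  D <- as.matrix(stats::dist(P))
  tab <- table(classes)
  usable <- names(tab)[tab >= 2]
  if (length(usable) < length(tab))
    warning("class(es) with < 2 members excluded from the statistic: ",
            paste(setdiff(names(tab), usable), collapse = ", "))
  if (length(usable) < 2) {
    if (length(usable) == 1 && all(classes %in% usable))
      return(list(statistic = 0, p_value = 1, n_perm = n_perm))
    if (length(usable) < 1) stop("no class with >= 2 members")
    return(list(statistic = 0, p_value = 1, n_perm = n_perm))
  }
  overall <- mean(D[upper.tri(D)])
  stat_for <- function(lab) {
    s <- 0; m <- 0L
    for (cl in usable) {
      idx <- which(lab == cl)
      if (length(idx) < 2) next
      sub <- D[idx, idx]
      s <- s + sum(sub[upper.tri(sub)])
      m <- m + length(idx) * (length(idx) - 1) / 2
    }
    s / m - overall
  }
  obs <- stat_for(classes)
  perm_le <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      stat_for(sample(classes)) <= obs
    }, logical(1)))
  })
  list(statistic = obs, p_value = (1 + perm_le) / (n_perm + 1),
       n_perm = n_perm)
}

#' Spatial clustering test via k-means partition agreement
#'
#' Alternative statistic: partition the coordinates by k-means into as many
#' groups as there are classes and measure the adjusted Rand index between
#' the spatial partition and the motional-class labels; the permutation
#' null permutes the labels. High agreement (large ARI) indicates spatial
#' segregation of classes.
#'
#' @inheritParams spatial_class_clustering_test
#' @return list with `statistic` (adjusted Rand index), `p_value`, `n_perm`.
#' @export
spatial_class_kmeans_test <- function(coords, classes, n_perm = 1999,
                                      seed = 1) {
  P <- as.matrix(as.data.frame(coords)[c("x", "y", "z")])
  classes <- as.character(classes)
  k <- length(unique(classes))
  if (k < 2) return(list(statistic = 0, p_value = 1, n_perm = n_perm))
  withr::with_seed(seed, {
    part <- stats::kmeans(P, centers = k, nstart = 20)$cluster
    obs <- mclust::adjustedRandIndex(part, classes)
    ge <- sum(vapply(seq_len(n_perm), function(i) {
      mclust::adjustedRandIndex(part, sample(classes)) >= obs
    }, logical(1)))
    list(statistic = obs, p_value = (1 + ge) / (n_perm + 1),
         n_perm = n_perm)
  })
}

#' Pseudo-cloud of lipid points from a bilayer z-slab
#'
#' When no explicit lipid/detergent coordinates are available, the
#' approximate bilayer-spanning region can be supplied as a z-slab
#' \[z_min, z_max\]; a regular grid of points on the two slab surfaces then
#' serves as the reference cloud for [distance_to_cloud()].
#'
#' @param z_min,z_max slab faces, angstrom.
#' @param xy_range half-width of the lateral grid, angstrom.
#' @param spacing grid spacing, angstrom.
#' @return data.frame with x, y, z.
#' @export
zslab_pseudo_cloud <- function(z_min, z_max, xy_range = 30, spacing = 2) {
  stopifnot(z_max > z_min)
  g <- seq(-xy_range, xy_range, by = spacing)
  grid <- expand.grid(x = g, y = g)
  rbind(data.frame(grid, z = z_min), data.frame(grid, z = z_max))
}
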