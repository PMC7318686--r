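#' Ground-truth presets for synthetic methyl-dynamics data
#'
#' Bundles every parameter of the synthetic generators, with defaults that
#' emulate the two study systems: an alpha-helical membrane protein in
#' DHPC-type micelles / DMPC bicelles ("pSRII"-like, 90 resolved methyls,
#' tumbling 21.9/28.9 ns, class centers 0.21/0.36/0.55) and a beta-barrel
#' ("OmpW"-like, 55 methyls, tumbling 24.0/29.9 ns, centers
#' 0.21/0.42/0.66). Mixture weights are set so that the ensemble mean
#' O2_axis is 0.36 with roughly one third of probes in the highly dynamic
#' J-prime class (for the beta-barrel the higher J/alpha centers force a
#' heavier low-order tail to preserve the same ensemble mean). The lowest
#' class draws Met/Leu/Ile vs Val 3:1; the others 1:1.
#'
#' @param preset "pSRII" or "OmpW".
#' @param ... overrides for any field of the returned list.
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(preset = c("pSRII", "OmpW"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    pSRII = list(
      name = "pSRII-like",
      n_probes = 90,
      tau_m_ns = c(micelle = 21.9, bicelle = 28.9),
      centers = c(0.21, 0.36, 0.55),
      weights = c(0.3333, 0.4035, 0.2632),
      sigma_class = 0.05,
      error_range = c(0.010, 0.066),
      high_error_frac = 0.05,
      target_R2_env = 0.81,
      temperature_K = 323.15),
    OmpW = list(
      name = "OmpW-like",
      n_probes = 55,
      tau_m_ns = c(micelle = 24.0, bicelle = 29.9),
      centers = c(0.21, 0.42, 0.66),
      weights = c(0.52, 0.28, 0.20),
      sigma_class = 0.05,
      error_range = c(0.005, 0.033),
      high_error_frac = 0.05,
      target_R2_env = 0.96,
      temperature_K = 313.15))
  truth <- utils::modifyList(c(base, list(
    comp_jprime_MLI = 0.75,
    comp_other_MLI = 0.50,
    delays_s = seq(0.004, 0.024, by = 0.004),
    sigma_ratio = 0.01,
    rate_noise_frac = 0.02,
    S2_backbone_range = c(0.8, 0.9),
    field_MHz = 600)), list(...))
  truth$weights <- truth$weights / sum(truth$weights)
  stopifnot(all(truth$weights > 0), truth$sigma_class > 0,
            length(truth$centers) == length(truth$weights))
  class(truth) <- "ground_truth"
  truth
}

#' Write a ground-truth sidecar JSON next to generated tables
#'
#' @param truth a [ground_truth()] object.
#' @param path output path (JSON).
#' @param seed the seed used for generation, recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path, seed) {
  out <- unclass(truth)
  out$seed <- seed
  # preserve element names of named vectors (jsonlite drops them when
  # serializing atomic vectors as arrays)
  out <- lapply(out, function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Synthesize a backbone 15N relaxation table
#'
#' Rates from the rigid model-free forward model at the preset tumbling
#' time, with per-residue S2 drawn uniformly from the backbone range,
#' multiplicative Gaussian noise on the rates and, optionally, planted
#' exchange outliers.
#'
#' @param truth a [ground_truth()] object.
#' @param n_residues number of residues (default 20).
#' @param environment which tumbling time to use ("micelle" or "bicelle").
#' @param noise_frac fractional Gaussian noise on R1 and R2 (default the
#'   preset's `rate_noise_frac`; 0 for noiseless tables).
#' @param n_outliers number of residues given an exchange contribution.
#' @param R_ex_outlier exchange rate planted in the outliers, s^-1.
#' @param seed generation seed.
#' @param constants a [methyl_constants()] object.
#' @return `relaxation_records` table with attribute `outlier_residues`.
#' @export
make_backbone_dataset <- function(truth, n_residues = 20,
                                  environment = "micelle",
                                  noise_frac = truth$rate_noise_frac,
                                  n_outliers = 0, R_ex_outlier = 8,
                                  seed = 1,
                                  constants = methyl_constants()) {
  tau_m <- truth$tau_m_ns[[environment]] * 1e-9
  withr::with_seed(seed, {
    S2 <- stats::runif(n_residues, truth$S2_backbone_range[1],
                       truth$S2_backbone_range[2])
    outliers <- if (n_outliers > 0)
      sample(n_residues, n_outliers) else integer(0)
    R1 <- R2 <- numeric(n_residues)
    for (i in seq_len(n_residues)) {
      rex <- if (i %in% outliers) R_ex_outlier else 0
      r <- predict_n15_rates(S2 = S2[i], tau_m = tau_m, R_ex = rex,
                             field_MHz = truth$field_MHz,
                             constants = constants)
      R1[i] <- r$R1; R2[i] <- r$R2
    }
    if (noise_frac > 0) {
      R1 <- R1 * (1 + stats::rnorm(n_residues, 0, noise_frac))
      R2 <- R2 * (1 + stats::rnorm(n_residues, 0, noise_frac))
    }
    rec <- relaxation_records(data.frame(
      residue_number = seq_len(n_residues),
      R1 = R1, R1_err = abs(R1) * max(noise_frac, 1e-6),
      R2 = R2, R2_err = abs(R2) * max(noise_frac, 1e-6),
      field_MHz = truth$field_MHz, temperature_K = truth$temperature_K))
    attr(rec, "outlier_residues") <- sort(outliers)
    rec
  })
}

#' Synthesize per-methyl build-up series with known order parameters
#'
#' Draws true O2_axis values from the preset's motional-class mixture
#' (truncated into (0, 0.95\]), assigns residue types per the class
#' composition rule, converts each O2 to an eta at the environment's
#' tumbling time and emits build-up ratios from the forward model with
#' Gaussian noise. A paired bicelle replicate shares the same underlying
#' O2 values plus an independent perturbation whose variance is chosen so
#' that the expected micelle/bicelle R^2 equals the preset target
#' (s^2 = Var(O2) (1/R2 - 1)).
#'
#' @param truth a [ground_truth()] object.
#' @param environments subset of c("micelle", "bicelle") to generate.
#' @param sigma_ratio build-up ratio noise (default preset value; 0 for
#'   noiseless series).
#' @param seed generation seed.
#' @param constants a [methyl_constants()] object.
#' @return list with `buildup` (per environment: list of `buildup_series`),
#'   `truth_sets` (per environment: `o2_set` of the true O2 values with the
#'   drawn reported errors), `class_index` (true class per probe) and
#'   `probes`.
#' @export
make_methyl_dataset <- function(truth,
                                environments = c("micelle", "bicelle"),
                                sigma_ratio = truth$sigma_ratio,
                                seed = 1,
                                constants = methyl_constants()) {
  n <- truth$n_probes
  withr::with_seed(seed, {
    cls <- sample(seq_along(truth$weights), n, replace = TRUE,
                  prob = truth$weights)
    o2_true <- truth$centers[cls] +
      stats::rnorm(n, 0, truth$sigma_class)
    o2_true <- pmin(pmax(o2_true, 0.02), 0.95)

    p_mli <- ifelse(cls == 1, truth$comp_jprime_MLI, truth$comp_other_MLI)
    is_mli <- stats::runif(n) < p_mli
    rtype <- ifelse(is_mli, sample(c("MET", "LEU", "ILE"), n, replace = TRUE),
                    "VAL")
    mid <- c(ILE = "d1", LEU = "d1", VAL = "g1", MET = "e")[rtype]
    probes <- methyl_probes(seq_len(n), rtype, mid, chain = "A")

    errs <- stats::runif(n, truth$error_range[1], truth$error_range[2])
    hi <- stats::runif(n) < truth$high_error_frac
    errs[hi] <- stats::runif(sum(hi), 0.105, 0.15)

    # calibrate the bicelle perturbation so the expected micelle/bicelle
    # R^2 equals the preset target: with shared truth t (variance V),
    # measurement noise m^2 on each fitted O2 and perturbation s^2 on the
    # bicelle side, R^2 = V^2 / ((V + m^2)(V + s^2 + m^2)). m^2 comes from
    # the delta method on the build-up fit at each probe's true eta.
    v_o2 <- stats::var(o2_true)
    scale_mic <- o2axis_to_eta(1, truth$tau_m_ns[["micelle"]] * 1e-9,
                               constants)
    eta_mic <- o2_true * scale_mic
    # per-probe eta variance from the 2 x 2 Fisher information of the
    # (eta, delta) fit evaluated at delta = 0
    var_eta <- vapply(eta_mic, function(e) {
      gh <- 0.75 * truth$delays_s / cosh(e * truth$delays_s)^2
      gd <- 0.75 * tanh(e * truth$delays_s)^2 / e
      A <- sum(gh^2); B <- sum(gd^2); C <- sum(gh * gd)
      sigma_ratio^2 * B / (A * B - C^2)
    }, numeric(1))
    m2 <- mean(var_eta) / scale_mic^2
    s2 <- max(v_o2^2 / (truth$target_R2_env * (v_o2 + m2)) - v_o2 - m2, 0)
    s_env <- sqrt(s2)

    out <- list(buildup = list(), truth_sets = list())
    for (env in environments) {
      o2_env <- if (env == "bicelle")
        pmin(pmax(o2_true + stats::rnorm(n, 0, s_env), 0.02), 0.95)
      else o2_true
      tau_m <- truth$tau_m_ns[[env]] * 1e-9
      eta <- o2axis_to_eta(o2_env, tau_m, constants)
      series <- lapply(seq_len(n), function(i) {
        r <- buildup_ratio(truth$delays_s, eta[i])
        if (sigma_ratio > 0)
          r <- r + stats::rnorm(length(r), 0, sigma_ratio)
        r <- pmin(pmax(r, -0.999), 0.999)
        buildup_series(probes[i, ], truth$delays_s, r,
                       rep(sigma_ratio, length(r)),
                       truth$temperature_K)
      })
      out$buildup[[env]] <- series
      out$truth_sets[[env]] <- o2_set(probes, o2_env, errs,
                                      truth$temperature_K, env,
                                      tau_m_ns = truth$tau_m_ns[[env]])
    }
    out$class_index <- cls
    out$probes <- probes
    out
  })
}

#' Fit a full build-up data set to an order-parameter set
#'
#' Pipeline glue: runs [fit_eta()] on every series and converts to O2_axis
#' at the given tumbling time, propagating the eta error.
#'
#' @param series_list list of `buildup_series`.
#' @param tau_m_ns tumbling time, ns.
#' @param environment environment tag for the resulting set.
#' @param n_mc Monte-Carlo draws per probe for the eta error.
#' @param seed fitting seed.
#' @param constants a [methyl_constants()] object.
#' @return an `o2_set` of fitted values; non-convergent probes are dropped
#'   with a warning.
#' @export
fit_o2_set <- function(series_list, tau_m_ns, environment = "micelle",
                       n_mc = 100, seed = 1,
                       constants = methyl_constants()) {
  tau_m <- tau_m_ns * 1e-9
  scale <- o2axis_to_eta(1, tau_m, constants)
  rows <- list()
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    fit <- tryCatch(fit_eta(s, n_mc = n_mc, seed = seed + i),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning("fit failed for probe ", probe_key(s$probe), "; dropped")
      next
    }
    rows[[length(rows) + 1L]] <- cbind(
      s$probe[c("chain", "residue_number", "residue_type", "methyl_id")],
      O2 = fit$eta / scale,
      err = if (is.finite(fit$eta_err)) fit$eta_err / scale else 0,
      temperature_K = s$temperature_K)
  }
  if (!length(rows)) stop("no series could be fitted")
  df <- do.call(rbind, rows)
  o2_set(df[c("chain", "residue_number", "residue_type", "methyl_id")],
         O2_axis = df$O2, error = df$err,
         temperature_K = df$temperature_K,
         environment = environment, tau_m_ns = tau_m_ns)
}

#' Random walk of a unit vector inside a cone
#'
#' Reflecting random walk with uniform stationary density on the spherical
#' cap of semi-angle theta0 about +z: the cosine of the polar angle
#' performs a reflecting Gaussian walk on \[cos(theta0), 1\] (uniform in
#' cos(theta) = uniform area density) while the azimuth diffuses freely.
#' Step sizes are set so the orientational decorrelation time is about
#' `decorr_frames` frames.
#'
#' @param theta0_deg cone semi-angle, degrees, in (0, 90).
#' @param n_frames number of frames (>= 2).
#' @param dt frame spacing, ps.
#' @param seed generation seed.
#' @param decorr_frames target decorrelation time in frames (default 50).
#' @return a `vector_trajectory`.
#' @export
make_cone_trajectory <- function(theta0_deg, n_frames, dt = 1, seed = 1,
                                 decorr_frames = 50) {
  stopifnot(theta0_deg > 0, theta0_deg < 90, n_frames >= 2)
  u_min <- cos(theta0_deg * pi / 180)
  L <- 1 - u_min
  sd_u <- L * sqrt(2 / (pi^2 * decorr_frames))
  sd_phi <- sqrt(2 / decorr_frames)
  withr::with_seed(seed, {
    u_free <- cumsum(c(stats::runif(1, u_min, 1),
                       stats::rnorm(n_frames - 1, 0, sd_u)))
    # fold the free walk into [u_min, 1]: reflection = triangle-wave map
    y <- (u_free - u_min) %% (2 * L)
    u <- u_min + ifelse(y > L, 2 * L - y, y)
    phi <- cumsum(c(stats::runif(1, 0, 2 * pi),
                    stats::rnorm(n_frames - 1, 0, sd_phi)))
    st <- sqrt(pmax(1 - u^2, 0))
    vector_trajectory(cbind(st * cos(phi), st * sin(phi), u), dt = dt,
                      label = sprintf("cone %g deg", theta0_deg))
  })
}

#' Closed-form order parameter of diffusion in a cone
#'
#' O2 = \[cos(theta0) (1 + cos(theta0)) / 2\]^2 for uniform sampling of a
#' cap of semi-angle theta0; the oracle for [make_cone_trajectory()].
#'
#' @param theta0_deg cone semi-angle, degrees.
#' @return O2, dimensionless.
#' @export
cone_order_parameter <- function(theta0_deg) {
  ct <- cos(theta0_deg * pi / 180)
  (ct * (1 + ct) / 2)^2
}

#' Isotropically disordered trajectory (uniform on the sphere)
#'
#' Independent uniform directions; the O2 -> 0 limit used to check the
#' isotropic behaviour of the estimators.
#'
#' @param n_frames number of frames.
#' @param seed generation seed.
#' @return a `vector_trajectory`.
#' @export
make_sphere_trajectory <- function(n_frames, seed = 1) {
  withr::with_seed(seed, {
    u <- stats::runif(n_frames, -1, 1)
    phi <- stats::runif(n_frames, 0, 2 * pi)
    st <- sqrt(1 - u^2)
    vector_trajectory(cbind(st * cos(phi), st * sin(phi), u),
                      label = "isotropic")
  })
}

#' Synthesize a spatial data set for the clustering tests
#'
#' Gaussian point cloud inside a 40 angstrom box with three motional-class
#' labels, either assigned at random (null) or by spatial octant
#' (clustered), plus a lipid pseudo-cloud on two z-planes bracketing the
#' cloud.
#'
#' @param clustered logical; plant spatial segregation of classes.
#' @param n number of probes (>= 10).
#' @param seed generation seed.
#' @return list with `coords` (data frame x, y, z), `classes`, `O2_axis`
#'   (class-typical values with scatter) and `lipid_cloud`.
#' @export
make_spatial_dataset <- function(clustered = FALSE, n = 60, seed = 1) {
  stopifnot(n >= 10)
  centers <- c(0.21, 0.36, 0.55)
  withr::with_seed(seed, {
    xyz <- matrix(stats::rnorm(3 * n, 0, 10), ncol = 3)
    xyz <- pmin(pmax(xyz, -20), 20)
    coords <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    if (clustered) {
      octant <- (xyz[, 1] > 0) + 2 * (xyz[, 2] > 0) + 4 * (xyz[, 3] > 0)
      cls <- octant %% 3 + 1
    } else {
      cls <- sample(1:3, n, replace = TRUE)
    }
    o2 <- pmin(pmax(centers[cls] + stats::rnorm(n, 0, 0.05), 0.02), 0.95)
    list(coords = coords,
         classes = c("Jprime", "J", "alpha")[cls],
         O2_axis = o2,
         lipid_cloud = zslab_pseudo_cloud(-22, 22, xy_range = 24,
                                          spacing = 4))
  })
}
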