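#' Forward model for cross-correlated relaxation build-up ratios
#'
#' Intensity ratio of the cross-correlation-filtered experiment as a
#' function of the relaxation delay T for intra-methyl 1H-1H dipolar
#' cross-correlated relaxation rate eta and nuisance cross-relaxation
#' term delta:
#'
#'   ratio(T) = (3/4) eta tanh(s T) / (s - delta tanh(s T)),
#'   s = sqrt(eta^2 + delta^2).
#'
#' With delta = 0 this reduces to (3/4) tanh(eta T).
#'
#' @param T relaxation delay(s), s.
#' @param eta cross-correlated relaxation rate, s^-1.
#' @param delta nuisance cross-relaxation term, s^-1.
#' @return predicted intensity ratios.
#' @export
buildup_ratio <- function(T, eta, delta = 0) {
  if (eta == 0 && delta == 0) return(rep(0, length(T)))
  s <- sqrt(eta^2 + delta^2)
  th <- tanh(s * T)
  0.75 * eta * th / (s - delta * th)
}

#' Fit eta (and delta) to a build-up series
#'
#' Nonlinear least squares of the build-up ratio model to one probe's
#' (delay, ratio) series. The error on eta is obtained by seeded Monte-Carlo
#' resampling of the ratios at their stated errors. With fewer than 4 points
#' delta is fixed at zero to avoid overparameterization.
#'
#' @param series a [buildup_series()].
#' @param fix_delta_zero force the single-parameter (3/4) tanh(eta T) model.
#'   Default `NULL`: fit delta when >= 4 points are available.
#' @param n_mc Monte-Carlo draws for the eta error (0 disables and reports
#'   the asymptotic standard error instead).
#' @param seed seed for the Monte-Carlo resampling.
#' @return list of class `eta_fit` with `eta`, `eta_err`, `delta`,
#'   `residual_rms`, `n_points`, `seed`.
#' @export
fit_eta <- function(series, fix_delta_zero = NULL, n_mc = 200, seed = 1) {
  stopifnot(inherits(series, "buildup_series"))
  if (any(abs(series$ratios) >= 1))
    stop("intensity ratios must lie in (-1, 1)")
  Tt <- series$delays
  if (is.null(fix_delta_zero)) fix_delta_zero <- length(Tt) < 4

  fit_1p <- function(d, eta0) {
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ 0.75 * tanh(eta * Tt), data = d,
      start = list(eta = eta0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    c(eta = unname(stats::coef(fit)["eta"]), delta = 0,
      se = tryCatch(summary(fit)$coefficients["eta", "Std. Error"],
                    error = function(e) NA_real_),
      rms = sqrt(mean(stats::resid(fit)^2)))
  }

  fit_once <- function(y) {
    # slope of ratio ~ (3/4) eta T at the shortest delay seeds the search
    eta0 <- y[1] / (0.75 * Tt[1])
    if (!is.finite(eta0) || eta0 == 0) eta0 <- 1
    d <- data.frame(Tt = Tt, y = y)
    if (fix_delta_zero) return(fit_1p(d, eta0))
    # delta is weakly identified when eta*T is small (its Jacobian column
    # ~ tanh^2): try several starts, then fall back to the delta = 0 model
    for (d0 in c(0, 0.2, -0.2) * max(abs(eta0), 1)) {
      fit <- tryCatch(minpack.lm::nlsLM(
        y ~ 0.75 * eta * tanh(sqrt(eta^2 + delta^2) * Tt) /
          (sqrt(eta^2 + delta^2) - delta * tanh(sqrt(eta^2 + delta^2) * Tt)),
        data = d, start = list(eta = eta0, delta = d0),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
      if (!is.null(fit))
        return(c(eta = unname(stats::coef(fit)["eta"]),
                 delta = unname(stats::coef(fit)["delta"]),
                 se = tryCatch(summary(fit)$coefficients["eta", "Std. Error"],
                               error = function(e) NA_real_),
                 rms = sqrt(mean(stats::resid(fit)^2))))
    }
    fit_1p(d, eta0)
  }

  base <- fit_once(series$ratios)
  if (is.null(base))
    stop("build-up fit did not converge for probe ",
         probe_key(series$probe))

  eta_err <- unname(base["se"])
  if (n_mc > 0 && any(series$ratio_errs > 0)) {
    draws <- withr::with_seed(seed, {
      vapply(seq_len(n_mc), function(i) {
        y <- series$ratios + stats::rnorm(length(Tt), 0, series$ratio_errs)
        y <- pmin(pmax(y, -0.999), 0.999)
        r <- fit_once(y)
        if (is.null(r)) NA_real_ else r["eta"]
      }, numeric(1))
    })
    eta_err <- stats::sd(draws, na.rm = TRUE)
  } else if (all(series$ratio_errs == 0)) {
    eta_err <- 0
  }

  structure(list(eta = unname(base["eta"]), eta_err = eta_err,
                 delta = unname(base["delta"]),
                 residual_rms = unname(base["rms"]),
                 n_points = length(Tt), seed = seed,
                 fix_delta_zero = fix_delta_zero),
            class = "eta_fit")
}

#' Convert a cross-correlated relaxation rate to O2_axis
#'
#' Lipari-Szabo interpretation of the intra-methyl 1H-1H dipolar
#' cross-correlated relaxation rate: eta is proportional to the squared
#' order parameter of the methyl symmetry axis times the tumbling time,
#'
#'   O2_axis = (10/9) eta r_HH^6 /
#'             ( \[P2(cos theta)\]^2 (mu0/4pi)^2 gamma_H^4 hbar^2 tau_m ),
#'
#' with theta the axis/H-H angle (90 degrees for ideal geometry, so the
#' squared Legendre factor is 1/4). The value is returned unclipped; callers
#' should consult the `valid` flag before treating it as a physical
#' order parameter.
#'
#' @param eta cross-correlated relaxation rate, s^-1 (vectorized).
#' @param tau_m tumbling time, s.
#' @param constants a [methyl_constants()] object.
#' @return list with `O2_axis` (unclipped) and `valid` (TRUE when in
#'   \[0, 1\]).
#' @export
eta_to_O2axis <- function(eta, tau_m, constants = methyl_constants()) {
  stopifnot(tau_m > 0)
  o2 <- eta / o2axis_to_eta(1, tau_m, constants)
  list(O2_axis = o2, valid = o2 >= 0 & o2 <= 1)
}

#' Algebraic inverse of [eta_to_O2axis()]
#'
#' @param O2_axis squared axis order parameter (vectorized).
#' @param tau_m tumbling time, s.
#' @param constants a [methyl_constants()] object.
#' @return eta in s^-1.
#' @export
o2axis_to_eta <- function(O2_axis, tau_m, constants = methyl_constants()) {
  stopifnot(tau_m > 0)
  p2sq <- p2_legendre(cos(constants$theta_axis_HH * pi / 180))^2
  O2_axis * 0.9 * p2sq * constants$mu0_over_4pi^2 * constants$gamma_H^4 *
    constants$hbar^2 * tau_m / constants$r_HH_methyl^6
}
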