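#' Lipari-Szabo model-free spectral density
#'
#' Two-parameter ("model-free") spectral density for a bond vector with
#' internal motion of amplitude S2 and effective correlation time tau_e
#' superimposed on isotropic overall tumbling with correlation time tau_m:
#'
#'   J(w) = (2/5) \[ S2 tau_m / (1 + (w tau_m)^2)
#'                 + (1 - S2) tau / (1 + (w tau)^2) \],
#'   1/tau = 1/tau_m + 1/tau_e.
#'
#' With tau_e = 0 the internal term vanishes.
#'
#' @param omega angular frequency, rad s^-1 (vectorized).
#' @param S2 squared generalized order parameter in \[0, 1\].
#' @param tau_m overall tumbling time, s.
#' @param tau_e effective internal correlation time, s (default 0).
#' @return J(omega) in s rad^-1.
#' @export
spectral_density <- function(omega, S2, tau_m, tau_e = 0) {
  stopifnot(S2 >= 0, S2 <= 1, tau_m > 0, tau_e >= 0)
  if (tau_e > 0 && tau_e >= tau_m)
    stop("tau_e must be smaller than tau_m")
  j <- S2 * tau_m / (1 + (omega * tau_m)^2)
  if (tau_e > 0) {
    tau <- 1 / (1 / tau_m + 1 / tau_e)
    j <- j + (1 - S2) * tau / (1 + (omega * tau)^2)
  }
  0.4 * j
}

#' Predict backbone 15N R1 and R2
#'
#' Standard dipolar + CSA expressions for an amide 15N relaxed by the
#' attached proton and its own chemical-shift anisotropy, with
#' d2 = \[(mu0/4pi) hbar gamma_H gamma_N / r_NH^3\]^2 and
#' c2 = (delta_sigma * omega_N)^2 / 3:
#'
#'   R1 = (d2/4)\[J(wH-wN) + 3 J(wN) + 6 J(wH+wN)\] + c2 J(wN)
#'   R2 = (d2/8)\[4 J(0) + J(wH-wN) + 3 J(wN) + 6 J(wH) + 6 J(wH+wN)\]
#'        + (c2/6)\[4 J(0) + 3 J(wN)\] + R_ex
#'
#' @param S2,tau_m,tau_e model-free parameters (s for times).
#' @param R_ex chemical-exchange contribution to R2, s^-1.
#' @param field_MHz 1H Larmor frequency, MHz.
#' @param constants a [methyl_constants()] object.
#' @return list with `R1` and `R2` in s^-1.
#' @export
predict_n15_rates <- function(S2, tau_m, tau_e = 0, R_ex = 0, field_MHz,
                              constants = methyl_constants()) {
  stopifnot(field_MHz > 0, R_ex >= 0)
  wH <- 2 * pi * field_MHz * 1e6
  wN <- wH * constants$gamma_N / constants$gamma_H
  d2 <- (constants$mu0_over_4pi * constants$hbar * constants$gamma_H *
           constants$gamma_N / constants$r_NH^3)^2
  c2 <- (constants$delta_sigma_N * 1e-6 * wN)^2 / 3
  Jf <- function(w) spectral_density(abs(w), S2, tau_m, tau_e)
  R1 <- d2 / 4 * (Jf(wH - wN) + 3 * Jf(wN) + 6 * Jf(wH + wN)) + c2 * Jf(wN)
  R2 <- d2 / 8 * (4 * Jf(0) + Jf(wH - wN) + 3 * Jf(wN) + 6 * Jf(wH) +
                    6 * Jf(wH + wN)) +
    c2 / 6 * (4 * Jf(0) + 3 * Jf(wN)) + R_ex
  list(R1 = R1, R2 = R2)
}

#' Estimate the global tumbling time from R2/R1 ratios
#'
#' Under the rigid (tau_e = 0, R_ex = 0) model the R2/R1 ratio is
#' independent of S2 and a monotone function of tau_m, so each residue
#' yields a tau_m by a one-dimensional root solve. Residues suspected of
#' chemical exchange (elevated R1*R2 product, see
#' [r1r2_exchange_screen()]) and mobile tails (R2/R1 below the 10th
#' percentile) are trimmed before averaging when `trim = TRUE`.
#'
#' @param records a `relaxation_records` table (>= 5 usable rows).
#' @param constants a [methyl_constants()] object.
#' @param trim drop exchange-flagged residues and low-ratio mobile tails.
#' @param k MAD multiplier passed to the exchange screen.
#' @param bracket_ns search bracket for the per-residue root solve, ns.
#' @return list of class `tumbling_estimate` with `tau_m_ns`,
#'   `tau_m_err_ns` (standard deviation over retained residues),
#'   `n_residues_used`, `method` and the per-residue solutions.
#' @export
estimate_tau_m <- function(records, constants = methyl_constants(),
                           trim = TRUE, k = 3,
                           bracket_ns = c(0.5, 200)) {
  df <- as.data.frame(records)
  if (nrow(df) < 5) stop("need at least 5 relaxation records, have ",
                         nrow(df))
  keep <- rep(TRUE, nrow(df))
  if (trim) {
    flags <- r1r2_exchange_screen(records, k = k, iterate = TRUE)$flag
    ratio <- df$R2 / df$R1
    keep <- !flags & ratio >= stats::quantile(ratio, 0.10)
  }
  use <- df[keep, , drop = FALSE]
  if (nrow(use) < 5) stop("fewer than 5 usable records after trimming")
  per_res <- rep(NA_real_, nrow(use))
  for (i in seq_len(nrow(use))) {
    target <- use$R2[i] / use$R1[i]
    f <- function(tm_ns) {
      r <- predict_n15_rates(S2 = 1, tau_m = tm_ns * 1e-9,
                             field_MHz = use$field_MHz[i],
                             constants = constants)
      r$R2 / r$R1 - target
    }
    lo <- f(bracket_ns[1]); hi <- f(bracket_ns[2])
    if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0) {
      warning("no tau_m root in bracket for residue ",
              use$residue_number[i], "; excluded")
      next
    }
    per_res[i] <- stats::uniroot(f, bracket_ns, tol = 1e-8)$root
  }
  ok <- is.finite(per_res)
  if (sum(ok) < 5) stop("fewer than 5 residues yielded a tau_m solution")
  est <- structure(list(tau_m_ns = mean(per_res[ok]),
                        tau_m_err_ns = stats::sd(per_res[ok]),
                        n_residues_used = sum(ok),
                        method = "R2/R1 ratio, rigid model-free",
                        per_residue_tau_m_ns = per_res[ok],
                        residue_number = use$residue_number[ok]),
                   class = "tumbling_estimate")
  est
}

#' @export
print.tumbling_estimate <- function(x, ...) {
  cat(sprintf("tau_m = %.2f +/- %.2f ns (%d residues; %s)\n",
              x$tau_m_ns, x$tau_m_err_ns, x$n_residues_used, x$method))
  invisible(x)
}

#' R1*R2 screen for slow-timescale chemical exchange
#'
#' The R1*R2 product is nearly independent of the global tumbling time for
#' rigid residues, so exchange broadening (R_ex) stands out as an elevated
#' product. Residues with product strictly above median + k * MAD are
#' flagged as exchange-suspect; with zero spread nothing is flagged.
#'
#' When `iterate = TRUE` the screen is reapplied with the median and MAD
#' recomputed over the unflagged residues until the flag set stabilizes;
#' this stops heavily exchange-broadened residues from inflating the MAD
#' and masking one another, at the cost of a slightly higher false-flag
#' rate on clean data.
#'
#' @param records a `relaxation_records` table (>= 5 rows).
#' @param k MAD multiplier (default 3).
#' @param iterate recompute the threshold over unflagged residues until
#'   convergence (default FALSE = single pass).
#' @return data.frame with `residue_number`, `r1r2`, `flag`.
#' @export
r1r2_exchange_screen <- function(records, k = 3, iterate = FALSE) {
  df <- as.data.frame(records)
  if (nrow(df) < 5) stop("need at least 5 records")
  prod <- df$R1 * df$R2
  flag <- rep(FALSE, length(prod))
  for (i in seq_len(if (iterate) 10L else 1L)) {
    med <- stats::median(prod[!flag])
    madv <- stats::mad(prod[!flag], constant = 1)
    new_flag <- prod > med + k * madv
    if (identical(new_flag, flag)) break
    flag <- new_flag
  }
  data.frame(residue_number = df$residue_number, r1r2 = prod, flag = flag)
}
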