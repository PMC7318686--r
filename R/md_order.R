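#' Bond-vector trajectories
#'
#' A time-ordered series of unit bond vectors in the molecular frame
#' (overall tumbling already removed), e.g. the methyl symmetry axis of an
#' ILV residue or the Ne-He vector of an arginine. Vectors are normalized
#' on construction; a deviation from unit norm above 1e-3 triggers a
#' warning, above ~30% an error.
#'
#' @param vectors n x 3 matrix of bond vectors, one frame per row (n >= 2).
#' @param dt time step, ps.
#' @param label probe or bond-convention label (e.g. "ILE13 axis",
#'   "ARG72 Ne-He").
#' @return list of class `vector_trajectory`.
#' @export
vector_trajectory <- function(vectors, dt = 1, label = "") {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 3) stop("vectors must be an n x 3 matrix")
  if (nrow(vectors) < 2) stop("need at least 2 frames")
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0) || any(abs(norms - 1) > 0.3))
    stop("input vectors deviate grossly from unit norm")
  if (any(abs(norms - 1) > 1e-3))
    warning("vectors deviate from unit norm by more than 1e-3; renormalized")
  structure(list(vectors = vectors / norms, dt = dt, label = label),
            class = "vector_trajectory")
}

#' Read a bond-vector trajectory from a TSV of (t, x, y, z) rows
#'
#' @param path file path; columns `t`, `x`, `y`, `z`.
#' @param label probe label.
#' @return a `vector_trajectory` (dt from the first time difference).
#' @export
read_vector_trajectory <- function(path, label = "") {
  df <- utils::read.delim(path, comment.char = "#")
  missing <- setdiff(c("t", "x", "y", "z"), names(df))
  if (length(missing))
    stop("trajectory table lacks column(s): ", paste(missing, collapse = ", "))
  vector_trajectory(cbind(df$x, df$y, df$z),
                    dt = if (nrow(df) > 1) df$t[2] - df$t[1] else 1,
                    label = label)
}

#' Order parameter from the ensemble-average formula
#'
#' The isotropic-ensemble order parameter of a unit bond vector e,
#'
#'   O2 = (3/2) sum_\{i<=j\} w_ij <e_i e_j>^2 - 1/2,
#'
#' with weights 1 on the diagonal and 2 off-diagonal and averages taken
#' over frames. Equals 1 for a fixed vector and 0 in expectation for
#' isotropic disorder; finite-sample values can dip slightly below 0.
#'
#' @param traj a `vector_trajectory`.
#' @return O2, dimensionless.
#' @export
order_parameter_iso <- function(traj) {
  stopifnot(inherits(traj, "vector_trajectory"))
  v <- traj$vectors
  mxx <- mean(v[, 1]^2); myy <- mean(v[, 2]^2); mzz <- mean(v[, 3]^2)
  mxy <- mean(v[, 1] * v[, 2])
  mxz <- mean(v[, 1] * v[, 3])
  myz <- mean(v[, 2] * v[, 3])
  1.5 * (mxx^2 + myy^2 + mzz^2 + 2 * (mxy^2 + mxz^2 + myz^2)) - 0.5
}

#' P2 autocorrelation function of a bond vector
#'
#' C(t) = < P2( e(tau) . e(tau + t) ) > over time origins tau, with
#' P2(x) = (3 x^2 - 1)/2. C(0) = 1 identically; for internal motion that
#' is stationary the long-time plateau equals the order parameter.
#'
#' @param traj a `vector_trajectory`.
#' @param max_lag maximum lag in frames (< half the trajectory length).
#' @param lag_step compute every `lag_step`-th lag (default 1).
#' @param origin_stride subsample time origins for speed (default 1 = all).
#' @return data.frame with `lag` (frames), `t` (ps) and `C`.
#' @export
p2_autocorrelation <- function(traj, max_lag, lag_step = 1,
                               origin_stride = 1) {
  stopifnot(inherits(traj, "vector_trajectory"))
  v <- traj$vectors
  n <- nrow(v)
  if (max_lag >= n / 2) stop("max_lag must be below half the trajectory length")
  lags <- seq(0, max_lag, by = lag_step)
  C <- vapply(lags, function(lag) {
    if (lag == 0) return(1)
    idx <- seq(1, n - lag, by = origin_stride)
    dots <- rowSums(v[idx, , drop = FALSE] * v[idx + lag, , drop = FALSE])
    mean(p2_legendre(dots))
  }, numeric(1))
  data.frame(lag = lags, t = lags * traj$dt, C = C)
}

#' Plateau of a correlation function
#'
#' Mean of C(t) over the tail of the computed lags; used as the
#' long-time-limit estimate of the order parameter from
#' [p2_autocorrelation()]. Reliable only when the internal decay time is
#' much shorter than the start of the window.
#'
#' @param C data.frame from [p2_autocorrelation()] (or any with columns
#'   `lag`, `C`).
#' @param window_frac fraction of the final lags to average (default 0.25).
#' @return plateau value.
#' @export
plateau_estimate <- function(C, window_frac = 0.25) {
  stopifnot(window_frac > 0, window_frac <= 1)
  n <- nrow(C)
  start <- floor(n * (1 - window_frac)) + 1
  if (start > n) stop("plateau window is empty")
  mean(C$C[start:n])
}
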