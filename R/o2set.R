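#' Order-parameter sets
#'
#' An order-parameter set holds per-methyl squared generalized order
#' parameters of the methyl symmetry axis (O2_axis) with their errors, the
#' sample temperature and the membrane-mimetic environment, plus the global
#' tumbling time used in the eta -> O2_axis conversion. Values are stored
#' unclipped (slightly negative or >1 values can arise from noise) so that
#' downstream steps can apply their own validity policy.
#'
#' @param probes a `methyl_probes` table (or data frame with probe columns).
#' @param O2_axis numeric vector of O2_axis values (unclipped).
#' @param error numeric vector of per-probe errors, >= 0.
#' @param temperature_K sample temperature(s), kelvin (recycled).
#' @param environment one of "micelle", "bicelle", "md" (recycled).
#' @param tau_m_ns tumbling time used in the conversion, ns (scalar, NA if
#'   not applicable).
#'
#' @return data.frame of class `o2_set` with attribute `tau_m_ns`.
#' @export
o2_set <- function(probes, O2_axis, error, temperature_K,
                   environment = c("micelle", "bicelle", "md"),
                   tau_m_ns = NA_real_) {
  probes <- as.data.frame(probes)
  validate_probes(probes)
  n <- nrow(probes)
  environment <- match.arg(environment, several.ok = TRUE)
  df <- data.frame(probes[c("chain", "residue_number", "residue_type",
                            "methyl_id")],
                   O2_axis = as.numeric(O2_axis),
                   error = as.numeric(error),
                   temperature_K = rep_len(as.numeric(temperature_K), n),
                   environment = rep_len(environment, n),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$O2_axis)) || any(!is.finite(df$error)))
    stop("O2_axis and error must be finite")
  if (any(df$error < 0)) stop("errors must be >= 0")
  key <- paste(probe_key(df), df$environment, df$temperature_K)
  if (anyDuplicated(key))
    stop("duplicate (probe, environment, temperature) entries")
  attr(df, "tau_m_ns") <- tau_m_ns
  class(df) <- c("o2_set", "data.frame")
  df
}

#' @export
print.o2_set <- function(x, ...) {
  cat(sprintf("O2_axis set: %d probes, environment(s) %s, tau_m = %s ns\n",
              nrow(x), paste(unique(x$environment), collapse = "/"),
              format(attr(x, "tau_m_ns"))))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Ensemble summary of an order-parameter set
#'
#' Unweighted mean O2_axis and mean reported error over all entries; the
#' quantities quoted as "average order parameter" and "average precision"
#' for a protein.
#'
#' @param set an `o2_set`.
#' @return list with `mean_O2`, `mean_error`, `n`.
#' @export
summarize_set <- function(set) {
  if (nrow(set) == 0) stop("cannot summarize an empty set")
  list(mean_O2 = mean(set$O2_axis), mean_error = mean(set$error),
       n = nrow(set))
}

#' Temperature dependence of methyl order parameters
#'
#' Pairs probes by identity across two sets measured at different
#' temperatures and reports the mean per-probe change and the implied
#' temperature coefficient dO2/dT. Side chains rigidify on cooling, so the
#' mean change low-minus-high is typically positive and the slope negative.
#'
#' @param set_T1,set_T2 `o2_set` objects at two distinct temperatures.
#' @return list with `mean_delta` (mean O2(T_low) - O2(T_high)),
#'   `slope` (dO2/dT, K^-1), `n_paired`, and the two temperatures.
#' @export
temperature_slope <- function(set_T1, set_T2) {
  t1 <- unique(set_T1$temperature_K); t2 <- unique(set_T2$temperature_K)
  if (length(t1) != 1 || length(t2) != 1)
    stop("each set must be at a single temperature")
  if (t1 == t2) stop("sets must be at different temperatures")
  lo <- if (t1 < t2) set_T1 else set_T2
  hi <- if (t1 < t2) set_T2 else set_T1
  m <- match(probe_key(lo), probe_key(hi))
  paired <- which(!is.na(m))
  if (!length(paired)) stop("no probes shared between the two sets")
  delta <- lo$O2_axis[paired] - hi$O2_axis[m[paired]]
  T_lo <- min(t1, t2); T_hi <- max(t1, t2)
  mean_delta <- mean(delta)
  list(mean_delta = mean_delta,
       slope = -mean_delta / (T_hi - T_lo),
       n_paired = length(paired),
       T_low_K = T_lo, T_high_K = T_hi)
}

#' Compare order parameters between membrane mimetics
#'
#' Ordinary least squares of set_b values on set_a values over probes present
#' in both sets, with the squared Pearson correlation. Used to ask whether
#' fast side-chain dynamics depend on the micelle vs bicelle environment.
#'
#' @param set_a,set_b `o2_set` objects sharing >= 3 probes.
#' @return list with `R2`, `slope`, `intercept`, `n_paired`.
#' @export
compare_environments <- function(set_a, set_b) {
  m <- match(probe_key(set_a), probe_key(set_b))
  paired <- which(!is.na(m))
  if (length(paired) < 3)
    stop("need at least 3 paired probes, have ", length(paired))
  x <- set_a$O2_axis[paired]
  y <- set_b$O2_axis[m[paired]]
  fit <- stats::lm(y ~ x)
  list(R2 = stats::cor(x, y)^2,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_paired = length(paired))
}
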