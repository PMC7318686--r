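#' Conformational entropy from the diffusion-in-a-cone model
#'
#' Maps a methyl symmetry-axis order parameter to the configurational
#' entropy of a bond vector diffusing freely in a cone. Writing
#' O_axis = sqrt(O2_axis), the cone model gives
#'
#'   S / k_B = ln\[ pi (3 - sqrt(1 + 8 O_axis)) \].
#'
#' At O2_axis = 0 (isotropic disorder) this is ln(2 pi); it decreases
#' strictly with increasing order and diverges to -infinity as
#' O2_axis -> 1, which is why rigid entries must be excluded rather than
#' clipped. The mapping is an interpretation layer: it turns measured order
#' parameters into a residual-entropy scale but is one defensible
#' calibration among several.
#'
#' @param O2_axis squared axis order parameter(s) in \[0, 1).
#' @return data.frame with `S_kB` (multiples of k_B) and `S_J_mol_K`
#'   (via the gas constant, J mol^-1 K^-1).
#' @export
cone_entropy <- function(O2_axis) {
  if (any(O2_axis < 0)) stop("O2_axis must be >= 0")
  if (any(O2_axis >= 1))
    stop("cone entropy diverges for O2_axis >= 1; exclude such entries")
  o <- sqrt(O2_axis)
  s_kb <- log(pi * (3 - sqrt(1 + 8 * o)))
  R_gas <- 8.31446261815324
  data.frame(S_kB = s_kb, S_J_mol_K = s_kb * R_gas)
}

#' Residual conformational entropy of an order-parameter set
#'
#' Applies [cone_entropy()] per probe and aggregates. Entries with
#' O2_axis >= 1 or < 0 are skipped with a warning (the cone mapping is
#' undefined or divergent there).
#'
#' @param set an `o2_set`.
#' @return list of class `entropy_estimate` with `per_probe` (data frame of
#'   probe columns + S_kB + S_J_mol_K), `total_kB`, `mean_kB`,
#'   `total_J_mol_K`, `n_probes`, `n_skipped`.
#' @export
ensemble_entropy <- function(set) {
  if (nrow(set) == 0) stop("empty order-parameter set")
  ok <- set$O2_axis >= 0 & set$O2_axis < 1
  if (any(!ok))
    warning(sum(!ok), " entries outside [0, 1) skipped for entropy")
  if (!any(ok)) stop("no entries with O2_axis in [0, 1)")
  kept <- set[ok, , drop = FALSE]
  s <- cone_entropy(kept$O2_axis)
  per <- cbind(as.data.frame(kept)[c("chain", "residue_number",
                                     "residue_type", "methyl_id",
                                     "O2_axis")], s)
  structure(list(per_probe = per, total_kB = sum(s$S_kB),
                 mean_kB = mean(s$S_kB),
                 total_J_mol_K = sum(s$S_J_mol_K),
                 n_probes = nrow(per), n_skipped = sum(!ok)),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("Residual conformational entropy: %d probes, total %.2f k_B (mean %.3f k_B)\n",
              x$n_probes, x$total_kB, x$mean_kB))
  if (x$n_skipped) cat(sprintf("  (%d entries skipped)\n", x$n_skipped))
  invisible(x)
}

#' Entropy change between two states
#'
#' Per-probe cone-model entropy difference S(b) - S(a) over probes shared
#' between the two sets, e.g. two temperatures or two ligation states.
#'
#' @param set_a,set_b `o2_set` objects sharing >= 1 probe with O2_axis in
#'   \[0, 1).
#' @return list with `per_probe` (probe columns + dS_kB) and `total_kB`.
#' @export
delta_entropy <- function(set_a, set_b) {
  ok_a <- set_a$O2_axis >= 0 & set_a$O2_axis < 1
  ok_b <- set_b$O2_axis >= 0 & set_b$O2_axis < 1
  a <- set_a[ok_a, , drop = FALSE]
  b <- set_b[ok_b, , drop = FALSE]
  m <- match(probe_key(a), probe_key(b))
  paired <- which(!is.na(m))
  if (!length(paired)) stop("no probes shared between the two sets")
  s_a <- cone_entropy(a$O2_axis[paired])$S_kB
  s_b <- cone_entropy(b$O2_axis[m[paired]])$S_kB
  per <- cbind(as.data.frame(a)[paired, c("chain", "residue_number",
                                          "residue_type", "methyl_id")],
               dS_kB = s_b - s_a)
  rownames(per) <- NULL
  list(per_probe = per, total_kB = sum(per$dS_kB),
       n_paired = length(paired))
}
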