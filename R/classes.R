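#' Filter an order-parameter set by error
#'
#' Retains entries whose reported error is less than or equal to
#' `max_error` (boundary inclusive); order is preserved. The same filter the
#' motional-class histograms use, so class statistics are not distorted by
#' poorly determined probes.
#'
#' @param set an `o2_set`.
#' @param max_error maximum allowed error (default 0.1).
#' @return the filtered `o2_set`, with attribute `n_removed`.
#' @export
filter_by_error <- function(set, max_error = 0.1) {
  keep <- set$error <= max_error
  out <- set[keep, , drop = FALSE]
  attr(out, "tau_m_ns") <- attr(set, "tau_m_ns")
  attr(out, "n_removed") <- sum(!keep)
  class(out) <- class(set)
  out
}

#' Select the number of motional classes
#'
#' Fits one-dimensional Gaussian mixtures with k = 1..max(k_candidates)
#' components (unequal variances, EM) and scores each k by the Bayesian
#' information criterion, BIC = -2 log L + df log n (smaller is better).
#' When two candidate counts score within `tie_margin` of the minimum, the
#' larger count is preferred: with near-equal evidence the finer taxonomy is
#' retained so that classes matching those known from soluble proteins can
#' be identified.
#'
#' @param values numeric vector of O2_axis values (>= 10).
#' @param k_candidates candidate class counts (default 1:5).
#' @param tie_margin BIC units within which a larger k wins (default 2).
#' @param seed seed for the EM initialization.
#' @return list with `k_best` and `selection_scores` (named BIC per k;
#'   non-convergent candidates score +Inf).
#' @export
select_class_count <- function(values, k_candidates = 1:5, tie_margin = 2,
                               seed = 1) {
  if (length(values) < 10) stop("need at least 10 values")
  # Mclust() looks up mclustBIC() in the calling frame, so bind it locally
  mclustBIC <- mclust::mclustBIC
  scores <- withr::with_seed(seed, {
    vapply(k_candidates, function(k) {
      fit <- tryCatch(
        suppressWarnings(mclust::Mclust(values, G = k, modelNames = "V",
                                        verbose = FALSE)),
        error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$bic)) {
        warning("mixture fit did not converge for k = ", k)
        return(Inf)
      }
      # mclust reports BIC as 2 logL - df log n; convert to the
      # smaller-is-better convention
      -fit$bic
    }, numeric(1))
  })
  names(scores) <- k_candidates
  finite <- which(is.finite(scores))
  if (!length(finite)) stop("no mixture fit converged")
  best <- min(scores[finite])
  in_tie <- finite[scores[finite] <= best + tie_margin]
  k_best <- max(k_candidates[in_tie])
  list(k_best = k_best, selection_scores = scores)
}

#' k-means decomposition of an order-parameter distribution
#'
#' One-dimensional k-means (multiple random restarts, best inertia kept)
#' on the O2_axis values; class boundaries are midpoints between adjacent
#' sorted centers, and classes are named low-to-high from the motional
#' taxonomy \{J', J, alpha, omega\}: J' for extensive multi-torsion
#' rotameric sampling (centered near 0.21 in membrane proteins), J for
#' two-state rotamer interconversion, alpha for large intra-rotamer
#' excursions with occasional jumps, omega for motion restricted to a
#' single rotamer. With k = 3 the rule depends on whether a rigid band is
#' present: all centers < 0.75 gives (J', J, alpha) -- the omega class is
#' taken as absent -- otherwise (J, alpha, omega). With k = 2 the taxonomy
#' is ambiguous and generic labels are used with a warning.
#'
#' Values outside \[0, 1\] are clipped into \[0, 1\] for the clustering
#' only and flagged.
#'
#' @param values numeric vector of O2_axis values.
#' @param k number of classes (must not exceed the number of distinct
#'   values).
#' @param nstart k-means restarts (default 50).
#' @param seed seed making the restarts reproducible.
#' @return list of class `class_model` with `k`, `centers` (ascending),
#'   `boundaries`, `labels`, `assignments` (per-value class label),
#'   `sizes`, `clipped` (logical per value).
#' @export
kmeans_classes <- function(values, k, nstart = 50, seed = 1) {
  vals <- as.numeric(values)
  if (k > length(unique(vals)))
    stop("k exceeds the number of distinct values")
  clipped <- vals < 0 | vals > 1
  work <- pmin(pmax(vals, 0), 1)
  km <- withr::with_seed(seed, {
    stats::kmeans(matrix(work, ncol = 1), centers = k, nstart = nstart,
                  iter.max = 100)
  })
  ord <- order(km$centers[, 1])
  centers <- km$centers[ord, 1]
  rank_of <- match(seq_len(k), ord)
  cls <- rank_of[km$cluster]
  boundaries <- if (k > 1) (centers[-1] + centers[-k]) / 2 else numeric(0)
  labels <- class_labels(centers)
  structure(list(k = k, centers = unname(centers),
                 boundaries = unname(boundaries), labels = labels,
                 assignments = labels[cls], sizes = tabulate(cls, k),
                 clipped = clipped),
            class = "class_model")
}

class_labels <- function(centers) {
  k <- length(centers)
  if (k == 1) return("single")
  if (k == 2) {
    warning("two classes: motional taxonomy is ambiguous, using generic labels")
    return(c("J-like", "alpha-like"))
  }
  if (k == 3) {
    if (all(centers < 0.75)) c("Jprime", "J", "alpha")
    else c("J", "alpha", "omega")
  } else if (k == 4) {
    c("Jprime", "J", "alpha", "omega")
  } else {
    paste0("class", seq_len(k))
  }
}

#' @export
print.class_model <- function(x, ...) {
  cat(sprintf("Motional class model: k = %d\n", x$k))
  for (i in seq_len(x$k))
    cat(sprintf("  %-7s center %.3f  n = %d\n", x$labels[i], x$centers[i],
                x$sizes[i]))
  if (length(x$boundaries))
    cat("  boundaries:", paste(sprintf("%.3f", x$boundaries),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Residue-type composition of motional classes
#'
#' For each class, the fraction of probes that are methionine, leucine or
#' isoleucine (two or more sampleable torsion angles; grouped as "MLI")
#' versus valine (one non-terminal torsion; "V"), compared with the same
#' fractions over all probes. Enrichment is the class fraction minus the
#' overall fraction: a positive MLI enrichment in the most dynamic class
#' indicates that extensive multi-torsion sampling drives the lowest order
#' parameters.
#'
#' @param model a `class_model`.
#' @param probes a probe table aligned row-wise with the values the model
#'   was fitted to.
#' @return data.frame with one row per class plus an "overall" row:
#'   `class`, `n`, `frac_MLI`, `frac_V`, `enrich_MLI`, `enrich_V`. Empty
#'   classes are reported with NA fractions.
#' @export
class_composition <- function(model, probes) {
  stopifnot(inherits(model, "class_model"))
  probes <- as.data.frame(probes)
  if (nrow(probes) != length(model$assignments))
    stop("probes and class assignments differ in length")
  grp <- ifelse(probes$residue_type %in% c("MET", "LEU", "ILE"), "MLI", "V")
  overall_mli <- mean(grp == "MLI")
  rows <- lapply(model$labels, function(lab) {
    in_cls <- model$assignments == lab
    if (!any(in_cls))
      return(data.frame(class = lab, n = 0L, frac_MLI = NA_real_,
                        frac_V = NA_real_, enrich_MLI = NA_real_,
                        enrich_V = NA_real_))
    f_mli <- mean(grp[in_cls] == "MLI")
    data.frame(class = lab, n = sum(in_cls), frac_MLI = f_mli,
               frac_V = 1 - f_mli, enrich_MLI = f_mli - overall_mli,
               enrich_V = (1 - f_mli) - (1 - overall_mli))
  })
  out <- do.call(rbind, rows)
  rbind(out,
        data.frame(class = "overall", n = nrow(probes),
                   frac_MLI = overall_mli, frac_V = 1 - overall_mli,
                   enrich_MLI = 0, enrich_V = 0))
}
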