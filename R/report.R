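#' End-to-end summary report over order-parameter tables
#'
#' Aggregates one or more order-parameter sets into the summary statistics
#' used to characterize fast side-chain dynamics of a protein: per-set
#' ensemble mean and precision, the error-filtered motional-class model and
#' residue-type composition, the temperature coefficient when two
#' temperatures are present, the micelle/bicelle correlation when two
#' environments are present, and residual-entropy totals.
#'
#' @param sets named list of `o2_set` objects (e.g. list(micelle_323 = ...)).
#' @param max_error error filter for the class analysis (default 0.1).
#' @param k number of motional classes; `NULL` selects it by BIC on the
#'   first filtered set.
#' @param seed seed for clustering and model selection.
#' @return list of class `methyldyn_report`; see Details for fields.
#' @details Fields: `per_set` (summary + class model + composition per
#'   input set), `temperature` (slope, when two temperatures share an
#'   environment), `environment` (R2/slope, when two environments share a
#'   temperature), `entropy` (per-set totals), `options`.
#' @export
run_report <- function(sets, max_error = 0.1, k = NULL, seed = 1) {
  if (!length(sets)) stop("need at least one order-parameter set")
  if (is.null(names(sets)))
    names(sets) <- paste0("set", seq_along(sets))
  per_set <- list()
  for (nm in names(sets)) {
    set <- sets[[nm]]
    filt <- filter_by_error(set, max_error)
    summ <- summarize_set(set)
    entry <- list(n = summ$n, mean_O2 = summ$mean_O2,
                  mean_error = summ$mean_error,
                  n_filtered = nrow(filt),
                  n_removed = attr(filt, "n_removed"))
    if (nrow(filt) >= 10) {
      kk <- k
      if (is.null(kk))
        kk <- select_class_count(filt$O2_axis, seed = seed)$k_best
      model <- kmeans_classes(filt$O2_axis, kk, seed = seed)
      entry$class_model <- model
      entry$composition <- class_composition(model, filt)
      entry$mean_O2_filtered <- mean(filt$O2_axis)
      entry$mean_error_filtered <- mean(filt$error)
    }
    ent <- tryCatch(ensemble_entropy(set), error = function(e) NULL)
    if (!is.null(ent))
      entry$entropy <- list(total_kB = ent$total_kB, mean_kB = ent$mean_kB,
                            n = ent$n_probes)
    per_set[[nm]] <- entry
  }
  report <- list(per_set = per_set,
                 options = list(max_error = max_error, k = k, seed = seed))

  temps <- vapply(sets, function(s) unique(s$temperature_K)[1], numeric(1))
  envs <- vapply(sets, function(s) unique(s$environment)[1], character(1))
  # temperature pair: same environment, two temperatures
  for (env in unique(envs)) {
    idx <- which(envs == env)
    if (length(idx) == 2 && temps[idx[1]] != temps[idx[2]]) {
      report$temperature <- c(
        list(environment = env, sets = names(sets)[idx]),
        temperature_slope(sets[[idx[1]]], sets[[idx[2]]]))
      break
    }
  }
  # environment pair: same temperature, two environments
  for (tt in unique(temps)) {
    idx <- which(temps == tt)
    if (length(idx) == 2 && envs[idx[1]] != envs[idx[2]]) {
      cmp <- tryCatch(compare_environments(sets[[idx[1]]], sets[[idx[2]]]),
                      error = function(e) NULL)
      if (!is.null(cmp))
        report$environment <- c(list(sets = names(sets)[idx]), cmp)
      break
    }
  }
  class(report) <- "methyldyn_report"
  report
}

#' @export
print.methyldyn_report <- function(x, ...) {
  for (nm in names(x$per_set)) {
    e <- x$per_set[[nm]]
    cat(sprintf("[%s] n = %d, <O2_axis> = %.3f, <err> = %.3f (filtered: %d kept, %d removed)\n",
                nm, e$n, e$mean_O2, e$mean_error, e$n_filtered,
                e$n_removed))
    if (!is.null(e$class_model)) {
      cat("  classes: ")
      cat(paste(sprintf("%s %.3f (n=%d)", e$class_model$labels,
                        e$class_model$centers, e$class_model$sizes),
                collapse = ", "), "\n")
    }
    if (!is.null(e$entropy))
      cat(sprintf("  entropy: total %.1f k_B over %d probes\n",
                  e$entropy$total_kB, e$entropy$n))
  }
  if (!is.null(x$temperature))
    cat(sprintf("Temperature: mean dO2 (low-high) = %+.3f, dO2/dT = %.4g K^-1 (%d pairs)\n",
                x$temperature$mean_delta, x$temperature$slope,
                x$temperature$n_paired))
  if (!is.null(x$environment))
    cat(sprintf("Environments: R2 = %.3f, slope = %.3f (%d pairs)\n",
                x$environment$R2, x$environment$slope,
                x$environment$n_paired))
  invisible(x)
}

#' Serialize a report to JSON
#'
#' @param report a `methyldyn_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "class_model"))
      x <- list(k = x$k, centers = x$centers, boundaries = x$boundaries,
                labels = x$labels, sizes = x$sizes)
    if (is.list(x)) lapply(x, strip) else x
  }
  jsonlite::write_json(strip(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}
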