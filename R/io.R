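#' Read a backbone relaxation table
#'
#' Reads a TSV of per-residue 15N R1/R2 rates with errors. Files are UTF-8,
#' one header row, `#` comment lines allowed. Column names can be remapped
#' through `dialect`, a named character vector `c(internal = "file header")`,
#' so tables exported by other tools need not be rewritten.
#'
#' @param path file path.
#' @param dialect optional named character vector mapping the internal column
#'   names (`residue_number`, `R1`, `R1_err`, `R2`, `R2_err`, `field_MHz`,
#'   `temperature_K`) to the headers used in the file.
#' @return data.frame of class `relaxation_records` with one row per residue.
#'   Malformed rows abort with an error naming the offending line.
#' @export
read_relaxation_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  needed <- c("residue_number", "R1", "R1_err", "R2", "R2_err",
              "field_MHz", "temperature_K")
  if (!is.null(dialect)) {
    for (internal in names(dialect)) {
      j <- match(dialect[[internal]], names(df))
      if (!is.na(j)) names(df)[j] <- internal
    }
  }
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("relaxation table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) {
    warning("relaxation table is empty: ", path)
    return(relaxation_records(df[needed]))
  }
  for (col in needed) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric %s at data line(s) %s in %s (value '%s')",
                   col, paste(bad, collapse = ", "), path, df[[col]][bad[1]]))
    df[[col]] <- v
  }
  relaxation_records(df[needed])
}

#' Construct a validated table of relaxation records
#'
#' @param df data frame with columns residue_number, R1, R1_err, R2, R2_err,
#'   field_MHz, temperature_K.
#' @return the validated data frame, classed `relaxation_records`.
#' @export
relaxation_records <- function(df) {
  if (nrow(df)) {
    if (any(df$R1 <= 0) || any(df$R2 <= 0))
      stop("relaxation rates must be positive")
    if (any(df$R1_err < 0) || any(df$R2_err < 0))
      stop("rate errors must be >= 0")
    if (any(!is.finite(df$R1)) || any(!is.finite(df$R2)))
      stop("rates must be finite")
  }
  df$residue_number <- as.integer(df$residue_number)
  class(df) <- c("relaxation_records", "data.frame")
  df
}

#' Write a backbone relaxation table
#'
#' @param records a `relaxation_records` table.
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
write_relaxation_table <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# fixed column order shared by the order-parameter TSV reader/writer
.o2_cols <- c("chain", "residue_number", "residue_type", "methyl_id",
              "O2_axis", "error", "temperature_K", "environment", "tau_m_ns")

#' Write an order-parameter table
#'
#' TSV with a fixed column order (chain, residue_number, residue_type,
#' methyl_id, O2_axis, error, temperature_K, environment, tau_m_ns); reading
#' it back with [read_order_parameter_table()] reproduces the set exactly at
#' full printed precision.
#'
#' @param set an `o2_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_order_parameter_table <- function(set, path) {
  stopifnot(inherits(set, "o2_set"))
  out <- as.data.frame(set)
  out$tau_m_ns <- rep_len(attr(set, "tau_m_ns"), max(nrow(out), 0L))
  out <- out[.o2_cols[.o2_cols %in% names(out)]]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(.o2_cols, collapse = "\t"), con)
  if (nrow(out)) {
    fmt <- vapply(seq_len(nrow(out)), function(i) {
      paste(c(out$chain[i], out$residue_number[i], out$residue_type[i],
              out$methyl_id[i],
              format(out$O2_axis[i], digits = 17),
              format(out$error[i], digits = 17),
              format(out$temperature_K[i], digits = 17),
              out$environment[i],
              format(out$tau_m_ns[i], digits = 17)), collapse = "\t")
    }, character(1))
    writeLines(fmt, con)
  }
  invisible(path)
}

#' Read an order-parameter table written by [write_order_parameter_table()]
#'
#' @param path file path.
#' @return an `o2_set`.
#' @export
read_order_parameter_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(.o2_cols, names(df))
  if (length(missing))
    stop("order-parameter table lacks column(s): ",
         paste(missing, collapse = ", "))
  tau <- if (nrow(df)) unique(df$tau_m_ns) else NA_real_
  if (length(tau) > 1) tau <- tau[1]
  o2_set(df[c("chain", "residue_number", "residue_type", "methyl_id")],
         O2_axis = df$O2_axis, error = df$error,
         temperature_K = df$temperature_K,
         environment = if (nrow(df)) df$environment else "micelle",
         tau_m_ns = tau)
}

#' Read build-up series from a TSV
#'
#' Expected columns: chain, residue_number, residue_type, methyl_id, delay_s,
#' ratio, ratio_err, temperature_K. Rows are grouped by probe into one
#' build-up series each.
#'
#' @param path file path.
#' @return list of `buildup_series` objects.
#' @export
read_buildup_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("chain", "residue_number", "residue_type", "methyl_id",
              "delay_s", "ratio", "ratio_err", "temperature_K")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("build-up table lacks column(s): ", paste(missing, collapse = ", "))
  keys <- probe_key(df)
  lapply(split(seq_len(nrow(df)), factor(keys, levels = unique(keys))),
         function(idx) {
           d <- df[idx, ]
           o <- order(d$delay_s)
           buildup_series(
             probe = methyl_probes(d$residue_number[1], d$residue_type[1],
                                   d$methyl_id[1], d$chain[1]),
             delays = d$delay_s[o], ratios = d$ratio[o],
             ratio_errs = d$ratio_err[o],
             temperature_K = d$temperature_K[1])
         })
}

#' Write build-up series to a TSV
#'
#' @param series_list list of `buildup_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_buildup_table <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    data.frame(s$probe[c("chain", "residue_number", "residue_type",
                         "methyl_id")],
               delay_s = s$delays, ratio = s$ratios,
               ratio_err = s$ratio_errs, temperature_K = s$temperature_K,
               row.names = NULL)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a build-up series for one methyl probe
#'
#' Holds the (relaxation delay, intensity ratio, error) triples from which
#' the intra-methyl 1H-1H cross-correlated relaxation rate eta is fitted.
#'
#' @param probe single-row `methyl_probes`.
#' @param delays strictly increasing relaxation delays, s, >= 2 points.
#' @param ratios intensity ratios in (-1, 1), same length as `delays`.
#' @param ratio_errs errors >= 0, same length.
#' @param temperature_K sample temperature, kelvin.
#' @return list of class `buildup_series`.
#' @export
buildup_series <- function(probe, delays, ratios, ratio_errs,
                           temperature_K) {
  stopifnot(nrow(probe) == 1)
  if (length(delays) < 2) stop("need at least 2 delay points")
  if (any(diff(delays) <= 0)) stop("delays must be strictly increasing")
  if (length(ratios) != length(delays) ||
      length(ratio_errs) != length(delays))
    stop("delays, ratios and ratio_errs must have equal length")
  if (any(abs(ratios) >= 1)) stop("intensity ratios must lie in (-1, 1)")
  if (any(ratio_errs < 0)) stop("ratio errors must be >= 0")
  structure(list(probe = probe, delays = as.numeric(delays),
                 ratios = as.numeric(ratios),
                 ratio_errs = as.numeric(ratio_errs),
                 temperature_K = temperature_K),
            class = "buildup_series")
}
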