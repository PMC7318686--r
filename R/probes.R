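#' Methyl probe tables
#'
#' A methyl probe identifies one methyl group by residue number, residue type
#' (ILE, LEU, VAL, MET), a methyl label and a chain identifier. Probes are
#' represented as rows of a data frame with columns `chain`, `residue_number`,
#' `residue_type`, `methyl_id`; [methyl_probes()] validates the naming rules
#' and uniqueness.
#'
#' Allowed methyl labels per residue type: ILE d1 (and g2 when the
#' gamma-methyl is probed), LEU d1/d2, VAL g1/g2, MET e.
#'
#' @param residue_number integer vector, author numbering.
#' @param residue_type character vector in {ILE, LEU, VAL, MET}.
#' @param methyl_id character vector of methyl labels (d1, d2, g1, g2, e).
#' @param chain character vector of chain identifiers (recycled).
#'
#' @return data.frame of class `methyl_probes`.
#' @export
#' @examples
#' methyl_probes(10, "LEU", "d1")
methyl_probes <- function(residue_number, residue_type, methyl_id,
                          chain = "A") {
  df <- data.frame(chain = as.character(chain),
                   residue_number = as.integer(residue_number),
                   residue_type = toupper(as.character(residue_type)),
                   methyl_id = tolower(as.character(methyl_id)),
                   stringsAsFactors = FALSE)
  validate_probes(df)
  class(df) <- c("methyl_probes", "data.frame")
  df
}

.allowed_methyls <- list(ILE = c("d1", "g2"), LEU = c("d1", "d2"),
                         VAL = c("g1", "g2"), MET = "e")

validate_probes <- function(df) {
  needed <- c("chain", "residue_number", "residue_type", "methyl_id")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("probe table lacks column(s): ", paste(missing, collapse = ", "))
  bad_type <- !df$residue_type %in% names(.allowed_methyls)
  if (any(bad_type))
    stop("unknown residue type(s): ",
         paste(unique(df$residue_type[bad_type]), collapse = ", "))
  ok <- mapply(function(ty, me) me %in% .allowed_methyls[[ty]],
               df$residue_type, df$methyl_id)
  if (length(ok) && any(!ok))
    stop("methyl_id not allowed for residue type at row(s): ",
         paste(which(!ok), collapse = ", "))
  key <- probe_key(df)
  if (anyDuplicated(key))
    stop("duplicate probe identities: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  invisible(df)
}

#' Canonical probe identity key
#'
#' Probes are matched across data sets by exact (chain, residue_number,
#' methyl_id) identity; no fuzzy matching is attempted.
#'
#' @param df a data frame carrying probe columns.
#' @return character vector of keys.
#' @export
probe_key <- function(df) {
  paste(df$chain, df$residue_number, df$methyl_id, sep = ":")
}
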