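#' Extract ILVM methyl probes from a PDB structure
#'
#' Walks the ILE/LEU/VAL/MET residues of one chain and returns the methyl
#' carbon atoms present in the model (ILE CD1, LEU CD1/CD2, VAL CG1/CG2,
#' MET CE) together with their coordinates. Only the first model is used;
#' alternate locations other than 'A' or blank are ignored. Residue numbers
#' follow the author numbering in the file.
#'
#' @param path PDB file path.
#' @param chain chain identifier (default "A").
#' @return data.frame with probe columns plus `x`, `y`, `z` (angstrom),
#'   classed `methyl_coords`. Missing expected methyl atoms are skipped with
#'   a warning; a chain without ILVM residues returns an empty table with a
#'   warning.
#' @export
extract_methyl_probes <- function(path, chain = "A") {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("unreadable PDB file: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$chain == chain & at$type == "ATOM" &
             (is.na(at$alt) | at$alt %in% c("", "A")), , drop = FALSE]
  atom_map <- list(
    ILE = c(CD1 = "d1"),
    LEU = c(CD1 = "d1", CD2 = "d2"),
    VAL = c(CG1 = "g1", CG2 = "g2"),
    MET = c(CE = "e"))
  at <- at[at$resid %in% names(atom_map), , drop = FALSE]
  if (nrow(at) == 0) {
    warning("no ILVM residues found in chain ", chain)
    return(empty_methyl_coords())
  }
  rows <- list()
  n_missing <- 0L
  for (res in split(at, paste(at$resno, at$resid))) {
    expected <- atom_map[[res$resid[1]]]
    for (atom_name in names(expected)) {
      hit <- which(res$elety == atom_name)
      if (length(hit) == 0) { n_missing <- n_missing + 1L; next }
      hit <- hit[1]
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, residue_number = res$resno[hit],
        residue_type = res$resid[hit], methyl_id = expected[[atom_name]],
        x = res$x[hit], y = res$y[hit], z = res$z[hit],
        stringsAsFactors = FALSE)
    }
  }
  if (n_missing > 0)
    warning(n_missing, " expected methyl atom(s) missing from the model; skipped")
  out <- do.call(rbind, rows)
  out <- out[order(out$residue_number, out$methyl_id), , drop = FALSE]
  rownames(out) <- NULL
  validate_probes(out)
  class(out) <- c("methyl_coords", "data.frame")
  out
}

empty_methyl_coords <- function() {
  out <- data.frame(chain = character(), residue_number = integer(),
                    residue_type = character(), methyl_id = character(),
                    x = numeric(), y = numeric(), z = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("methyl_coords", "data.frame")
  out
}
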