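# Shared fixtures built in code: a minimal PDB writer and small tables.

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          altloc = " ") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, name, altloc, resname, chain, resno, x, y, z)
}

# A four-residue ILVM peptide with all expected methyl carbons present.
write_tiny_pdb <- function(path, drop_atoms = character(), chain = "A") {
  atoms <- list(
    list("CA",  "LEU", 10, 0, 0, 0), list("CD1", "LEU", 10, 1, 0, 0),
    list("CD2", "LEU", 10, 0, 1, 0),
    list("CA",  "ILE", 11, 5, 0, 0), list("CD1", "ILE", 11, 6, 0, 0),
    list("CA",  "VAL", 12, 10, 0, 0), list("CG1", "VAL", 12, 11, 0, 0),
    list("CG2", "VAL", 12, 10, 1, 0),
    list("CA",  "MET", 13, 15, 0, 0), list("CE",  "MET", 13, 16, 0, 0))
  lines <- character(0)
  serial <- 0
  for (a in atoms) {
    key <- paste0(a[[2]], a[[3]], ":", a[[1]])
    if (key %in% drop_atoms) next
    serial <- serial + 1
    lines <- c(lines, pdb_atom_line(serial, a[[1]], a[[2]], chain, a[[3]],
                                    a[[4]], a[[5]], a[[6]]))
  }
  writeLines(c(lines, "END"), path)
  path
}

# Relaxation records synthesized directly from the forward model.
rigid_records <- function(n = 20, tau_m_ns = 20, S2 = 0.85,
                          field_MHz = 600) {
  R1 <- R2 <- numeric(n)
  for (i in seq_len(n)) {
    r <- predict_n15_rates(S2 = S2, tau_m = tau_m_ns * 1e-9,
                           field_MHz = field_MHz)
    R1[i] <- r$R1; R2[i] <- r$R2
  }
  relaxation_records(data.frame(
    residue_number = seq_len(n), R1 = R1, R1_err = 0.01, R2 = R2,
    R2_err = 0.1, field_MHz = field_MHz, temperature_K = 323.15))
}

# An order-parameter set with given values on sequentially numbered ILE d1.
quick_set <- function(values, errors = 0.02, temperature_K = 323.15,
                      environment = "micelle", tau_m_ns = 21.9,
                      start_res = 1) {
  n <- length(values)
  o2_set(methyl_probes(seq_len(n) + start_res - 1, rep_len("ILE", n),
                       rep_len("d1", n), chain = rep_len("A", n)),
         O2_axis = values, error = rep_len(errors, n),
         temperature_K = temperature_K, environment = environment,
         tau_m_ns = tau_m_ns)
}
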