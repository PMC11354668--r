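# Fixture builders shared across test files. All fixtures are built in code.

# one PDB ATOM/HETATM record with correct fixed columns
pdb_record <- function(rec = "ATOM", serial = 1, atom = "CA", resname = "ALA",
                       chain = "A", resnum = 1, x = 0, y = 0, z = 0,
                       occ = 1, altloc = " ", element = "C") {
  sprintf("%-6s%5d %s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial,
          if (nchar(atom) < 4) sprintf(" %-3s", atom) else atom,
          altloc, resname, chain, resnum, x, y, z, occ, 0, element)
}

# minimal 3-entity fixture: 1 ALA (chain B), 1 DG ligand (chain Z), 1 NAG (chain E)
tiny_complex_text <- function() {
  paste(c(
    pdb_record("ATOM", 1, "CA", "ALA", "B", 423, 0, 0, 0),
    pdb_record("HETATM", 2, "P", "DG", "Z", 1, 0, 4, 0, element = "P"),
    pdb_record("HETATM", 3, "C1", "NAG", "E", 1, 10, 0, 0),
    "END"
  ), collapse = "\n")
}

# two single-atom residues a given distance apart (receptor GLU B423, ligand DG)
pair_complex <- function(distance) {
  txt <- paste(c(
    pdb_record("ATOM", 1, "CA", "GLU", "B", 423, 0, 0, 0),
    pdb_record("HETATM", 2, "P", "DG", "Z", 1, 0, distance, 0, element = "P"),
    "END"
  ), collapse = "\n")
  suppressWarnings(assign_regions(parse_complex(txt, "pair")))
}

# independent RK4 integration of dR/dt = kon*C*(Rmax - R) - kdis*R
ode_langmuir <- function(t_end, C, k_on, k_dis, R_max, R0 = 0, dt = 0.01) {
  f <- function(R) k_on * C * (R_max - R) - k_dis * R
  R <- R0
  n <- round(t_end / dt)
  for (i in seq_len(n)) {
    k1 <- f(R); k2 <- f(R + dt / 2 * k1); k3 <- f(R + dt / 2 * k2); k4 <- f(R + dt * k3)
    R <- R + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  R
}

# a contact_table built directly from a raw N matrix (bases x units)
table_from_N <- function(N, families = NULL) {
  contacts <- do.call(rbind, lapply(seq_len(nrow(N)), function(i) {
    do.call(rbind, lapply(seq_len(ncol(N)), function(j) {
      n <- N[i, j]
      if (n == 0) return(NULL)
      data.frame(ligand_resname = rownames(N)[i],
                 receptor_resname = colnames(N)[j],
                 receptor_kind = if (is.null(families)) "amino_acid" else families[j],
                 stringsAsFactors = FALSE)[rep(1, n), ]
    }))
  }))
  contact_table(contacts)
}
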