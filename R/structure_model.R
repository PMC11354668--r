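# Structure model: PDB parsing, chain/residue typing, and immunoglobulin
# domain-region annotation for docked antibody-ssDNA complexes.

AMINO_ACIDS_3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

DEOXYNUCLEOTIDES <- c("DA", "DC", "DG", "DT")

#' Default monosaccharide residue names recognised as glycan components
#'
#' Three-letter codes treated as monosaccharides when typing HETATM residues.
#' Covers the sugars found in IgG N-glycans plus fructose/fucose.
#' @export
MONOSACCHARIDES <- c("NAG", "MAN", "BMA", "GAL", "FUC", "FRU")

#' Classify a residue name into an entity kind
#'
#' @param name Character vector of 3-letter residue names (PDB `resName`).
#' @param monosaccharides Character vector of residue names to treat as
#'   monosaccharides.
#' @return Character vector with values `"amino_acid"`, `"nucleotide"`,
#'   `"monosaccharide"` or `"other"`.
#' @examples
#' residue_kind(c("ALA", "DG", "NAG", "XYZ"))
#' @export
residue_kind <- function(name, monosaccharides = MONOSACCHARIDES) {
  name <- toupper(trimws(name))
  out <- rep("other", length(name))
  out[name %in% AMINO_ACIDS_3] <- "amino_acid"
  out[name %in% DEOXYNUCLEOTIDES] <- "nucleotide"
  out[name %in% monosaccharides] <- "monosaccharide"
  out
}

fcs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fcs_error")))
}

#' Parse a PDB-format antibody-ligand complex
#'
#' Reads ATOM/HETATM records from PDB-format text and returns a typed complex:
#' protein receptor chains, exactly one ssDNA ligand chain, and any glycan
#' chains. Hydrogens and waters are discarded; alternate locations are resolved
#' to the highest-occupancy copy (ties keep the first record encountered).
#'
#' @param pdb_text PDB-format text: a single string or a character vector of
#'   lines.
#' @param complex_id Identifier attached to the returned structure.
#' @param monosaccharides Residue names treated as glycan monosaccharides.
#' @return An object of class `complex_structure`: a list with `complex_id`,
#'   an `atoms` data frame (`chain`, `resnum`, `resname`, `kind`, `atom`,
#'   `element`, `x`, `y`, `z`, `region`), and the chain ids `ligand_chain`,
#'   `receptor_chains`, `glycan_chains`.
#' @seealso [write_pdb()], [assign_regions()]
#' @export
parse_complex <- function(pdb_text, complex_id = "complex",
                          monosaccharides = MONOSACCHARIDES) {
  lines <- if (length(pdb_text) == 1L) strsplit(pdb_text, "\n", fixed = TRUE)[[1]] else pdb_text
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(keep) == 0L) {
    fcs_error("no ATOM/HETATM records found", "fcs_parse_error")
  }
  ln <- lines[keep]

  field <- function(x, a, b) trimws(substr(x, a, b))
  num_field <- function(x, a, b, what) {
    v <- suppressWarnings(as.numeric(field(x, a, b)))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      fcs_error(sprintf("unparseable %s in record at line %d", what, keep[bad[1]]),
                "fcs_parse_error")
    }
    v
  }

  atoms <- data.frame(
    chain   = substr(ln, 22, 22),
    resnum  = NA_integer_,
    resname = toupper(field(ln, 18, 20)),
    atom    = field(ln, 13, 16),
    altloc  = substr(ln, 17, 17),
    element = toupper(field(ln, 77, 78)),
    x = num_field(ln, 31, 38, "x coordinate"),
    y = num_field(ln, 39, 46, "y coordinate"),
    z = num_field(ln, 47, 54, "z coordinate"),
    occupancy = suppressWarnings(as.numeric(field(ln, 55, 60))),
    stringsAsFactors = FALSE
  )
  resnum <- suppressWarnings(as.integer(field(ln, 23, 26)))
  bad <- which(is.na(resnum))
  if (length(bad)) {
    fcs_error(sprintf("unparseable residue number in record at line %d", keep[bad[1]]),
              "fcs_parse_error")
  }
  atoms$resnum <- resnum
  atoms$occupancy[is.na(atoms$occupancy)] <- 1

  # element fallback: first alphabetic character of the atom name
  noel <- atoms$element == ""
  atoms$element[noel] <- substr(gsub("[^A-Za-z]", "", atoms$atom[noel]), 1, 1)
  if (any(atoms$element == "")) {
    fcs_error(sprintf("record with empty element at line %d",
                      keep[which(atoms$element == "")[1]]), "fcs_parse_error")
  }

  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  atoms <- atoms[!(atoms$resname %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(atoms) == 0L) fcs_error("no heavy atoms after filtering", "fcs_parse_error")

  # altloc resolution: per (chain, resnum, resname, atom) keep highest occupancy,
  # ties -> first encountered
  key <- paste(atoms$chain, atoms$resnum, atoms$resname, atoms$atom, sep = "\r")
  ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  # restore file order
  atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  atoms$altloc <- NULL
  atoms$occupancy <- NULL
  rownames(atoms) <- NULL

  atoms$kind <- residue_kind(atoms$resname, monosaccharides)
  atoms$region <- NA_character_

  chain_kind <- function(ch) {
    k <- unique(atoms$kind[atoms$chain == ch])
    if (identical(k, "nucleotide")) "nucleotide"
    else if (identical(k, "monosaccharide")) "glycan"
    else if ("amino_acid" %in% k) "protein"
    else "other"
  }
  chains <- unique(atoms$chain)
  ckind <- vapply(chains, chain_kind, character(1))

  dna_chains <- chains[ckind == "nucleotide"]
  if (length(dna_chains) == 0L) {
    fcs_error("no ligand: complex contains no pure-nucleotide chain", "fcs_no_ligand")
  }
  if (length(dna_chains) > 1L) {
    fcs_error(sprintf("no ligand: ambiguous - %d nucleotide chains (%s)",
                      length(dna_chains), paste(dna_chains, collapse = ", ")),
              "fcs_no_ligand")
  }
  receptor_chains <- chains[ckind == "protein"]
  if (length(receptor_chains) == 0L) {
    fcs_error("receptor must contain at least one protein chain", "fcs_parse_error")
  }

  if (any(atoms$kind == "other")) {
    bad_res <- unique(atoms$resname[atoms$kind == "other"])
    warning(sprintf("unknown residue name(s) %s typed as 'other'; excluded from contact statistics",
                    paste(bad_res, collapse = ", ")), call. = FALSE)
  }

  # ligand residues ordered 5'->3' by residue number
  lig <- atoms$chain == dna_chains
  atoms <- rbind(atoms[!lig, , drop = FALSE],
                 atoms[lig, , drop = FALSE][order(atoms$resnum[lig]), , drop = FALSE])
  rownames(atoms) <- NULL

  structure(
    list(
      complex_id = complex_id,
      atoms = atoms,
      ligand_chain = dna_chains,
      receptor_chains = sort(receptor_chains),
      glycan_chains = sort(chains[ckind == "glycan"])
    ),
    class = "complex_structure"
  )
}

#' @export
print.complex_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "resnum")]))
  cat(sprintf("<complex_structure> %s: %d atoms, %d residues\n",
              x$complex_id, nrow(x$atoms), nres))
  cat(sprintf("  receptor chains: %s | ligand chain: %s | glycan chains: %s\n",
              paste(x$receptor_chains, collapse = ","), x$ligand_chain,
              if (length(x$glycan_chains)) paste(x$glycan_chains, collapse = ",") else "-"))
  invisible(x)
}

#' Write a complex back to normalized PDB text
#'
#' Produces fixed-column ATOM/HETATM records (HETATM for non-amino-acid
#' residues), one TER per chain. Deterministic: the same structure always
#' yields identical bytes, so generated fixtures round-trip through
#' [parse_complex()].
#'
#' @param structure A `complex_structure`.
#' @return A single string of PDB-format text.
#' @export
write_pdb <- function(structure) {
  a <- structure$atoms
  out <- character(0)
  serial <- 0L
  for (ch in unique(a$chain)) {
    sub <- a[a$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      rec <- if (sub$kind[i] == "amino_acid") "ATOM  " else "HETATM"
      name <- sub$atom[i]
      # PDB atom-name column convention: 1-2 char element names start in col 14
      name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
      out <- c(out, sprintf(
        "%s%5d %s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        rec, serial, name_fmt, " ", sub$resname[i], sub$chain[i], sub$resnum[i],
        sub$x[i], sub$y[i], sub$z[i], 1, 0, sub$element[i]
      ))
    }
    serial <- serial + 1L
    out <- c(out, sprintf("TER   %5d      %-3s %s%4d", serial,
                          sub$resname[nrow(sub)], ch, sub$resnum[nrow(sub)]))
  }
  paste0(paste(out, collapse = "\n"), "\nEND\n")
}

#' Region map describing immunoglobulin domain intervals
#'
#' A region map is a data frame with columns `chain`, `start`, `end`, `region`
#' giving inclusive author-numbering intervals labelled with one of
#' VH, CH1, hinge, CH2, CH3, VL, CL (glycan chains are labelled implicitly).
#' `default_region_map()` returns the map shipped with the package, keyed to an
#' IgG laid out like PDB entry 1IGT (light chains A/C, heavy chains B/D,
#' glycan chains E/F), with the hinge placed at heavy-chain residues 455-475.
#'
#' @param path JSON file containing a list of `{chain, start, end, region}`
#'   objects.
#' @return A data frame of class `region_map`.
#' @examples
#' default_region_map()
#' @export
read_region_map <- function(path) {
  df <- jsonlite::fromJSON(path)
  as_region_map(df)
}

#' @rdname read_region_map
#' @export
default_region_map <- function() {
  read_region_map(system.file("extdata", "regions_1igt.json", package = "fcscreen"))
}

REGION_LABELS <- c("VH", "CH1", "hinge", "CH2", "CH3", "VL", "CL", "glycan")

as_region_map <- function(df) {
  stopifnot(all(c("chain", "start", "end", "region") %in% names(df)))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$end < df$start)) stop("region interval with end < start")
  if (!all(df$region %in% REGION_LABELS)) {
    stop("unknown region label(s): ",
         paste(setdiff(df$region, REGION_LABELS), collapse = ", "))
  }
  # intervals within one chain must not overlap
  for (ch in unique(df$chain)) {
    iv <- df[df$chain == ch, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)])) {
      stop(sprintf("overlapping region intervals on chain %s", ch))
    }
  }
  class(df) <- c("region_map", "data.frame")
  df
}

#' Write a region map to JSON
#' @param map A `region_map` data frame.
#' @param path Output file path.
#' @export
write_region_map <- function(map, path) {
  jsonlite::write_json(as.data.frame(map)[, c("chain", "start", "end", "region")],
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Map region labels to the Fab/Fc/hinge groupings
#'
#' Fab = \{VH, CH1, VL, CL\}; Fc = \{CH2, CH3, glycan\}; the hinge is its own
#' group. Anything else (including `"unassigned"`) maps to `NA`.
#'
#' @param region Character vector of region labels.
#' @return Character vector with values `"Fab"`, `"Fc"`, `"hinge"` or `NA`.
#' @export
region_group <- function(region) {
  out <- rep(NA_character_, length(region))
  out[region %in% c("VH", "CH1", "VL", "CL")] <- "Fab"
  out[region %in% c("CH2", "CH3", "glycan")] <- "Fc"
  out[region %in% "hinge"] <- "hinge"
  out
}

#' Annotate every receptor residue with its domain region
#'
#' Receptor residues falling inside a region-map interval get that label;
#' all other receptor residues get `"unassigned"`. Glycan-chain residues are
#' always labelled `"glycan"`. Ligand nucleotides keep `NA`. A map interval
#' referencing a chain absent from the structure raises a warning, not an
#' error.
#'
#' @param structure A `complex_structure`.
#' @param region_map A `region_map`; defaults to [default_region_map()].
#' @return The structure with its `atoms$region` column filled in.
#' @export
assign_regions <- function(structure, region_map = default_region_map()) {
  a <- structure$atoms
  missing_chains <- setdiff(unique(region_map$chain), unique(a$chain))
  if (length(missing_chains)) {
    warning(sprintf("region map references chain(s) absent from %s: %s",
                    structure$complex_id, paste(missing_chains, collapse = ", ")),
            call. = FALSE)
  }
  reg <- rep(NA_character_, nrow(a))
  is_receptor <- a$chain %in% structure$receptor_chains
  reg[is_receptor] <- "unassigned"
  for (i in seq_len(nrow(region_map))) {
    hit <- a$chain == region_map$chain[i] &
      a$resnum >= region_map$start[i] & a$resnum <= region_map$end[i] &
      is_receptor
    reg[hit] <- region_map$region[i]
  }
  reg[a$chain %in% structure$glycan_chains] <- "glycan"
  structure$atoms$region <- reg
  structure
}

# residue-level view of a structure's atoms (one row per residue)
residue_table <- function(structure) {
  a <- structure$atoms
  key <- !duplicated(paste(a$chain, a$resnum, sep = "\r"))
  a[key, c("chain", "resnum", "resname", "kind", "region"), drop = FALSE]
}
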