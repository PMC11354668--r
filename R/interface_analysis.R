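# Interface analysis: ligand-receptor contact detection at distance cutoffs,
# per-site binding frequencies across an ensemble, and interface composition.

#' Contact-detection parameters
#'
#' A single heavy-atom cutoff is used by default. Optionally a per-class map
#' can be supplied: atom pairs where both atoms are N or O are classed as
#' hydrogen-bond capable (`hbond`), everything else as `other`, and each class
#' gets its own cutoff. The admissible band for cutoffs is (0, 10] Angstrom;
#' values between 3 and 6 Angstrom are typical for non-bonded contacts.
#'
#' @param default_cutoff Heavy-atom distance cutoff in Angstrom (default 4.5).
#' @param class_cutoffs Optional named numeric vector with entries `hbond`
#'   and `other`, e.g. `c(hbond = 3.5, other = 6)`.
#' @return A list of class `contact_params`.
#' @export
contact_params <- function(default_cutoff = 4.5, class_cutoffs = NULL) {
  cuts <- c(default_cutoff, class_cutoffs)
  if (any(!is.finite(cuts)) || any(cuts <= 0) || any(cuts > 10)) {
    stop("cutoffs must lie in (0, 10] Angstrom")
  }
  if (!is.null(class_cutoffs) &&
      !all(c("hbond", "other") %in% names(class_cutoffs))) {
    stop("class_cutoffs must name both 'hbond' and 'other'")
  }
  structure(list(default_cutoff = default_cutoff, class_cutoffs = class_cutoffs),
            class = "contact_params")
}

# split atoms into ligand side and receptor side (protein + glycan);
# 'other'-kind residues are excluded from contact statistics
contact_sides <- function(structure) {
  a <- structure$atoms
  lig <- a[a$chain == structure$ligand_chain, , drop = FALSE]
  rec <- a[a$chain %in% c(structure$receptor_chains, structure$glycan_chains) &
             a$kind %in% c("amino_acid", "monosaccharide"), , drop = FALSE]
  list(lig = lig, rec = rec)
}

atom_class <- function(element) ifelse(element %in% c("N", "O"), "hbond", "other")

pair_cutoffs <- function(params, lig_el, rec_el) {
  if (is.null(params$class_cutoffs)) {
    matrix(params$default_cutoff, length(lig_el), length(rec_el))
  } else {
    both_hb <- outer(atom_class(lig_el) == "hbond", atom_class(rec_el) == "hbond", "&")
    ifelse(both_hb, params$class_cutoffs[["hbond"]], params$class_cutoffs[["other"]])
  }
}

pair_classes <- function(params, lig_el, rec_el) {
  if (is.null(params$class_cutoffs)) {
    matrix("all", length(lig_el), length(rec_el))
  } else {
    ifelse(outer(atom_class(lig_el) == "hbond", atom_class(rec_el) == "hbond", "&"),
           "hbond", "other")
  }
}

# Aggregate qualifying atom pairs into residue-pair contacts; i/j are row
# indices into lig/rec atom tables, d the corresponding distances.
aggregate_contacts <- function(lig, rec, i, j, d, cls) {
  if (length(i) == 0L) {
    return(data.frame(
      ligand_chain = character(0), ligand_resnum = integer(0),
      ligand_resname = character(0), receptor_chain = character(0),
      receptor_resnum = integer(0), receptor_resname = character(0),
      receptor_kind = character(0), region = character(0),
      min_distance = numeric(0), interaction_class = character(0),
      stringsAsFactors = FALSE
    ))
  }
  key <- paste(lig$resnum[i], rec$chain[j], rec$resnum[j], sep = "\r")
  ord <- order(key, d)
  first <- ord[!duplicated(key[ord])]
  i <- i[first]; j <- j[first]; d <- d[first]; cls <- cls[first]
  out <- data.frame(
    ligand_chain = lig$chain[i], ligand_resnum = lig$resnum[i],
    ligand_resname = lig$resname[i],
    receptor_chain = rec$chain[j], receptor_resnum = rec$resnum[j],
    receptor_resname = rec$resname[j], receptor_kind = rec$kind[j],
    region = rec$region[j],
    min_distance = d, interaction_class = cls,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$ligand_resnum, out$receptor_chain, out$receptor_resnum), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect ligand-receptor interface contacts
#'
#' A contact is a (ligand nucleotide, receptor residue-or-monosaccharide) pair
#' with at least one heavy-atom pair within the applicable cutoff. The minimum
#' heavy-atom distance over the pair is recorded. Implemented with a cell-grid
#' neighbour search; [find_contacts_brute()] is the independent all-pairs
#' reference used to validate it.
#'
#' @param structure A region-annotated `complex_structure`.
#' @param params A [contact_params()] object.
#' @return Data frame of contacts sorted by ligand residue number then
#'   receptor chain/residue, with columns `ligand_chain`, `ligand_resnum`,
#'   `ligand_resname`, `receptor_chain`, `receptor_resnum`,
#'   `receptor_resname`, `receptor_kind`, `region`, `min_distance`,
#'   `interaction_class`. An empty ligand yields zero rows, not an error.
#' @export
find_contacts <- function(structure, params = contact_params()) {
  s <- contact_sides(structure)
  lig <- s$lig; rec <- s$rec
  if (nrow(lig) == 0L || nrow(rec) == 0L) {
    return(aggregate_contacts(lig, rec, integer(0), integer(0), numeric(0), character(0)))
  }
  max_cut <- if (is.null(params$class_cutoffs)) params$default_cutoff
             else max(params$class_cutoffs)

  # cell grid over receptor atoms, cell edge = max cutoff
  cell <- function(v) as.integer(floor(v / max_cut))
  rc <- paste(cell(rec$x), cell(rec$y), cell(rec$z), sep = "\r")
  grid <- split(seq_len(nrow(rec)), rc)

  ii <- integer(0); jj <- integer(0); dd <- numeric(0); cc <- character(0)
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  for (k in seq_len(nrow(lig))) {
    cx <- cell(lig$x[k]); cy <- cell(lig$y[k]); cz <- cell(lig$z[k])
    keys <- paste(cx + offsets$dx, cy + offsets$dy, cz + offsets$dz, sep = "\r")
    cand <- unlist(grid[keys], use.names = FALSE)
    if (length(cand) == 0L) next
    d <- sqrt((rec$x[cand] - lig$x[k])^2 +
              (rec$y[cand] - lig$y[k])^2 +
              (rec$z[cand] - lig$z[k])^2)
    cut <- pair_cutoffs(params, lig$element[k], rec$element[cand])[1, ]
    cls <- pair_classes(params, lig$element[k], rec$element[cand])[1, ]
    hit <- which(d <= cut)
    if (length(hit)) {
      ii <- c(ii, rep.int(k, length(hit)))
      jj <- c(jj, cand[hit])
      dd <- c(dd, d[hit])
      cc <- c(cc, cls[hit])
    }
  }
  aggregate_contacts(lig, rec, ii, jj, dd, cc)
}

#' @describeIn find_contacts Independent O(n^2) all-pairs implementation;
#'   identical contract, used as a brute-force oracle.
#' @export
find_contacts_brute <- function(structure, params = contact_params()) {
  s <- contact_sides(structure)
  lig <- s$lig; rec <- s$rec
  if (nrow(lig) == 0L || nrow(rec) == 0L) {
    return(aggregate_contacts(lig, rec, integer(0), integer(0), numeric(0), character(0)))
  }
  dx <- outer(lig$x, rec$x, "-")
  dy <- outer(lig$y, rec$y, "-")
  dz <- outer(lig$z, rec$z, "-")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  cut <- pair_cutoffs(params, lig$element, rec$element)
  cls <- pair_classes(params, lig$element, rec$element)
  hit <- which(d <= cut, arr.ind = TRUE)
  aggregate_contacts(lig, rec, hit[, 1], hit[, 2], d[hit], cls[hit])
}

#' Per-site binding frequency across an ensemble of complexes
#'
#' Counts, for every receptor site (chain, residue number, residue name), the
#' number of complexes whose interface includes that site. A site contacted by
#' several nucleotides of one ligand is still counted once for that complex.
#'
#' @param contacts_list List of contact data frames, one per complex (as
#'   returned by [find_contacts()]).
#' @param region_filter `"Fc"`, `"Fab"`, `"hinge"` to restrict to one
#'   grouping, or `"all"`.
#' @return Data frame with columns `chain`, `resnum`, `resname`, `region`,
#'   `count`, `n_complexes`, `fraction`, sorted by chain then residue number.
#' @export
binding_frequency <- function(contacts_list, region_filter = "Fc") {
  if (length(contacts_list) == 0L) stop("empty ensemble")
  n <- length(contacts_list)
  per_complex <- lapply(contacts_list, function(ct) {
    if (region_filter != "all") {
      ct <- ct[!is.na(region_group(ct$region)) &
                 region_group(ct$region) == region_filter, , drop = FALSE]
    }
    unique(ct[, c("receptor_chain", "receptor_resnum", "receptor_resname", "region")])
  })
  all_sites <- do.call(rbind, per_complex)
  if (is.null(all_sites) || nrow(all_sites) == 0L) {
    return(data.frame(chain = character(0), resnum = integer(0),
                      resname = character(0), region = character(0),
                      count = integer(0), n_complexes = integer(0),
                      fraction = numeric(0)))
  }
  key <- paste(all_sites$receptor_chain, all_sites$receptor_resnum, sep = "\r")
  tab <- table(key)
  first <- all_sites[!duplicated(key), , drop = FALSE]
  out <- data.frame(
    chain = first$receptor_chain, resnum = first$receptor_resnum,
    resname = first$receptor_resname, region = first$region,
    count = as.integer(tab[paste(first$receptor_chain, first$receptor_resnum, sep = "\r")]),
    n_complexes = n,
    stringsAsFactors = FALSE
  )
  out$fraction <- out$count / n
  out <- out[order(out$chain, out$resnum), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interface composition by residue / monosaccharide type
#'
#' Share of interface contacts carried by each amino-acid and each
#' monosaccharide type. The two families are normalised separately, each to
#' 100 percent.
#'
#' @param contacts A contact data frame, possibly pooled (`rbind`) over an
#'   ensemble.
#' @return Data frame with columns `family`, `unit`, `count`, `share_pct`.
#' @export
interface_composition <- function(contacts) {
  if (is.null(contacts) || nrow(contacts) == 0L) stop("zero contacts")
  out <- do.call(rbind, lapply(split(contacts, contacts$receptor_kind), function(ct) {
    tab <- sort(table(ct$receptor_resname), decreasing = TRUE)
    data.frame(family = ct$receptor_kind[1], unit = names(tab),
               count = as.integer(tab),
               share_pct = 100 * as.integer(tab) / sum(tab),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
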