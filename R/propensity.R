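# Contact propensity: base-vs-structural-unit preference statistics computed
# from interface contact counts.

BASES <- c("DA", "DC", "DG", "DT")

#' Build a base-by-unit contact count table
#'
#' Tabulates contacts as N[i, j]: the number of base-i / unit-j residue-pair
#' contacts, for bases DA/DC/DG/DT against every amino-acid or monosaccharide
#' unit observed on the receptor side. T[j], the total number of contacts of
#' unit j over the entire dataset, defaults to the column sums of N but may be
#' supplied externally (e.g. when the interface set under study is a subset of
#' the full dataset).
#'
#' @param contacts Contact data frame, typically pooled over all complexes.
#' @param T_j Optional named numeric vector of per-unit dataset totals; names
#'   must cover the units of `N`.
#' @return Object of class `contact_table`: list with integer matrix `N`
#'   (4 x units), numeric vector `T`, and `family` (unit -> family map).
#' @export
contact_table <- function(contacts, T_j = NULL) {
  if (is.null(contacts) || nrow(contacts) == 0L) stop("no contacts to tabulate")
  units <- sort(unique(contacts$receptor_resname))
  N <- matrix(0L, nrow = length(BASES), ncol = length(units),
              dimnames = list(BASES, units))
  tab <- table(factor(contacts$ligand_resname, levels = BASES),
               factor(contacts$receptor_resname, levels = units))
  N[] <- as.integer(tab)
  fam <- vapply(units, function(u) {
    contacts$receptor_kind[match(u, contacts$receptor_resname)]
  }, character(1))
  if (is.null(T_j)) {
    T_j <- colSums(N)
  } else {
    if (!all(units %in% names(T_j))) stop("T_j must name every unit in N")
    T_j <- T_j[units]
    if (any(T_j < apply(N, 2, max))) {
      stop("inconsistent totals: T_j smaller than a single-base count")
    }
  }
  structure(list(N = N, T = T_j, family = fam), class = "contact_table")
}

#' @export
print.contact_table <- function(x, ...) {
  cat(sprintf("<contact_table> %d bases x %d units, %d contacts\n",
              nrow(x$N), ncol(x$N), sum(x$N)))
  print(x$N)
  invisible(x)
}

#' Base-unit contact propensity
#'
#' For base i and structural unit j (amino acid or monosaccharide),
#' \deqn{P_{ij} = \frac{N_{ij} / \sum_j N_{ij}}{T_j / \sum_j T_j}}
#' i.e. unit j's share of base-i contacts divided by unit j's share of all
#' dataset contacts. P > 1 marks a favoured pairing, P < 1 a disfavoured one.
#' Units with T_j = 0 get `NA` (undefined), never 0. `sum_over = "bases"`
#' selects the alternative normalisation in which the numerator share is taken
#' down each column (over bases i) instead.
#'
#' @param table A [contact_table()].
#' @param sum_over `"units"` (default, the standard propensity) or `"bases"`.
#' @return Object of class `propensity_table`: list with numeric matrix `P`
#'   and the input table.
#' @export
contact_propensity <- function(table, sum_over = c("units", "bases")) {
  sum_over <- match.arg(sum_over)
  N <- table$N; T_j <- table$T
  if (sum(N) == 0) stop("all-zero contact table")
  if (sum(T_j) == 0) stop("all-zero dataset totals")
  bad <- which(T_j == 0 & apply(N, 2, max) > 0)
  if (length(bad)) {
    stop(sprintf("inconsistent table: T_j = 0 but N_ij > 0 for unit(s) %s",
                 paste(colnames(N)[bad], collapse = ", ")))
  }
  t_share <- T_j / sum(T_j)
  if (sum_over == "units") {
    row_tot <- rowSums(N)
    n_share <- sweep(N, 1, ifelse(row_tot > 0, row_tot, NA_real_), "/")
  } else {
    col_tot <- colSums(N)
    n_share <- sweep(N, 2, ifelse(col_tot > 0, col_tot, NA_real_), "/")
  }
  P <- sweep(n_share, 2, t_share, "/")
  P[, t_share == 0] <- NA_real_
  structure(list(P = P, table = table, sum_over = sum_over),
            class = "propensity_table")
}

#' @export
print.propensity_table <- function(x, digits = 3, ...) {
  cat("<propensity_table> P_ij (NA = undefined, dashed null line at 1)\n")
  print(round(x$P, digits))
  invisible(x)
}

#' Classify propensities against the null line P = 1
#'
#' @param p A `propensity_table` or numeric matrix/vector of propensities.
#' @return Character object of the same shape with values `"favored"`
#'   (P > 1), `"disfavored"` (P < 1), `"neutral"` (P == 1) or `NA`.
#' @export
propensity_class <- function(p) {
  if (inherits(p, "propensity_table")) p <- p$P
  out <- ifelse(p > 1, "favored", ifelse(p < 1, "disfavored", "neutral"))
  out
}

#' Per-unit interface presence share within a family
#'
#' The probability of each structural unit appearing on the binding interface:
#' its share of the family's interface contacts, in percent. Families
#' (amino acids, monosaccharides) are normalised separately.
#'
#' @param table A [contact_table()].
#' @param family `"amino_acid"` or `"monosaccharide"`.
#' @return Named numeric vector of percentages summing to 100.
#' @export
presence_share <- function(table, family = c("amino_acid", "monosaccharide")) {
  family <- match.arg(family)
  units <- names(table$family)[table$family == family]
  if (length(units) == 0L) stop(sprintf("no units of family '%s'", family))
  counts <- colSums(table$N[, units, drop = FALSE])
  if (sum(counts) == 0) stop(sprintf("family '%s' has zero contacts", family))
  100 * counts / sum(counts)
}
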