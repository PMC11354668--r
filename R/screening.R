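# Screening: binding-mode classification of docked ligands, Fc-binder
# filtering/ranking, and the mutation re-docking comparison report.

MODE_LEVELS <- c("FAB", "MODE1", "MODE2", "MODE3", "UNCLASSIFIED")

#' Classify a docked ligand's binding mode
#'
#' Modes describe where a docked ssDNA ligand sits on the antibody:
#' \describe{
#'   \item{FAB}{every contacted receptor residue lies in the Fab grouping
#'     (VH/CH1/VL/CL);}
#'   \item{MODE1}{every contacted residue lies in the Fc grouping
#'     (CH2/CH3/glycan) - full Fc binding, the orientation useful for
#'     directional antibody immobilisation;}
#'   \item{MODE2}{at least one contacted residue lies in the hinge interval
#'     and neither pure case holds;}
#'   \item{MODE3}{at least `majority_threshold` of the contacting nucleotides
#'     touch Fc and every remaining contacting nucleotide touches CH1 or CL;}
#'   \item{UNCLASSIFIED}{anything else, including a ligand with no contacts
#'     (which also raises a warning).}
#' }
#' Precedence: the pure cases (FAB, MODE1), then MODE2, then MODE3.
#'
#' @param structure A region-annotated `complex_structure`.
#' @param contacts Contact data frame from [find_contacts()].
#' @param majority_threshold Fraction of contacting nucleotides that must
#'   touch Fc for MODE3 (default 0.5, strict majority at > 0.5 is not
#'   required: the comparison is >=).
#' @param pose Optional list/row with `zdock_score` (and `pose_rank`) to
#'   carry through.
#' @return One-row data frame (a screening record): `ligand_id`, `mode`,
#'   `fc_bound`, `zdock_score`, `frac_fc`, `frac_fab`, `frac_hinge`
#'   (share of all ligand nucleotides contacting each grouping).
#' @export
classify_binding_mode <- function(structure, contacts, majority_threshold = 0.5,
                                  pose = NULL) {
  stopifnot(majority_threshold > 0, majority_threshold <= 1)
  lig_res <- residue_table(structure)
  lig_res <- lig_res[lig_res$chain == structure$ligand_chain, , drop = FALSE]
  n_nt <- nrow(lig_res)
  score <- if (!is.null(pose)) as.numeric(pose$zdock_score) else NA_real_

  groups <- region_group(contacts$region)
  # share of ligand nucleotides contacting each grouping
  frac_of <- function(gr) {
    nt <- unique(contacts$ligand_resnum[!is.na(groups) & groups == gr])
    length(nt) / n_nt
  }
  rec <- data.frame(
    ligand_id = structure$complex_id, mode = "UNCLASSIFIED", fc_bound = FALSE,
    zdock_score = score, frac_fc = frac_of("Fc"), frac_fab = frac_of("Fab"),
    frac_hinge = frac_of("hinge"), stringsAsFactors = FALSE
  )

  if (nrow(contacts) == 0L) {
    warning(sprintf("ligand %s has zero contacts: UNCLASSIFIED", structure$complex_id),
            call. = FALSE)
    return(rec)
  }

  mode <- if (all(!is.na(groups) & groups == "Fab")) {
    "FAB"
  } else if (all(!is.na(groups) & groups == "Fc")) {
    "MODE1"
  } else if (any(!is.na(groups) & groups == "hinge")) {
    "MODE2"
  } else {
    # per contacting nucleotide: does it touch Fc? if not, does it touch CH1/CL?
    by_nt <- split(seq_len(nrow(contacts)), contacts$ligand_resnum)
    touches_fc <- vapply(by_nt, function(ix) any(groups[ix] %in% "Fc"), logical(1))
    rem_ok <- vapply(by_nt, function(ix) {
      any(contacts$region[ix] %in% c("CH1", "CL"))
    }, logical(1))
    frac_fc_contacting <- mean(touches_fc)
    if (frac_fc_contacting >= majority_threshold && all(touches_fc | rem_ok)) {
      "MODE3"
    } else {
      "UNCLASSIFIED"
    }
  }
  rec$mode <- mode
  rec$fc_bound <- mode == "MODE1"
  rec
}

#' Filter and rank Fc-specific binders
#'
#' Keeps records with `fc_bound == TRUE` (mode MODE1), sorted by docking score
#' descending; ties broken by `ligand_id` lexicographically for
#' reproducibility.
#'
#' @param records Data frame of screening records
#'   (rows from [classify_binding_mode()], with a `zdock_score` column).
#' @return The filtered, ranked data frame; attribute `n_total` carries the
#'   input record count.
#' @export
screen_fc_binders <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("no screening records supplied")
  out <- records[records$fc_bound %in% TRUE, , drop = FALSE]
  out <- out[order(-out$zdock_score, out$ligand_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_total") <- nrow(records)
  out
}

#' Before/after mutation re-docking comparison
#'
#' Compares a ligand's docking score and site engagement before and after a
#' receptor point mutation (e.g. a glutamate-to-glycine substitution at a
#' high-frequency binding site). A negative `delta` means the mutation lost
#' docking favourability, i.e. the original residue facilitated binding.
#'
#' @param before,after Lists with elements `pose` (containing `ligand_id` and
#'   `zdock_score`) and `contacts` (a contact data frame).
#' @param site The probed receptor site, either `"B:423"`-style string or a
#'   list with `chain` and `resnum`.
#' @return One-row data frame: `ligand_id`, `score_before`, `score_after`,
#'   `delta`, `site_still_contacted`.
#' @export
mutation_report <- function(before, after, site) {
  if (!identical(before$pose$ligand_id, after$pose$ligand_id)) {
    stop(sprintf("mismatched ligand ids: '%s' vs '%s'",
                 before$pose$ligand_id, after$pose$ligand_id))
  }
  if (is.character(site)) {
    parts <- strsplit(site, ":", fixed = TRUE)[[1]]
    site <- list(chain = parts[1], resnum = as.integer(parts[2]))
  }
  sb <- as.numeric(before$pose$zdock_score)
  sa <- as.numeric(after$pose$zdock_score)
  engaged <- any(after$contacts$receptor_chain == site$chain &
                   after$contacts$receptor_resnum == site$resnum)
  data.frame(
    ligand_id = before$pose$ligand_id,
    score_before = sb, score_after = sa, delta = sa - sb,
    site_still_contacted = engaged,
    stringsAsFactors = FALSE
  )
}

#' Read / write a docking pose-score table
#'
#' Tab-separated with columns `ligand_id`, `pose_rank`, `zdock_score`.
#' Pose rank 1 is the highest-scoring pose of that ligand; scores are produced
#' by an external rigid-docking engine and only consumed here.
#'
#' @param path File path.
#' @return Data frame with the three columns.
#' @export
read_pose_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ligand_id", "pose_rank", "zdock_score")
  if (!all(need %in% names(df))) {
    stop("pose table must have columns ligand_id, pose_rank, zdock_score")
  }
  df$pose_rank <- as.integer(df$pose_rank)
  df$zdock_score <- as.numeric(df$zdock_score)
  if (any(df$pose_rank < 1L)) stop("pose_rank must be >= 1")
  df[, need]
}

#' @rdname read_pose_table
#' @param poses Data frame with columns `ligand_id`, `pose_rank`,
#'   `zdock_score`.
#' @export
write_pose_table <- function(poses, path) {
  utils::write.table(poses, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
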