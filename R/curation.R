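#' Convert an IC50 in nanomolar to pIC50
#'
#' pIC50 is the negative decadic logarithm of the molar IC50, so an IC50 of
#' 10 nM corresponds to pIC50 = 8 and lower IC50 (more potent) gives higher
#' pIC50.  Since the input is in nM, \code{pIC50 = 9 - log10(IC50_nM)}.
#'
#' @param ic50_nM Positive IC50 value(s) in nanomolar.
#' @return pIC50 value(s), unitless.
#' @export
#' @examples
#' to_pic50(10)        # 8
#' to_pic50(0.002)     # 11.699
#' to_pic50(1.5e6)     # 2.824
to_pic50 <- function(ic50_nM) {
  if (any(!is.finite(ic50_nM)) || any(ic50_nM <= 0)) {
    stop_qsar("IC50 must be a positive finite concentration in nM",
              "qsarnest_domain_error")
  }
  9 - log10(ic50_nM)
}

#' Convert pIC50 back to an IC50 in nanomolar
#'
#' Inverse of [to_pic50()]; used when reports quote potency thresholds in
#' concentration units (pIC50 >= 8 is IC50 <= 10 nM).
#'
#' @param pic50 pIC50 value(s).
#' @return IC50 in nM.
#' @export
pic50_to_ic50 <- function(pic50) {
  10^(9 - pic50)
}

#' Standardize a SMILES string to a canonical structure key
#'
#' Produces a canonical structure key used for duplicate detection: the input
#' is parsed, the largest covalent fragment is kept (stripping counter-ions
#' and co-crystallized small fragments), simple protonation charges are
#' neutralized, and the result is written as canonical SMILES.  A salt and
#' its parent acid therefore map to the same key, so e.g. an acid and its
#' sodium salt are treated as duplicate records of the acid form.
#'
#' Fragment size is measured in heavy atoms; ties are broken by the longer
#' canonical SMILES string and then lexicographically, so the choice is
#' deterministic.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical structure keys.  Unparsable inputs
#'   raise an error naming the offending string.
#' @export
#' @examples
#' standardize_smiles("CC(=O)O.[Na+]")  # same key as "CC(=O)O"
standardize_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    can <- ob_canonical(s)
    if (is.na(can)) {
      stop_qsar(sprintf("unparsable SMILES: '%s'", s), "qsarnest_parse_error")
    }
    frags <- strsplit(can, ".", fixed = TRUE)[[1]]
    if (length(frags) > 1) {
      frags <- unique(frags)
      heavy <- ob_heavy_atoms(frags)
      ord <- order(-heavy, -nchar(frags), frags)
      frags <- frags[ord[1]]
    }
    out <- ob_canonical(frags, neutralize = TRUE)
    if (is.na(out)) out <- frags  # neutralization failure: keep fragment as-is
    out
  }, character(1), USE.NAMES = FALSE)
}

#' Read a compound activity table from CSV
#'
#' Reads a CSV with one compound per row, keeping rows with a parsable
#' SMILES and a positive numeric IC50 (nM).  Rows failing either check are
#' dropped and recorded in the curation log attached to the result.  pIC50
#' is computed for every retained record.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param id_col,smiles_col,ic50_col Column names holding the compound id,
#'   SMILES string and IC50 in nM.
#' @return A data frame of compound records (\code{id}, \code{smiles},
#'   \code{ic50_nM}, \code{pic50}) with a \code{"curation_log"} attribute:
#'   a data frame of dropped rows and the drop reason.
#' @export
read_activity_table <- function(path, id_col = "id", smiles_col = "smiles",
                                ic50_col = "ic50_nM") {
  if (!file.exists(path)) {
    stop_qsar(sprintf("activity table not found: %s", path), "qsarnest_io_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", check.names = FALSE)
  missing_cols <- setdiff(c(id_col, smiles_col, ic50_col), names(raw))
  if (length(missing_cols)) {
    stop_qsar(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
              "qsarnest_schema_error")
  }
  id <- as.character(raw[[id_col]])
  smiles <- as.character(raw[[smiles_col]])
  ic50 <- suppressWarnings(as.numeric(raw[[ic50_col]]))

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(ic50)] <- "missing or non-numeric IC50"
  reason[!is.na(ic50) & ic50 <= 0] <- "non-positive IC50"
  bad_smiles <- is.na(reason) & is.na(ob_canonical(smiles))
  reason[bad_smiles] <- "unparsable SMILES"

  keep <- is.na(reason)
  records <- data.frame(
    id = id[keep], smiles = smiles[keep], ic50_nM = ic50[keep],
    pic50 = to_pic50(ic50[keep]), stringsAsFactors = FALSE
  )
  attr(records, "curation_log") <- data.frame(
    id = id[!keep], reason = reason[!keep], stringsAsFactors = FALSE
  )
  records
}

#' Merge duplicate compound records by median IC50
#'
#' Records are grouped by canonical structure key (see
#' [standardize_smiles()]).  Each group collapses to a single record whose
#' IC50 is the median of the group's IC50 values (midpoint of the two
#' central values for even counts); the pIC50 is recomputed from that merged
#' IC50, not averaged over the duplicates' pIC50s.  The id of the first
#' occurrence is retained.
#'
#' @param records Data frame of compound records as returned by
#'   [read_activity_table()].
#' @param standardize Standardize SMILES before grouping (set to FALSE when
#'   the \code{smiles} column already holds structure keys).
#' @return A \code{curated_dataset}: list with \code{records} (one row per
#'   unique structure, columns \code{id}, \code{smiles}, \code{ic50_nM},
#'   \code{pic50}, \code{split}) and \code{log} (merge actions).
#' @export
deduplicate <- function(records, standardize = TRUE) {
  if (nrow(records) == 0) {
    out <- records
    out$split <- character(0)
    return(structure(list(records = out, log = list()), class = "curated_dataset"))
  }
  key <- if (standardize) standardize_smiles(records$smiles) else records$smiles
  groups <- split(seq_len(nrow(records)), factor(key, levels = unique(key)))
  log <- list()
  rows <- lapply(groups, function(idx) {
    ic50 <- stats::median(records$ic50_nM[idx])
    if (length(idx) > 1) {
      log[[length(log) + 1L]] <<- sprintf(
        "merged %d records (%s) into '%s' with median IC50 %g nM",
        length(idx), paste(records$id[idx], collapse = ", "),
        records$id[idx[1]], ic50
      )
    }
    data.frame(
      id = records$id[idx[1]],
      smiles = key[idx[1]],
      ic50_nM = ic50,
      pic50 = to_pic50(ic50),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$split <- rep("unsplit", nrow(out))
  structure(list(records = out, log = log), class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat(sprintf("Curated dataset: %d compounds (%d train / %d test / %d unsplit)\n",
              nrow(x$records),
              sum(x$records$split == "train"),
              sum(x$records$split == "test"),
              sum(x$records$split == "unsplit")))
  if (length(x$log)) cat(sprintf("  %d curation action(s) logged\n", length(x$log)))
  invisible(x)
}

#' Random train/test split
#'
#' Draws a plain (unstratified) random split.  The training-set size is
#' \code{floor(n * ratio)}, so a 3:1 split of 227 compounds gives 170
#' training and 57 test compounds.
#'
#' @param n Number of records (>= 2).
#' @param ratio Training fraction in (0, 1); 0.75 is a 3:1 split.
#' @param seed Integer seed; the same (n, seed) always yields the same split.
#' @return List with integer vectors \code{train} and \code{test} (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(n, ratio = 0.75, seed = 1) {
  if (n < 2) stop_qsar("need at least 2 records to split", "qsarnest_domain_error")
  if (ratio <= 0 || ratio >= 1) {
    stop_qsar("ratio must be strictly between 0 and 1", "qsarnest_domain_error")
  }
  n_train <- floor(n * ratio)
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[seq(n_train + 1, n)]))
}

#' Apply a random split to a curated dataset
#'
#' @param dataset A \code{curated_dataset}.
#' @inheritParams split_train_test
#' @return The dataset with its \code{split} column filled in.
#' @export
assign_split <- function(dataset, ratio = 0.75, seed = 1) {
  idx <- split_train_test(nrow(dataset$records), ratio, seed)
  dataset$records$split <- "test"
  dataset$records$split[idx$train] <- "train"
  dataset$log <- c(dataset$log, sprintf(
    "split %d compounds into %d train / %d test (ratio %g, seed %d)",
    nrow(dataset$records), length(idx$train), length(idx$test), ratio, seed))
  dataset
}

#' Count Lipinski rule-of-five failures
#'
#' Checks the drug-likeness bounds MW <= 500, ALogP <= 5, H-bond donors
#' <= 5, H-bond acceptors <= 10, and (as a configurable fifth criterion)
#' rotatable bonds <= 10.  With \code{five_rules = FALSE} only the four
#' canonical checks are applied.
#'
#' @param mw Molecular weight, g/mol.
#' @param alogp Atomic logP estimate.
#' @param hbd,hba Hydrogen-bond donor and acceptor counts.
#' @param rotatable_bonds Rotatable-bond count (used only when
#'   \code{five_rules} is TRUE).
#' @param five_rules Include the rotatable-bond criterion as a fifth check.
#' @return Integer count of violated criteria (0..5, or 0..4).
#' @export
lipinski_failures <- function(mw, alogp, hbd, hba, rotatable_bonds = NULL,
                              five_rules = TRUE) {
  fails <- (mw > 500) + (alogp > 5) + (hbd > 5) + (hba > 10)
  if (five_rules) {
    if (is.null(rotatable_bonds)) {
      stop_qsar("rotatable_bonds required when five_rules = TRUE",
                "qsarnest_domain_error")
    }
    fails <- fails + (rotatable_bonds > 10)
  }
  as.integer(fails)
}

#' Physico-chemical property profile of compounds
#'
#' Computes, per SMILES, the inputs of [lipinski_failures()] plus the
#' MW/ALogP pair used for chemical-space summaries: molecular weight, an
#' atomic-contribution logP estimate, H-bond donor/acceptor counts, and the
#' rotatable-bond count.
#'
#' @param smiles Character vector of SMILES.
#' @return Data frame with columns \code{mw}, \code{alogp}, \code{hbd},
#'   \code{hba}, \code{rotatable_bonds}; one row per compound.
#' @export
property_profile <- function(smiles) {
  bad <- is.na(ob_canonical(smiles))
  if (any(bad)) {
    stop_qsar(sprintf("unparsable SMILES: %s",
                      paste(smiles[bad], collapse = ", ")),
              "qsarnest_parse_error")
  }
  out <- do.call(rbind, lapply(smiles, ob_properties))
  rownames(out) <- NULL
  out
}

#' End-to-end curation of an activity CSV
#'
#' Convenience wrapper chaining [read_activity_table()],
#' [standardize_smiles()], [deduplicate()] and [assign_split()]: the §-style
#' curation recipe of reading, standardizing, merging duplicates by median
#' IC50 and drawing a 3:1 random split.
#'
#' @inheritParams read_activity_table
#' @inheritParams split_train_test
#' @param exclude_ids Optional character vector of ids to drop before
#'   deduplication (manual-review exclusion list).
#' @return A \code{curated_dataset} with splits assigned.
#' @export
curate_activity_table <- function(path, id_col = "id", smiles_col = "smiles",
                                  ic50_col = "ic50_nM", ratio = 0.75,
                                  seed = 1, exclude_ids = NULL) {
  records <- read_activity_table(path, id_col, smiles_col, ic50_col)
  drop_log <- attr(records, "curation_log")
  if (!is.null(exclude_ids)) {
    excluded <- records$id %in% exclude_ids
    if (any(excluded)) {
      drop_log <- rbind(drop_log, data.frame(
        id = records$id[excluded], reason = "manual exclusion list",
        stringsAsFactors = FALSE))
      records <- records[!excluded, , drop = FALSE]
    }
  }
  ds <- deduplicate(records)
  ds$log <- c(
    sprintf("dropped row '%s': %s", drop_log$id, drop_log$reason),
    ds$log
  )
  assign_split(ds, ratio = ratio, seed = seed)
}
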