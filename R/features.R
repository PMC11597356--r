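#' Construct a feature matrix
#'
#' Container pairing an n x p numeric matrix with feature metadata: the
#' feature kind (binary fingerprint bits vs. continuous descriptors),
#' optional per-feature block labels (descriptor families), and a record of
#' features removed by preprocessing filters together with the drop reason.
#'
#' @param values Numeric matrix, rows = compounds, columns = features.
#'   Column names must be unique and non-empty.
#' @param kind "binary" or "continuous".
#' @param blocks Optional named character vector mapping feature names to
#'   block labels.
#' @param dropped Named character vector of drop reasons for features no
#'   longer present in \code{values}.
#' @return A \code{feature_matrix} object.
#' @export
feature_matrix <- function(values, kind = c("continuous", "binary"),
                           blocks = NULL, dropped = character(0)) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  if (anyDuplicated(colnames(values))) {
    stop_qsar("feature names must be unique", "qsarnest_domain_error")
  }
  if (kind == "binary" && !all(values %in% c(0, 1))) {
    stop_qsar("binary feature matrix may contain only 0/1",
              "qsarnest_domain_error")
  }
  structure(list(values = values, kind = kind, blocks = blocks,
                 dropped = dropped),
            class = "feature_matrix")
}

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d compounds x %d %s features",
              nrow(x$values), ncol(x$values), x$kind))
  if (length(x$dropped)) cat(sprintf(" (%d dropped)", length(x$dropped)))
  cat("\n")
  invisible(x)
}

# Accept either a feature_matrix or a bare matrix in downstream code.
fm_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}

#' Compute MACCS structural-key fingerprints
#'
#' Computes the 166-bit MACCS key fingerprint for each compound: bit i is 1
#' when the i-th predefined substructure pattern (e.g. key 42, a fluorine
#' atom) occurs in the molecule.  Computation is deterministic.
#'
#' @param smiles_list Character vector of SMILES; names (or compound ids via
#'   \code{ids}) become row names.
#' @param ids Optional compound ids.
#' @return A binary \code{feature_matrix} with 166 columns named
#'   \code{MACCS_1} .. \code{MACCS_166}.
#' @export
maccs_fingerprints <- function(smiles_list, ids = names(smiles_list)) {
  bad <- is.na(ob_canonical(smiles_list))
  if (any(bad)) {
    labels <- if (!is.null(ids)) ids[bad] else smiles_list[bad]
    stop_qsar(sprintf("unparsable SMILES for: %s", paste(labels, collapse = ", ")),
              "qsarnest_parse_error")
  }
  m <- t(vapply(smiles_list, ob_maccs_row, integer(166)))
  colnames(m) <- paste0("MACCS_", seq_len(166))
  rownames(m) <- ids %||% NULL
  feature_matrix(m, kind = "binary")
}

#' Load a continuous descriptor table from CSV
#'
#' Reads a descriptor table (one row per compound, one column per
#' descriptor) from any descriptor provider, aligns it to a given compound
#' id order, coerces cells to numeric, and drops any descriptor with a
#' missing value (logging the reason).
#'
#' @param path CSV path with an id column and numeric descriptor columns.
#' @param ids Character vector of compound ids defining the row order; every
#'   id must be present in the table.
#' @param id_col Name of the id column.
#' @param block_map Optional path to a 2-column CSV (feature, block) with
#'   descriptor-block labels.
#' @return A continuous \code{feature_matrix} aligned to \code{ids}.
#' @export
load_descriptor_table <- function(path, ids, id_col = "id", block_map = NULL) {
  if (!file.exists(path)) {
    stop_qsar(sprintf("descriptor table not found: %s", path), "qsarnest_io_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!id_col %in% names(raw)) {
    stop_qsar(sprintf("missing id column '%s'", id_col), "qsarnest_schema_error")
  }
  table_ids <- as.character(raw[[id_col]])
  absent <- setdiff(ids, table_ids)
  if (length(absent)) {
    stop_qsar(sprintf("descriptor table lacks compound(s): %s",
                      paste(absent, collapse = ", ")),
              "qsarnest_alignment_error")
  }
  raw <- raw[match(ids, table_ids), setdiff(names(raw), id_col), drop = FALSE]
  values <- vapply(raw, function(col) suppressWarnings(as.numeric(col)),
                   numeric(nrow(raw)))
  values <- matrix(values, nrow = nrow(raw),
                   dimnames = list(ids, setdiff(names(raw), id_col)))
  has_missing <- apply(values, 2, anyNA)
  dropped <- stats::setNames(rep("missing values", sum(has_missing)),
                             colnames(values)[has_missing])
  values <- values[, !has_missing, drop = FALSE]
  blocks <- NULL
  if (!is.null(block_map)) {
    bm <- utils::read.csv(block_map, stringsAsFactors = FALSE)
    blocks <- stats::setNames(as.character(bm[[2]]), as.character(bm[[1]]))
    blocks <- blocks[names(blocks) %in% colnames(values)]
  }
  feature_matrix(values, kind = "continuous", blocks = blocks, dropped = dropped)
}

#' Remove constant and quasi-constant features
#'
#' Constant columns are always dropped.  A column is quasi-constant when the
#' ratio of the most-common to the second-most-common value frequency
#' exceeds \code{freq_ratio} AND its number of distinct values is below
#' \code{unique_pct} percent of the number of rows (near-zero-variance
#' convention).
#'
#' @param fm A \code{feature_matrix} (or plain matrix).
#' @param freq_ratio Frequency-ratio threshold (default 19, i.e. 95/5).
#' @param unique_pct Distinct-value percentage threshold (default 10).
#' @return The filtered \code{feature_matrix}; dropped features and reasons
#'   are appended to its \code{dropped} record.
#' @export
drop_low_variance <- function(fm, freq_ratio = 19, unique_pct = 10) {
  values <- fm_values(fm)
  n <- nrow(values)
  reason <- vapply(seq_len(ncol(values)), function(j) {
    tab <- sort(table(values[, j]), decreasing = TRUE)
    if (length(tab) == 1) return("constant")
    ratio <- tab[[1]] / tab[[2]]
    if (ratio > freq_ratio && 100 * length(tab) / n < unique_pct) {
      return("quasi-constant")
    }
    NA_character_
  }, character(1))
  keep_fm(fm, values, is.na(reason), reason)
}

#' Remove highly correlated features
#'
#' Greedy pairwise-correlation filter: while any absolute Pearson
#' correlation above \code{cutoff} remains, the member of the worst
#' offending pair with the larger mean absolute correlation to all remaining
#' features is removed (ties broken by removing the lexicographically later
#' feature name).  The returned matrix has no pair with |r| > cutoff.
#'
#' @param fm Feature matrix with at least 2 columns.
#' @param cutoff Absolute correlation threshold, default 0.90.
#' @return Filtered \code{feature_matrix}.
#' @export
drop_correlated <- function(fm, cutoff = 0.90) {
  values <- fm_values(fm)
  if (ncol(values) < 2) return(if (inherits(fm, "feature_matrix")) fm else feature_matrix(values))
  r <- abs(suppressWarnings(stats::cor(values)))
  r[is.na(r)] <- 0
  diag(r) <- 0
  keep <- rep(TRUE, ncol(values))
  nms <- colnames(values)
  repeat {
    live <- which(keep)
    sub <- r[live, live, drop = FALSE]
    if (max(sub) <= cutoff) break
    worst <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    a <- live[worst[1]]; b <- live[worst[2]]
    mean_a <- mean(r[a, live])
    mean_b <- mean(r[b, live])
    drop_j <- if (mean_a > mean_b) a
              else if (mean_b > mean_a) b
              else if (nms[a] > nms[b]) a else b
    keep[drop_j] <- FALSE
  }
  reason <- ifelse(keep, NA_character_,
                   sprintf("correlated above %g", cutoff))
  keep_fm(fm, values, keep, reason)
}

keep_fm <- function(fm, values, keep, reason) {
  dropped <- stats::setNames(reason[!keep], colnames(values)[!keep])
  kept <- values[, keep, drop = FALSE]
  if (inherits(fm, "feature_matrix")) {
    feature_matrix(kept, kind = fm$kind, blocks = fm$blocks,
                   dropped = c(fm$dropped, dropped))
  } else {
    feature_matrix(kept, dropped = dropped)
  }
}

#' Fit a centering/scaling transform on training rows
#'
#' Learns per-feature mean and standard deviation on the training rows only,
#' so that applying the transform inside cross-validation leaks no
#' information from held-out rows.  Tree-based learners bypass scaling
#' entirely (their [learner_spec()] declares \code{needs_scaling = FALSE}).
#'
#' @param fm Feature matrix.
#' @param train_idx Integer indices of the training rows.
#' @return A \code{feature_scaler} storing means, sds and the fit indices.
#' @export
fit_scaler <- function(fm, train_idx = seq_len(nrow(fm_values(fm)))) {
  values <- fm_values(fm)[train_idx, , drop = FALSE]
  mu <- colMeans(values)
  sd <- apply(values, 2, stats::sd)
  zero <- sd == 0
  if (any(zero)) {
    stop_qsar(sprintf("zero training variance for feature(s): %s",
                      paste(colnames(values)[zero], collapse = ", ")),
              "qsarnest_domain_error")
  }
  structure(list(mean = mu, sd = sd, fit_idx = train_idx),
            class = "feature_scaler")
}

#' Apply a fitted scaling transform
#'
#' @param scaler A \code{feature_scaler} from [fit_scaler()].
#' @param fm Feature matrix with the same columns as the training data.
#' @return Matrix of standardized values (no clipping: rows outside the
#'   training range map beyond +-1 accordingly).
#' @export
apply_scaler <- function(scaler, fm) {
  values <- fm_values(fm)
  if (!identical(colnames(values), names(scaler$mean))) {
    stop_qsar("feature columns do not match the scaler's training columns",
              "qsarnest_alignment_error")
  }
  sweep(sweep(values, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}
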