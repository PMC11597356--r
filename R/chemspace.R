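#' Tanimoto similarity of two binary fingerprints
#'
#' \eqn{T(a, b) = c / (|a| + |b| - c)} where c is the number of bits set in
#' both vectors.  By convention the similarity of two all-zero fingerprints
#' is 0 (with a warning), since no substructure evidence is shared.
#'
#' @param a,b Binary vectors of equal length.
#' @return Similarity in \[0, 1\]; symmetric in its arguments.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop_qsar("fingerprints differ in length", "qsarnest_domain_error")
  }
  both <- sum(a & b)
  denom <- sum(a) + sum(b) - both
  if (denom == 0) {
    warning("both fingerprints are all-zero; returning similarity 0")
    return(0)
  }
  both / denom
}

# All n(n-1)/2 unique pairwise Tanimoto similarities of the rows of a binary
# matrix, computed via the bit-count identity c_ij / (r_i + r_j - c_ij).
pairwise_tanimoto <- function(m) {
  m <- fm_values(m)
  co <- tcrossprod(m)           # c_ij = shared on-bits
  rs <- rowSums(m)
  denom <- outer(rs, rs, "+") - co
  sims <- ifelse(denom == 0, 0, co / denom)
  sims[upper.tri(sims)]
}

#' Pairwise Tanimoto similarity summary of a compound set
#'
#' Dataset-diversity statistic: the mean and the first/third quartiles of
#' the Tanimoto similarity over all n(n-1)/2 unique unordered compound
#' pairs.  Low values indicate a structurally diverse set.  Quartiles use
#' linear interpolation.
#'
#' @param fm Binary \code{feature_matrix} (or 0/1 matrix) with n >= 2 rows.
#' @return A \code{similarity_summary} list: \code{mean}, \code{q1},
#'   \code{q3}, \code{n_pairs}.
#' @export
pairwise_similarity_summary <- function(fm) {
  m <- fm_values(fm)
  if (nrow(m) < 2) {
    stop_qsar("need at least 2 compounds for a pairwise summary",
              "qsarnest_domain_error")
  }
  sims <- pairwise_tanimoto(m)
  qs <- stats::quantile(sims, c(0.25, 0.75), names = FALSE, type = 7)
  structure(list(mean = mean(sims), q1 = qs[1], q3 = qs[2],
                 n_pairs = length(sims)),
            class = "similarity_summary")
}

#' @export
print.similarity_summary <- function(x, ...) {
  cat(sprintf("Tanimoto similarity over %d pairs: mean %.3f (Q1 %.3f, Q3 %.3f)\n",
              x$n_pairs, x$mean, x$q1, x$q3))
  invisible(x)
}

#' Chemical-space table (MW vs. ALogP)
#'
#' Per-compound molecular weight and logP estimate plus the Lipinski
#' failure count -- the data behind the classic chemical-space scatter plot
#' and drug-likeness histogram.
#'
#' @param smiles Character vector of SMILES.
#' @param ids Optional compound ids.
#' @param five_rules Passed to [lipinski_failures()].
#' @return Data frame with \code{id}, \code{mw}, \code{alogp},
#'   \code{lipinski_failures}.
#' @export
chemical_space_table <- function(smiles, ids = NULL, five_rules = TRUE) {
  prof <- property_profile(smiles)
  data.frame(
    id = ids %||% as.character(seq_along(smiles)),
    mw = prof$mw,
    alogp = prof$alogp,
    lipinski_failures = lipinski_failures(
      prof$mw, prof$alogp, prof$hbd, prof$hba, prof$rotatable_bonds,
      five_rules = five_rules
    ),
    stringsAsFactors = FALSE
  )
}
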