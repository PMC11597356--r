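#' Similarity-based applicability domain for fingerprint models
#'
#' A query compound is inside the applicability domain (AD) when its
#' maximum Tanimoto similarity to any training compound exceeds the
#' threshold (strictly).  The default threshold of 0.20 means a compound
#' sharing less than 20% bit similarity with every training structure is
#' considered too dissimilar for the model's prediction to be trusted.
#'
#' @param train_fps Binary \code{feature_matrix} (or 0/1 matrix) of
#'   training fingerprints, >= 1 row.
#' @param threshold Similarity cutoff in (0, 1), default 0.20.
#' @param statistic "max" (default) compares against the closest training
#'   compound; "mean" against the average similarity to the training set.
#' @return An \code{ad_model} of kind "similarity".
#' @export
fit_similarity_ad <- function(train_fps, threshold = 0.20,
                              statistic = c("max", "mean")) {
  m <- fm_values(train_fps)
  if (nrow(m) < 1) stop_qsar("empty training set", "qsarnest_domain_error")
  if (threshold < 0 || threshold > 1) {
    stop_qsar("similarity threshold must lie in [0, 1]",
              "qsarnest_domain_error")
  }
  structure(list(kind = "similarity", train = m, threshold = threshold,
                 statistic = match.arg(statistic)),
            class = "ad_model")
}

#' Assess one fingerprint against a similarity AD
#'
#' @param model An \code{ad_model} of kind "similarity".
#' @param fp Binary vector of the same length as the training
#'   fingerprints.
#' @return List with \code{score} (the similarity statistic) and
#'   \code{inside} (\code{score > threshold}, strict).
#' @export
assess_similarity <- function(model, fp) {
  if (length(fp) != ncol(model$train)) {
    stop_qsar("fingerprint length does not match the training set",
              "qsarnest_domain_error")
  }
  sims <- vapply(seq_len(nrow(model$train)), function(i) {
    suppressWarnings(tanimoto(model$train[i, ], fp))
  }, numeric(1))
  score <- if (model$statistic == "max") max(sims) else mean(sims)
  list(score = score, inside = score > model$threshold)
}

#' Isolation-forest applicability domain for descriptor models
#'
#' Fits an isolation forest on the training descriptors: an ensemble of
#' random binary trees, each grown on a subsample, in which anomalous
#' points isolate after few random splits.  The anomaly score of a point is
#' \eqn{2^{-E[h]/c(\psi)}} where \eqn{E[h]} is its mean path length over
#' the trees and \eqn{c(\psi)} the expected path length of an unsuccessful
#' binary-search-tree lookup at the subsample size; scores near 1 indicate
#' isolation (outside the training chemical space), scores near or below
#' 0.5 indicate typical points.  A compound is inside the AD when its
#' score is below the threshold.
#'
#' @param train_desc Continuous \code{feature_matrix} (or matrix), n >= 20.
#' @param n_trees Number of isolation trees, default 100.
#' @param ntry Number of candidate features drawn per split; the split
#'   feature is chosen among the drawn candidates that vary in the node.
#' @param threshold Anomaly-score cutoff, default 0.5 (the canonical
#'   anomaly boundary).
#' @param sample_size Subsample size per tree, default min(256, n).
#' @param seed Integer seed; verdicts are deterministic given it.
#' @return An \code{ad_model} of kind "isolation_forest".
#' @export
fit_isoforest_ad <- function(train_desc, n_trees = 100, ntry = 10,
                             threshold = 0.5, sample_size = NULL, seed = 1) {
  m <- fm_values(train_desc)
  if (nrow(m) < 20) {
    stop_qsar("isolation forest needs at least 20 training compounds",
              "qsarnest_domain_error")
  }
  if (anyNA(m) || !all(is.finite(m))) {
    stop_qsar("training descriptors must be finite", "qsarnest_domain_error")
  }
  psi <- min(sample_size %||% 256L, nrow(m))
  max_depth <- ceiling(log2(psi))
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(t) {
      rows <- sample.int(nrow(m), psi)
      grow_itree(m[rows, , drop = FALSE], depth = 0L,
                 max_depth = max_depth, ntry = ntry)
    })
  })
  structure(list(kind = "isolation_forest", trees = trees, psi = psi,
                 threshold = threshold, p = ncol(m),
                 feature_names = colnames(m)),
            class = "ad_model")
}

# Expected path length of unsuccessful BST search among m points.
c_factor <- function(m) {
  if (m <= 1) return(0)
  if (m == 2) return(1)
  2 * (log(m - 1) + 0.5772156649) - 2 * (m - 1) / m
}

grow_itree <- function(m, depth, max_depth, ntry) {
  n <- nrow(m)
  if (n <= 1 || depth >= max_depth) {
    return(list(leaf = TRUE, size = n))
  }
  cand <- sample.int(ncol(m), min(ntry, ncol(m)))
  ranges <- apply(m[, cand, drop = FALSE], 2, function(v) diff(range(v)))
  cand <- cand[ranges > 0]
  if (length(cand) == 0) return(list(leaf = TRUE, size = n))
  j <- if (length(cand) == 1) cand else sample(cand, 1)
  lo <- min(m[, j]); hi <- max(m[, j])
  s <- stats::runif(1, lo, hi)
  left <- m[, j] < s
  list(leaf = FALSE, feature = j, split = s,
       left = grow_itree(m[left, , drop = FALSE], depth + 1L, max_depth, ntry),
       right = grow_itree(m[!left, , drop = FALSE], depth + 1L, max_depth, ntry))
}

itree_path <- function(tree, x, depth = 0) {
  if (tree$leaf) return(depth + c_factor(tree$size))
  if (x[tree$feature] < tree$split) {
    itree_path(tree$left, x, depth + 1)
  } else {
    itree_path(tree$right, x, depth + 1)
  }
}

#' Anomaly scores and AD verdicts from a fitted AD model
#'
#' @param object An \code{ad_model}.
#' @param newdata Matrix of query compounds (fingerprints or descriptors
#'   matching the training feature space).
#' @param ... Unused.
#' @return Data frame with one row per query: \code{score} and
#'   \code{inside}.
#' @export
predict.ad_model <- function(object, newdata, ...) {
  m <- fm_values(newdata)
  if (object$kind == "similarity") {
    out <- lapply(seq_len(nrow(m)), function(i) {
      assess_similarity(object, m[i, ])
    })
    data.frame(score = vapply(out, `[[`, numeric(1), "score"),
               inside = vapply(out, `[[`, logical(1), "inside"))
  } else {
    if (ncol(m) != object$p) {
      stop_qsar("descriptor columns do not match the AD training space",
                "qsarnest_alignment_error")
    }
    cn <- c_factor(object$psi)
    score <- vapply(seq_len(nrow(m)), function(i) {
      paths <- vapply(object$trees, itree_path, numeric(1), x = m[i, ])
      2^(-mean(paths) / cn)
    }, numeric(1))
    data.frame(score = score, inside = score < object$threshold)
  }
}

#' @export
print.ad_model <- function(x, ...) {
  if (x$kind == "similarity") {
    cat(sprintf("Similarity AD (%s Tanimoto > %.2f) over %d training compounds\n",
                x$statistic, x$threshold, nrow(x$train)))
  } else {
    cat(sprintf("Isolation-forest AD (%d trees, score < %.2f)\n",
                length(x$trees), x$threshold))
  }
  invisible(x)
}

#' Applicability-domain coverage table
#'
#' Given per-compound, per-model inside/outside verdicts, counts for each
#' compound how many models accept it, and tabulates the marginal
#' distribution of those counts (how many compounds are inside all M
#' models, inside M-1, ..., inside none).
#'
#' @param verdicts Logical matrix, rows = compounds, columns = models.
#' @return List with \code{per_compound} (integer counts) and
#'   \code{distribution} (data frame: \code{n_inside}, \code{n_compounds},
#'   \code{pct}).
#' @export
ad_coverage <- function(verdicts) {
  verdicts <- as.matrix(verdicts)
  counts <- rowSums(verdicts)
  m <- ncol(verdicts)
  dist <- vapply(0:m, function(k) sum(counts == k), integer(1))
  list(
    per_compound = as.integer(counts),
    distribution = data.frame(
      n_inside = 0:m,
      n_compounds = dist,
      pct = round_half_up(100 * dist / nrow(verdicts), 2)
    )
  )
}
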