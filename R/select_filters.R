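# Information-theoretic filter selection: a shared discrete mutual-
# information estimator plus the CMIM and JMIM greedy criteria.

# Equal-frequency binning.  Variables with few distinct values (binary
# fingerprint bits in particular) keep their original levels.
bin_equal_freq <- function(x, n_bins = 10) {
  u <- unique(x)
  if (length(u) <= n_bins) return(match(x, sort(u)))
  r <- rank(x, ties.method = "average")
  b <- ceiling(r * n_bins / length(x))
  b[b < 1] <- 1L
  as.integer(b)
}

# Plug-in MI (nats) of two integer-coded discrete variables.
mi_disc <- function(a, b) {
  p <- table(a, b) / length(a)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

# Combine two integer codes into one joint code.
joint_code <- function(a, b) {
  (as.integer(factor(a)) - 1L) * length(unique(b)) + as.integer(factor(b))
}

#' Mutual information between two variables (plug-in estimate)
#'
#' Discretizes both variables by equal-frequency binning (variables with at
#' most \code{n_bins} distinct values, such as binary fingerprint bits, keep
#' their levels) and returns the plug-in mutual information
#' \eqn{\sum_{ij} p_{ij} \log(p_{ij} / p_i p_j)} in nats.  A constant
#' vector carries no information and returns 0.
#'
#' @param x,y Numeric vectors of equal length (>= 4).
#' @param n_bins Number of equal-frequency bins, default 10.
#' @return Non-negative mutual information in nats.
#' @export
mutual_information <- function(x, y, n_bins = 10) {
  if (length(x) != length(y) || length(x) < 4) {
    stop_qsar("mutual_information needs two equal-length vectors (n >= 4)",
              "qsarnest_domain_error")
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(0)
  mi_disc(bin_equal_freq(x, n_bins), bin_equal_freq(y, n_bins))
}

selection_result <- function(selected, scores, method, params, seed) {
  structure(list(selected = selected, scores = scores, method = method,
                 params = params, seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d feature(s) selected\n",
              x$method, length(x$selected)))
  if (length(x$selected)) {
    cat("  ", paste(utils::head(x$selected, 10), collapse = ", "),
        if (length(x$selected) > 10) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

# Shared greedy loop for CMIM and JMIM.  Both start from the feature with
# maximal marginal MI with y; they differ in the score kept per candidate:
#   cmim: min over selected s of I(f; y | s)  (conditional MI)
#   jmim: min over selected s of I(f, s; y)   (joint MI)
# Conditional MI is computed on the joint binned table as
# I(f; y | s) = I((f, s); y) - I(s; y).
greedy_mi_select <- function(X, y, k, n_bins, criterion, method, seed) {
  X <- fm_values(X)
  p <- ncol(X)
  k <- min(k, p)
  params <- list(k = k, n_bins = n_bins)
  if (k <= 0) {
    return(selection_result(character(0), numeric(0), method, params, seed))
  }
  by <- bin_equal_freq(y, n_bins)
  bx <- lapply(seq_len(p), function(j) bin_equal_freq(X[, j], n_bins))
  marginal <- vapply(bx, function(b) mi_disc(b, by), numeric(1))

  selected <- integer(0)
  sel_scores <- numeric(0)
  score <- marginal        # running min over the selected set
  repeat {
    cand <- setdiff(seq_len(p), selected)
    best <- cand[which.max(score[cand])]   # ties: lowest column index
    selected <- c(selected, best)
    sel_scores <- c(sel_scores, score[best])
    if (length(selected) >= k) break
    bs <- bx[[best]]
    mi_s <- mi_disc(bs, by)
    if (criterion == "jmim" && length(selected) == 1) {
      # the marginal MI seeded the first pick only; joint MI is bounded
      # below by it, so it must not survive into the running min
      score[] <- Inf
    }
    for (j in setdiff(seq_len(p), selected)) {
      joint <- mi_disc(joint_code(bx[[j]], bs), by)
      val <- if (criterion == "cmim") joint - mi_s else joint
      score[j] <- min(score[j], val)
    }
  }
  nms <- colnames(X) %||% paste0("f", seq_len(p))
  selection_result(nms[selected], stats::setNames(sel_scores, nms[selected]),
                   method, params, seed)
}

#' CMIM feature selection (conditional mutual information maximization)
#'
#' Greedy filter: the first feature maximizes the marginal mutual
#' information with the response; each subsequent pick maximizes
#' \eqn{\min_{s \in S} I(f; y | s)} over already-selected features S, which
#' discounts candidates whose information about y is already carried by a
#' selected feature (an exact copy of a selected feature scores ~0).
#'
#' @param X Feature matrix (binary or continuous).
#' @param y Response vector.
#' @param k Number of features to select.
#' @param n_bins Bins for the MI estimator.
#' @param seed Recorded in the result; the estimator itself is
#'   deterministic.
#' @return A \code{selection_result}.
#' @export
cmim_select <- function(X, y, k = 30, n_bins = 10, seed = NULL) {
  greedy_mi_select(X, y, k, n_bins, "cmim", "cmim", seed)
}

#' JMIM feature selection (joint mutual information maximization)
#'
#' Greedy filter like [cmim_select()] but scoring candidates by
#' \eqn{\min_{s \in S} I(f, s; y)}, the joint mutual information of the
#' candidate together with each selected feature.  JMIM can pick up
#' features that are only informative through interactions: in an XOR-type
#' response neither variable is marginally informative, but once one is
#' selected the partner attains the maximal joint MI.
#'
#' @inheritParams cmim_select
#' @return A \code{selection_result}.
#' @export
jmim_select <- function(X, y, k = 30, n_bins = 10, seed = NULL) {
  greedy_mi_select(X, y, k, n_bins, "jmim", "jmim", seed)
}
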