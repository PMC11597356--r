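#' Boruta all-relevant feature selection
#'
#' Iteratively compares each feature's random-forest importance against
#' "shadow" features -- column-permuted copies that carry the marginal
#' distribution but no association with the response.  Per iteration, the
#' undecided features are shadowed, a random-forest regressor is fit on the
#' original plus shadow columns, and a feature scores a hit when its
#' importance exceeds the maximum shadow importance.  A two-sided binomial
#' test (p = 0.5) on the accumulated hit counts, Bonferroni-corrected across
#' the undecided features in each round, confirms clearly-winning features
#' and rejects clearly-losing ones.  The loop stops when all features are
#' decided or after \code{max_iter} iterations; features still undecided are
#' labelled tentative.
#'
#' @param X Feature matrix (n >= 20 rows).
#' @param y Response vector.
#' @param max_iter Maximum shadow iterations, default 100.
#' @param alpha Test level for the binomial decision test, default 0.05.
#' @param rf_params List of random-forest parameters (\code{num.trees},
#'   \code{mtry}, ...) passed to \code{ranger}.
#' @param include_tentative Also return tentative features as selected.
#' @param seed Integer seed; the whole procedure is reproducible given it.
#' @return A \code{selection_result}; \code{scores} holds each feature's
#'   mean importance over iterations, and the decision per feature
#'   (\code{"confirmed"}, \code{"rejected"}, \code{"tentative"}) is in
#'   \code{params$decision}.
#' @export
boruta_select <- function(X, y, max_iter = 100, alpha = 0.05,
                          rf_params = list(num.trees = 100),
                          include_tentative = FALSE, seed = 1) {
  X <- fm_values(X)
  if (nrow(X) < 20) {
    stop_qsar("boruta_select needs at least 20 observations",
              "qsarnest_domain_error")
  }
  if (anyNA(X) || !all(is.finite(X)) || anyNA(y)) {
    stop_qsar("boruta_select requires finite features and response",
              "qsarnest_domain_error")
  }
  p <- ncol(X)
  nms <- colnames(X) %||% paste0("f", seq_len(p))
  colnames(X) <- nms
  decision <- stats::setNames(rep("tentative", p), nms)
  hits <- stats::setNames(rep(0L, p), nms)
  imp_sum <- stats::setNames(rep(0, p), nms)
  seeds <- derive_seeds(seed, max_iter)

  iter <- 0L
  while (iter < max_iter && any(decision == "tentative")) {
    iter <- iter + 1L
    undecided <- nms[decision == "tentative"]
    res <- with_seed(seeds[iter], {
      # shadow every undecided feature, padding the shadow pool to at
      # least 5 columns for a stable max-shadow reference late in the run
      shadow_src <- undecided
      if (length(shadow_src) < 5 && p > length(shadow_src)) {
        extra <- sample(setdiff(nms, shadow_src),
                        min(5 - length(shadow_src), p - length(shadow_src)))
        shadow_src <- c(shadow_src, extra)
      }
      shadows <- apply(X[, shadow_src, drop = FALSE], 2, sample)
      colnames(shadows) <- paste0(".shadow.", shadow_src)
      imp <- rf_importance(cbind(X, shadows), y, rf_params,
                           seed = seeds[iter])
      list(real = imp[nms], shadow_max = max(imp[colnames(shadows)]))
    })
    imp_sum <- imp_sum + res$real
    hits[undecided] <- hits[undecided] +
      (res$real[undecided] > res$shadow_max)

    # two-sided binomial test at level alpha, Bonferroni over undecided
    m <- length(undecided)
    p_win <- stats::pbinom(hits[undecided] - 1L, iter, 0.5, lower.tail = FALSE)
    p_lose <- stats::pbinom(hits[undecided], iter, 0.5)
    decision[undecided][p_win < alpha / (2 * m)] <- "confirmed"
    decision[undecided][p_lose < alpha / (2 * m)] <- "rejected"
  }

  wanted <- if (include_tentative) c("confirmed", "tentative") else "confirmed"
  selected <- nms[decision %in% wanted]
  selection_result(
    selected,
    scores = imp_sum / iter,
    method = "boruta",
    params = list(max_iter = max_iter, alpha = alpha, iterations = iter,
                  decision = decision, rf_params = rf_params,
                  include_tentative = include_tentative),
    seed = seed
  )
}

# Permutation importance from a seeded random forest; shared by Boruta.
rf_importance <- function(X, y, rf_params, seed) {
  args <- c(list(
    x = X, y = y,
    importance = "permutation",
    seed = seed,
    num.threads = 1,
    respect.unordered.factors = FALSE
  ), rf_params)
  fit <- do.call(ranger::ranger, args)
  fit$variable.importance
}
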