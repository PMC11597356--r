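#' Rp-squared y-randomization validity statistic
#'
#' Combines the genuine model's cross-validated R-squared with the mean
#' R-squared of response-permuted models into
#' \deqn{R_p^2 = \sqrt{R^2} \cdot \sqrt{R^2 - R_r^2}.}
#' A valid model has \eqn{R_r^2} near zero (often negative for pooled
#' out-of-fold metrics) and \eqn{R_p^2} close to its genuine \eqn{R^2}.
#' When the permuted models outperform the genuine one
#' (\eqn{R^2 < R_r^2}) the statistic is undefined and \code{NA} is
#' returned with a warning.
#'
#' @param r2_true Genuine-model R-squared.
#' @param rr2_mean Mean R-squared over the permuted-response runs.
#' @return The Rp-squared value, or NA when undefined.
#' @export
#' @examples
#' rp_squared(0.719, -0.113)  # 0.773
rp_squared <- function(r2_true, rr2_mean) {
  if (r2_true < rr2_mean) {
    warning("Rp-squared undefined: permuted models outperform the genuine model")
    return(NA_real_)
  }
  if (r2_true < 0) {
    warning("Rp-squared undefined for a negative genuine R-squared")
    return(NA_real_)
  }
  sqrt(r2_true) * sqrt(r2_true - rr2_mean)
}

#' y-randomization (response scrambling) test
#'
#' Permutes the response \code{n_perm} times and, for each permutation,
#' reruns the entire pipeline from scratch -- preprocessing filters,
#' feature selection, hyperparameter tuning and nested cross-validation --
#' on the scrambled data.  If the genuine model's performance reflected a
#' real structure-activity relationship, the permuted runs should collapse
#' to chance level (mean permuted R-squared, \code{rr2_mean}, near or
#' below zero).  The Rp-squared statistic summarizes the contrast.
#'
#' @inheritParams nested_cv
#' @param genuine A fitted \code{nested_cv} result for the unpermuted data
#'   (the reference performance), or NULL to fit it here.
#' @param n_perm Number of response permutations, default 20.
#' @param seed Seed controlling the permutations and all derived runs.
#' @return A \code{y_randomization} object: per-permutation metric sets,
#'   \code{rr2_mean}, and \code{rp2}.
#' @export
y_randomize <- function(X, y, learner, selector = selector_spec("none"),
                        outer_folds = 10, inner_folds = 10, tune_budget = 10,
                        preprocess = TRUE, genuine = NULL, n_perm = 20,
                        seed = 1) {
  seeds <- derive_seeds(seed, 2 * n_perm + 1)
  if (is.null(genuine)) {
    genuine <- nested_cv(X, y, learner, selector, outer_folds, inner_folds,
                         tune_budget, preprocess, seed = seeds[1])
  }
  stopifnot(inherits(genuine, "nested_cv"))
  runs <- lapply(seq_len(n_perm), function(i) {
    y_perm <- with_seed(seeds[1 + i], sample(y))
    nested_cv(X, y_perm, learner, selector, outer_folds, inner_folds,
              tune_budget, preprocess, seed = seeds[1 + n_perm + i])$metrics
  })
  rr2_mean <- mean(vapply(runs, `[[`, numeric(1), "r2"))
  structure(list(
    genuine = genuine$metrics,
    permuted = runs,
    n_perm = n_perm,
    rr2_mean = rr2_mean,
    rp2 = suppressWarnings(rp_squared(genuine$metrics$r2, rr2_mean)),
    seed = seed
  ), class = "y_randomization")
}

#' @export
print.y_randomization <- function(x, ...) {
  cat(sprintf("y-randomization over %d permutations:\n", x$n_perm))
  cat(sprintf("  genuine R2 %.3f | mean permuted Rr2 %.3f | Rp2 %s\n",
              x$genuine$r2, x$rr2_mean,
              if (is.na(x$rp2)) "undefined" else sprintf("%.3f", x$rp2)))
  invisible(x)
}
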