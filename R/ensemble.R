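#' Pick the replicate whose CCC is closest to the replicate mean
#'
#' When stacking uses out-of-fold predictions from replicated nested CV,
#' one replicate must represent each base model.  The representative is
#' the replicate whose CCC lies closest to the mean CCC over all
#' replicates (ties resolve to the earlier replicate), so the stacked
#' inputs are typical rather than lucky runs.
#'
#' @param replicates A \code{cv_replicates} object, or a numeric vector of
#'   per-replicate CCC values.
#' @return Integer index of the representative replicate.
#' @export
select_representative_seed <- function(replicates) {
  cccs <- if (inherits(replicates, "cv_replicates")) {
    vapply(replicates$results, function(r) r$metrics$ccc, numeric(1))
  } else {
    as.numeric(replicates)
  }
  if (length(cccs) == 0) {
    stop_qsar("need at least one replicate", "qsarnest_domain_error")
  }
  which.min(abs(cccs - mean(cccs)))  # ties: earliest index
}

#' Assemble the stacking meta-feature matrix
#'
#' One column per base model, holding that model's out-of-fold predictions
#' from the outer loop of its nested cross-validation.  Because every
#' prediction was made by a model that never saw the compound, a
#' meta-learner trained on this matrix is leakage-free.
#'
#' @param base_results Named list (>= 2) of \code{nested_cv} objects (or
#'   plain numeric prediction vectors) sharing the same compound order.
#' @return A continuous \code{feature_matrix}, n compounds x m base models.
#' @export
build_meta_matrix <- function(base_results) {
  if (length(base_results) < 2) {
    stop_qsar("stacking needs at least 2 base models", "qsarnest_domain_error")
  }
  cols <- lapply(base_results, function(r) {
    if (inherits(r, "nested_cv")) r$oof else as.numeric(r)
  })
  n <- unique(vapply(cols, length, integer(1)))
  if (length(n) != 1) {
    stop_qsar("base models predict different compound sets",
              "qsarnest_alignment_error")
  }
  m <- do.call(cbind, cols)
  colnames(m) <- names(base_results) %||% paste0("base_", seq_along(cols))
  feature_matrix(m, kind = "continuous")
}

#' Nested cross-validation of a stacking meta-learner
#'
#' Runs [nested_cv()] of the meta-learner on the meta-feature matrix (no
#' feature-selection stage and no preprocessing filters: the handful of
#' base-model columns are all kept), giving an honest estimate of the
#' stacked ensemble's performance.
#'
#' @param meta A meta matrix from [build_meta_matrix()] (or a list of base
#'   results, which is assembled first).
#' @param y Observed response.
#' @param meta_learner [learner_spec()] for the meta-learner.
#' @param outer_folds,inner_folds,tune_budget As in [nested_cv()].
#' @param seed Integer seed (folds are drawn independently of the base
#'   models' folds).
#' @return A \code{nested_cv} object for the ensemble.
#' @export
evaluate_ensemble <- function(meta, y, meta_learner = learner_spec("svm_rbf"),
                              outer_folds = 10, inner_folds = 10,
                              tune_budget = 10, seed = 1) {
  if (!inherits(meta, "feature_matrix")) meta <- build_meta_matrix(meta)
  nested_cv(meta$values, y, meta_learner, selector = selector_spec("none"),
            outer_folds = outer_folds, inner_folds = inner_folds,
            tune_budget = tune_budget, preprocess = FALSE, seed = seed)
}

#' Fit a deployable stacked ensemble
#'
#' For screening-time use: refits every base model on the full training
#' set and trains the meta-learner on the base models' out-of-fold
#' predictions (the leakage-safe meta features).  Predicting a new
#' compound runs each base model and feeds their outputs to the
#' meta-learner.
#'
#' @param base_models Named list (>= 2) of fitted \code{qsar_model}s, all
#'   trained on the same feature space.
#' @param meta A meta matrix from [build_meta_matrix()] holding the base
#'   models' out-of-fold predictions, column order matching
#'   \code{base_models}.
#' @param y Training response.
#' @param meta_learner [learner_spec()] for the meta-learner.
#' @param tuned_params Optional parameter list for the meta-learner.
#' @return A \code{stacked_ensemble} supporting [predict()].
#' @export
fit_stacked_ensemble <- function(base_models, meta, y,
                                 meta_learner = learner_spec("svm_rbf"),
                                 tuned_params = NULL) {
  if (!inherits(meta, "feature_matrix")) meta <- build_meta_matrix(meta)
  if (length(base_models) != ncol(meta$values)) {
    stop_qsar("one meta column per base model is required",
              "qsarnest_alignment_error")
  }
  meta_model <- fit_learner(meta_learner, meta$values, y,
                            params = tuned_params)
  structure(list(base_models = base_models, meta_model = meta_model,
                 meta_names = colnames(meta$values)),
            class = "stacked_ensemble")
}

#' @export
predict.stacked_ensemble <- function(object, newdata, ...) {
  preds <- vapply(object$base_models, function(m) predict(m, newdata),
                  numeric(nrow(fm_values(newdata))))
  preds <- matrix(preds, ncol = length(object$base_models),
                  dimnames = list(NULL, object$meta_names))
  predict(object$meta_model, preds)
}

#' @export
print.stacked_ensemble <- function(x, ...) {
  cat(sprintf("<stacked_ensemble> %d base models -> %s meta-learner\n",
              length(x$base_models), x$meta_model$spec$name))
  invisible(x)
}
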