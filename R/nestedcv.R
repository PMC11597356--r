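#' Describe a feature-selection stage
#'
#' Pairs a selection method with its parameters, for use inside
#' cross-validation where selection must be re-run on every training
#' partition.
#'
#' @param method One of "none" (keep all features), "cmim", "jmim",
#'   "boruta", "ga".
#' @param ... Method parameters (e.g. \code{k} for the MI filters,
#'   \code{max_iter} for Boruta, \code{learner_spec} for the GA).
#' @return A \code{selector_spec} object.
#' @export
selector_spec <- function(method = c("none", "cmim", "jmim", "boruta", "ga"),
                          ...) {
  method <- match.arg(method)
  structure(list(method = method, params = list(...)), class = "selector_spec")
}

run_selector <- function(selector, X, y, seed) {
  X <- fm_values(X)
  p <- selector$params
  switch(selector$method,
    none = colnames(X),
    cmim = cmim_select(X, y, k = p$k %||% 30, n_bins = p$n_bins %||% 10,
                       seed = seed)$selected,
    jmim = jmim_select(X, y, k = p$k %||% 30, n_bins = p$n_bins %||% 10,
                       seed = seed)$selected,
    boruta = boruta_select(
      X, y,
      max_iter = p$max_iter %||% 50,
      alpha = p$alpha %||% 0.05,
      rf_params = p$rf_params %||% list(num.trees = 100),
      include_tentative = p$include_tentative %||% FALSE,
      seed = seed
    )$selected,
    ga = ga_select(
      X, y, learner_spec = p$learner_spec %||% learner_spec("linear"),
      pop_size = p$pop_size %||% 20, generations = p$generations %||% 10,
      fitness_folds = p$fitness_folds %||% 3, seed = seed
    )$selected
  )
}

#' Nested cross-validation of a selection + learning pipeline
#'
#' Estimates out-of-sample performance with two nested loops.  The outer
#' loop partitions the compounds into \code{outer_folds} folds; for each
#' fold, preprocessing filters (constant/quasi-constant then correlation),
#' feature selection and hyperparameter tuning (random search scored by
#' inner-loop CV RMSE) run on the outer-training partition only, and the
#' tuned model predicts the held-out fold.  Every compound is predicted
#' exactly once; the pooled out-of-fold vector yields the reported metrics
#' (R-squared as "true q2", Lin's CCC, RMSE).
#'
#' The separation matters: selecting features or hyperparameters on data
#' that later serves as a test set inflates performance estimates, which is
#' exactly what nested CV exists to prevent.
#'
#' @param X Feature matrix.
#' @param y Response (pIC50 scale in the QSAR setting).
#' @param learner A [learner_spec()].
#' @param selector A [selector_spec()]; default keeps all features.
#' @param outer_folds,inner_folds Fold counts (outer loop and tuning loop).
#' @param tune_budget Random-search configurations per outer fold.
#' @param preprocess Run the variance/correlation filters per outer fold.
#' @param seed Integer seed; folds, selection, tuning and learners all
#'   derive from it.
#' @return A \code{nested_cv} object: out-of-fold predictions
#'   (\code{oof}), the fold assignment, per-fold selected features and
#'   tuned parameters, and a \code{metric_set}.
#' @export
nested_cv <- function(X, y, learner, selector = selector_spec("none"),
                      outer_folds = 10, inner_folds = 10, tune_budget = 10,
                      preprocess = TRUE, seed = 1) {
  X <- fm_values(X)
  n <- nrow(X)
  if (n < outer_folds * 2) {
    stop_qsar("need at least 2 observations per outer fold",
              "qsarnest_domain_error")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  seeds <- derive_seeds(seed, 3 * outer_folds + 1)
  folds <- cv_folds(n, outer_folds, seed = seeds[1])
  oof <- rep(NA_real_, n)
  per_fold <- vector("list", outer_folds)

  for (f in seq_len(outer_folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(n), test_idx)
    s_sel <- seeds[1 + f]; s_tune <- seeds[1 + outer_folds + f]
    s_fit <- seeds[1 + 2 * outer_folds + f]

    X_tr <- X[train_idx, , drop = FALSE]
    if (preprocess) {
      fmat <- drop_correlated(drop_low_variance(feature_matrix(X_tr)))
      X_tr <- fmat$values
    }
    result <- tryCatch({
      feats <- run_selector(selector, X_tr, y[train_idx], seed = s_sel)
      if (length(feats) == 0) feats <- fallback_feature(X_tr, y[train_idx])
      spec_f <- learner
      spec_f$seed <- s_fit
      tuned <- tune_learner(spec_f, X_tr[, feats, drop = FALSE], y[train_idx],
                            folds = inner_folds, budget = tune_budget,
                            seed = s_tune)
      model <- fit_learner(spec_f, X_tr[, feats, drop = FALSE], y[train_idx],
                           params = tuned$params)
      pred <- predict(model, X[test_idx, feats, drop = FALSE])
      list(features = feats, params = tuned$params, pred = pred, error = NULL)
    }, qsarnest_error = function(e) {
      list(features = character(0), params = NULL, pred = NULL,
           error = conditionMessage(e))
    })
    if (is.null(result$error)) oof[test_idx] <- result$pred
    per_fold[[f]] <- result[c("features", "params", "error")]
  }

  done <- !is.na(oof)
  if (sum(done) < 3) {
    stop_qsar("nested CV failed on (nearly) all folds", "qsarnest_domain_error")
  }
  structure(list(
    seed = seed, oof = oof, y = y, folds = folds, per_fold = per_fold,
    metrics = metric_set(y[done], oof[done]),
    learner = learner$name, selector = selector$method,
    outer_folds = outer_folds, inner_folds = inner_folds
  ), class = "nested_cv")
}

# Last-resort single feature: the column with maximal marginal MI.
fallback_feature <- function(X, y) {
  mi <- vapply(seq_len(ncol(X)), function(j) {
    tryCatch(mutual_information(X[, j], y), error = function(e) -Inf)
  }, numeric(1))
  if (!any(is.finite(mi)) || max(mi) <= 0 && all(apply(X, 2, stats::sd) == 0)) {
    stop_qsar("no usable feature for fallback selection",
              "qsarnest_domain_error")
  }
  colnames(X)[which.max(mi)]
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf("Nested CV (%d outer x %d inner folds, seed %d): %s + %s\n",
              x$outer_folds, x$inner_folds, x$seed, x$selector, x$learner))
  print(x$metrics)
  invisible(x)
}

#' @export
summary.nested_cv <- function(object, ...) {
  n_feats <- vapply(object$per_fold, function(f) length(f$features), integer(1))
  cat(sprintf("Nested CV of %s (selection: %s)\n", object$learner,
              object$selector))
  print(object$metrics)
  cat(sprintf("Selected features per outer fold: median %g (range %d-%d)\n",
              stats::median(n_feats), min(n_feats), max(n_feats)))
  failed <- sum(!vapply(object$per_fold, function(f) is.null(f$error),
                        logical(1)))
  if (failed) cat(sprintf("%d fold(s) failed and were skipped\n", failed))
  invisible(object)
}

#' @export
residuals.nested_cv <- function(object, ...) object$y - object$oof

#' Replicate nested cross-validation over several seeds
#'
#' Repeats [nested_cv()] with different random seeds to separate genuine
#' model quality from seed luck, and reports the per-metric mean and
#' sample (n-1) standard deviation, rounded half-up to 3 decimals for
#' reporting.
#'
#' @inheritParams nested_cv
#' @param seeds Integer vector of seeds (>= 2 for an sd), default 5 seeds.
#' @return A \code{cv_replicates} object: the per-seed \code{nested_cv}
#'   results and a summary table.
#' @export
replicate_nested_cv <- function(X, y, learner, selector = selector_spec("none"),
                                outer_folds = 10, inner_folds = 10,
                                tune_budget = 10, preprocess = TRUE,
                                seeds = 1:5) {
  results <- lapply(seeds, function(s) {
    nested_cv(X, y, learner, selector, outer_folds, inner_folds,
              tune_budget, preprocess, seed = s)
  })
  structure(list(results = results, seeds = seeds,
                 summary = replicate_summary(results)),
            class = "cv_replicates")
}

replicate_summary <- function(results) {
  per_seed <- t(vapply(results, function(r) {
    c(r2 = r$metrics$r2, ccc = r$metrics$ccc, rmse = r$metrics$rmse)
  }, numeric(3)))
  data.frame(
    metric = colnames(per_seed),
    mean = round_half_up(colMeans(per_seed), 3),
    sd = if (nrow(per_seed) >= 2) {
      round_half_up(apply(per_seed, 2, stats::sd), 3)
    } else {
      NA_real_
    },
    row.names = NULL
  )
}

#' Aggregate replicate metric values
#'
#' Mean and sample standard deviation of one metric over replicate runs,
#' rounded half-up to 3 decimals (the table-reporting convention).  Exposed
#' directly so that published per-seed values can be aggregated without
#' rerunning models.
#'
#' @param values Numeric vector of per-seed metric values.
#' @return List with \code{mean} and \code{sd} (NA when fewer than 2
#'   values).
#' @export
aggregate_replicates <- function(values) {
  list(
    mean = round_half_up(mean(values), 3),
    sd = if (length(values) >= 2) round_half_up(stats::sd(values), 3)
         else NA_real_
  )
}

#' @export
print.cv_replicates <- function(x, ...) {
  cat(sprintf("Nested CV over %d seeds (%s + %s):\n", length(x$seeds),
              x$results[[1]]$selector, x$results[[1]]$learner))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-5s %.3f (%.3f)\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}
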