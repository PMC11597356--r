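#' Permutation feature importance
#'
#' Model-agnostic importance: for each feature, the increase in prediction
#' RMSE after randomly permuting that feature's column, averaged over
#' \code{n_repeats} permutations.  Features the model does not rely on
#' score near zero; a negative value is sampling noise.
#'
#' @param model A fitted \code{qsar_model}.
#' @param X Feature matrix with the model's training columns.
#' @param y Observed response for the rows of \code{X}.
#' @param n_repeats Permutations per feature (>= 1), default 10.
#' @param seed Integer seed.
#' @return Named numeric vector of mean RMSE increases, sorted decreasing.
#' @export
permutation_importance <- function(model, X, y, n_repeats = 10, seed = 1) {
  X <- fm_values(X)
  if (n_repeats < 1) {
    stop_qsar("n_repeats must be at least 1", "qsarnest_domain_error")
  }
  baseline <- rmse(y, predict(model, X))
  with_seed(seed, {
    imp <- vapply(seq_len(ncol(X)), function(j) {
      mean(vapply(seq_len(n_repeats), function(r) {
        Xp <- X
        Xp[, j] <- sample(Xp[, j])
        rmse(y, predict(model, Xp)) - baseline
      }, numeric(1)))
    }, numeric(1))
    sort(stats::setNames(imp, colnames(X)), decreasing = TRUE)
  })
}

#' Partial dependence of a model on one feature
#'
#' The average model prediction as the chosen feature is swept over a
#' quantile grid while all other features keep their observed values.  The
#' curve visualizes the direction and shape of the feature-activity
#' relationship implied by the model (e.g. whether adding a substructure
#' raises predicted potency).
#'
#' @param model A fitted \code{qsar_model}.
#' @param X Feature matrix with the model's training columns.
#' @param feature Feature name to sweep.
#' @param grid_size Number of grid points (quantile grid over the observed
#'   values; a binary feature yields a 2-point grid, a constant feature a
#'   single point).
#' @return Data frame with columns \code{value} (grid) and \code{yhat}
#'   (mean prediction).
#' @export
partial_dependence <- function(model, X, feature, grid_size = 20) {
  X <- fm_values(X)
  if (!feature %in% colnames(X)) {
    stop_qsar(sprintf("feature '%s' not in the matrix", feature),
              "qsarnest_domain_error")
  }
  obs <- X[, feature]
  grid <- if (length(unique(obs)) <= grid_size) {
    sort(unique(obs))
  } else {
    unique(stats::quantile(obs, probs = seq(0, 1, length.out = grid_size),
                           names = FALSE, type = 7))
  }
  yhat <- vapply(grid, function(g) {
    Xg <- X
    Xg[, feature] <- g
    mean(predict(model, Xg))
  }, numeric(1))
  data.frame(value = grid, yhat = yhat)
}
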