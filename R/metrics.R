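#' Coefficient of determination on out-of-fold predictions (true q-squared)
#'
#' Computes \eqn{R^2 = 1 - \sum (y - \hat y)^2 / \sum (y - \bar y)^2}, where
#' \eqn{\bar y} is the mean of the observed values over the same pooled set.
#' When \code{yhat} holds predictions for compounds never seen by the model
#' that produced them (out-of-fold predictions pooled over a cross-validation
#' outer loop), this is the "true q2" generalization estimate.  The value may
#' be negative when the model predicts worse than the constant mean.
#'
#' @param y Observed response (numeric, length >= 3, non-constant).
#' @param yhat Predicted response, same length as \code{y}.
#' @return A single numeric value, at most 1.
#' @seealso [ccc()], [rmse()]
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1.1, 2.0, 2.9))  # 0.99
r_squared <- function(y, yhat) {
  check_metric_input(y, yhat)
  if (stats::sd(y) == 0) {
    stop_qsar("r_squared is undefined for a constant observed response",
              "qsarnest_domain_error")
  }
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between observed and predicted values, penalizing both scatter
#' and location/scale shift:
#' \deqn{CCC = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)}
#' with population (1/n) moments as in Lin's original definition.  A model
#' can have perfect Pearson correlation yet CCC < 1 if its predictions are
#' shifted or rescaled, which makes CCC a conservative external-validation
#' metric for QSAR models.
#'
#' @param y Observed response.
#' @param yhat Predicted response.
#' @param sample_moments Use (n-1)-denominator moments instead of Lin's
#'   population moments.  Both variants coincide as n grows.
#' @return Numeric in \[-1, 1\].
#' @export
#' @examples
#' ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7: perfect correlation, unit shift
ccc <- function(y, yhat, sample_moments = FALSE) {
  check_metric_input(y, yhat)
  n <- length(y)
  denom_n <- if (sample_moments) n - 1 else n
  mx <- mean(y); my <- mean(yhat)
  sx2 <- sum((y - mx)^2) / denom_n
  sy2 <- sum((yhat - my)^2) / denom_n
  sxy <- sum((y - mx) * (yhat - my)) / denom_n
  if (sx2 == 0 && sy2 == 0) {
    stop_qsar("ccc is undefined when both vectors are constant",
              "qsarnest_domain_error")
  }
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Root mean squared error
#'
#' @param y Observed response.
#' @param yhat Predicted response.
#' @return Non-negative numeric, in response units (pIC50 for potency models).
#' @export
rmse <- function(y, yhat) {
  check_metric_input(y, yhat, min_n = 1)
  sqrt(mean((y - yhat)^2))
}

#' Bundle the three validation metrics
#'
#' Convenience constructor used throughout the cross-validation machinery:
#' computes R-squared (true q2), Lin's CCC and RMSE on one pooled
#' observed/predicted pair.
#'
#' @inheritParams r_squared
#' @return A \code{metric_set} list with elements \code{r2}, \code{ccc},
#'   \code{rmse}.
#' @export
metric_set <- function(y, yhat) {
  structure(
    list(r2 = r_squared(y, yhat), ccc = ccc(y, yhat), rmse = rmse(y, yhat)),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, digits = 3, ...) {
  cat(sprintf("R2 = %.*f, CCC = %.*f, RMSE = %.*f\n",
              digits, x$r2, digits, x$ccc, digits, x$rmse))
  invisible(x)
}

check_metric_input <- function(y, yhat, min_n = 3) {
  if (length(y) != length(yhat)) {
    stop_qsar("observed and predicted vectors differ in length",
              "qsarnest_domain_error")
  }
  if (length(y) < min_n) {
    stop_qsar(sprintf("need at least %d observations", min_n),
              "qsarnest_domain_error")
  }
  if (anyNA(y) || anyNA(yhat) || !all(is.finite(c(y, yhat)))) {
    stop_qsar("metric input must be finite and free of missing values",
              "qsarnest_domain_error")
  }
  invisible(TRUE)
}
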