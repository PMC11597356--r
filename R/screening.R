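#' Consensus of multiple model predictions under AD gating
#'
#' Aggregates one compound's predictions across models, trusting only the
#' models whose applicability domain contains the compound: the mean and
#' median pIC50 over inside-AD predictions, and their relative standard
#' deviation (RSD, 100 * sd / mean with sample sd) as an inter-model
#' agreement measure.  With fewer than 2 trusted predictions the RSD is
#' undefined (NA); with none, the compound is flagged and no aggregate is
#' reported.
#'
#' @param predictions Numeric vector, one prediction per model.
#' @param verdicts Logical vector, per-model inside-AD verdicts.
#' @param sample_sd Use sample (n-1) sd in the RSD (default) or the
#'   population variant.
#' @return A one-row data frame: \code{n_models}, \code{n_inside},
#'   \code{mean_pic50}, \code{median_pic50}, \code{rsd_pct}.
#' @export
consensus <- function(predictions, verdicts, sample_sd = TRUE) {
  if (length(predictions) != length(verdicts) || length(predictions) < 1) {
    stop_qsar("predictions and verdicts must be equal-length (>= 1)",
              "qsarnest_domain_error")
  }
  trusted <- predictions[verdicts]
  k <- length(trusted)
  if (k == 0) {
    return(data.frame(n_models = length(predictions), n_inside = 0L,
                      mean_pic50 = NA_real_, median_pic50 = NA_real_,
                      rsd_pct = NA_real_))
  }
  mu <- mean(trusted)
  rsd <- if (k >= 2) {
    s <- stats::sd(trusted)
    if (!sample_sd) s <- s * sqrt((k - 1) / k)
    100 * s / mu
  } else {
    NA_real_
  }
  data.frame(n_models = length(predictions), n_inside = as.integer(k),
             mean_pic50 = mu, median_pic50 = stats::median(trusted),
             rsd_pct = rsd)
}

#' AD-gated consensus virtual screening of a compound library
#'
#' Runs every (model, AD) pair over a screening library: each model
#' predicts pIC50 for every compound, its AD decides whether the
#' prediction is trustworthy, and per-compound consensus statistics are
#' aggregated over the trusted predictions.  An optional stacked ensemble
#' contributes an additional un-gated prediction column.
#'
#' @param features Feature matrix of the library compounds (same feature
#'   space as the models' training data).
#' @param models Named list of fitted \code{qsar_model}s.
#' @param ad_models Named list of \code{ad_model}s, parallel to
#'   \code{models}.  An AD may see a different feature representation:
#'   supply \code{ad_features} when the ADs were fit on other columns.
#' @param ids Optional compound ids.
#' @param ensemble Optional \code{stacked_ensemble} for the extra column.
#' @param ad_features Optional feature matrix for the AD assessment
#'   (defaults to \code{features}).
#' @param sample_sd Passed to [consensus()].
#' @return A \code{screening_result}: per-compound data frame plus the
#'   verdict and prediction matrices.
#' @export
screen_library <- function(features, models, ad_models, ids = NULL,
                           ensemble = NULL, ad_features = NULL,
                           sample_sd = TRUE) {
  if (length(models) < 1 || length(models) != length(ad_models)) {
    stop_qsar("need one AD model per prediction model",
              "qsarnest_domain_error")
  }
  X <- fm_values(features)
  Xad <- if (is.null(ad_features)) X else fm_values(ad_features)
  n <- nrow(X)
  preds <- vapply(models, function(m) predict(m, X), numeric(n))
  verdicts <- vapply(ad_models, function(a) predict(a, Xad)$inside, logical(n))
  preds <- matrix(preds, nrow = n)
  verdicts <- matrix(verdicts, nrow = n)
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    consensus(preds[i, ], verdicts[i, ], sample_sd = sample_sd)
  }))
  rows <- cbind(data.frame(id = ids %||% as.character(seq_len(n))), rows)
  if (!is.null(ensemble)) rows$ensemble_pic50 <- predict(ensemble, X)
  structure(list(table = rows, predictions = preds, verdicts = verdicts,
                 model_names = names(models) %||%
                   paste0("model_", seq_along(models))),
            class = "screening_result")
}

#' Summary report of a screening run
#'
#' Counts compounds whose consensus mean or median pIC50 reaches a potency
#' threshold, the AD-coverage distribution, and the RSD distribution
#' summary.
#'
#' @param object A \code{screening_result}.
#' @param threshold_pic50 Potency threshold, default 8 (IC50 <= 10 nM).
#' @param ... Unused.
#' @return List with \code{threshold_pic50}, \code{threshold_ic50_nM},
#'   hit counts and rates, \code{ad_distribution}, and \code{rsd} summary
#'   statistics.
#' @export
summary.screening_result <- function(object, threshold_pic50 = 8, ...) {
  tab <- object$table
  n <- nrow(tab)
  mean_hits <- sum(tab$mean_pic50 >= threshold_pic50, na.rm = TRUE)
  median_hits <- sum(tab$median_pic50 >= threshold_pic50, na.rm = TRUE)
  rsd <- tab$rsd_pct[!is.na(tab$rsd_pct)]
  out <- list(
    n_screened = n,
    threshold_pic50 = threshold_pic50,
    threshold_ic50_nM = pic50_to_ic50(threshold_pic50),
    n_mean_hits = mean_hits,
    n_median_hits = median_hits,
    mean_hit_rate_pct = hit_rate(mean_hits, n),
    ad_distribution = ad_coverage(object$verdicts)$distribution,
    rsd = if (length(rsd)) {
      c(mean = mean(rsd), median = stats::median(rsd), min = min(rsd),
        max = max(rsd), q3 = stats::quantile(rsd, 0.75, names = FALSE))
    } else {
      NULL
    }
  )
  if (!is.null(tab$ensemble_pic50)) {
    out$n_ensemble_hits <- sum(tab$ensemble_pic50 >= threshold_pic50)
    out$ensemble_hit_rate_pct <- hit_rate(out$n_ensemble_hits, n)
  }
  class(out) <- "screening_summary"
  out
}

#' @export
print.screening_summary <- function(x, ...) {
  cat(sprintf("Screened %d compounds; threshold pIC50 >= %g (IC50 <= %g nM)\n",
              x$n_screened, x$threshold_pic50, x$threshold_ic50_nM))
  cat(sprintf("  mean-consensus hits:   %d (%.2f%%)\n", x$n_mean_hits,
              x$mean_hit_rate_pct))
  cat(sprintf("  median-consensus hits: %d\n", x$n_median_hits))
  if (!is.null(x$n_ensemble_hits)) {
    cat(sprintf("  ensemble hits:         %d (%.2f%%)\n", x$n_ensemble_hits,
                x$ensemble_hit_rate_pct))
  }
  invisible(x)
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> %d compounds x %d models\n",
              nrow(x$table), length(x$model_names)))
  invisible(x)
}

#' Hit rate as a percentage
#'
#' @param n_hits Number of hits.
#' @param n_total Total screened (> 0).
#' @return 100 * n_hits / n_total, rounded half-up to 2 decimals.
#' @export
#' @examples
#' hit_rate(168, 219897)  # 0.08
hit_rate <- function(n_hits, n_total) {
  if (n_total <= 0) stop_qsar("n_total must be positive", "qsarnest_domain_error")
  round_half_up(100 * n_hits / n_total, 2)
}
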