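# Regression-learner registry.  Every learner is exposed through the same
# fit/predict surface so that cross-validation, tuning, GA selection and
# stacking can treat them interchangeably.  Scale-sensitive learners
# declare needs_scaling and are fed standardized features internally
# (statistics learned on their own training rows); tree-based learners use
# raw features.

.learner_registry <- new.env(parent = emptyenv())

register_learner <- function(name, fit, predict, needs_scaling, grid,
                             available = function() TRUE) {
  assign(name, list(fit = fit, predict = predict,
                    needs_scaling = needs_scaling, grid = grid,
                    available = available),
         envir = .learner_registry)
}

#' List registered learners
#'
#' @return Character vector of learner names accepted by [learner_spec()].
#' @export
list_learners <- function() sort(ls(.learner_registry))

#' Describe a regression learner
#'
#' Creates the specification used everywhere a learner is consumed: the
#' registry name, an optional hyperparameter grid overriding the default
#' search space, and a seed making stochastic learners reproducible.
#'
#' @param name Registered learner name; one of [list_learners()], e.g.
#'   "svm_rbf", "random_forest", "xgboost", "kknn", "linear", "mean".
#' @param grid Named list of hyperparameter candidates; each entry is
#'   either a vector of values or a \code{list(min =, max =, log =,
#'   integer =)} range.  NULL uses the registry default.
#' @param seed Integer seed for stochastic learners.
#' @return A \code{learner_spec} object.
#' @export
learner_spec <- function(name, grid = NULL, seed = 1) {
  if (!exists(name, envir = .learner_registry)) {
    stop_qsar(sprintf("unknown learner '%s'; known: %s", name,
                      paste(list_learners(), collapse = ", ")),
              "qsarnest_registry_error")
  }
  entry <- get(name, envir = .learner_registry)
  structure(list(name = name, grid = grid %||% entry$grid,
                 needs_scaling = entry$needs_scaling, seed = seed),
            class = "learner_spec")
}

#' Fit a learner on a feature matrix
#'
#' @param spec A [learner_spec()].
#' @param X Feature matrix (finite values), n >= 5 rows.
#' @param y Response vector of length n.
#' @param params Named list of hyperparameter values; NULL uses the
#'   learner's defaults.
#' @return A \code{qsar_model} supporting [predict()].
#' @export
fit_learner <- function(spec, X, y, params = NULL) {
  X <- fm_values(X)
  entry <- get(spec$name, envir = .learner_registry)
  if (!entry$available()) {
    stop_qsar(sprintf("learner '%s' has no available backend", spec$name),
              "qsarnest_learner_unavailable")
  }
  if (nrow(X) < 5) {
    stop_qsar("need at least 5 training rows", "qsarnest_domain_error")
  }
  if (length(y) != nrow(X)) {
    stop_qsar("response length must match the number of rows",
              "qsarnest_domain_error")
  }
  if (anyNA(X) || !all(is.finite(X))) {
    stop_qsar("features must be finite", "qsarnest_domain_error")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  scaler <- NULL
  X_fit <- X
  if (spec$needs_scaling && ncol(X) > 0) {
    sds <- apply(X, 2, stats::sd)
    scaler <- list(mean = colMeans(X), sd = ifelse(sds == 0, 1, sds))
    X_fit <- scale_with(X, scaler)
  }
  inner <- with_seed(spec$seed, entry$fit(X_fit, y, params %||% list(), spec$seed))
  structure(list(spec = spec, inner = inner, scaler = scaler,
                 feature_names = colnames(X), params = params,
                 n_train = nrow(X)),
            class = "qsar_model")
}

scale_with <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' Predict from a fitted learner
#'
#' @param object A \code{qsar_model} from [fit_learner()].
#' @param newdata Matrix with exactly the training feature columns, in
#'   order.
#' @param ... Unused.
#' @return Numeric vector of predictions, one per row.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  X <- fm_values(newdata)
  if (is.null(colnames(X)) && ncol(X) == length(object$feature_names)) {
    colnames(X) <- object$feature_names
  }
  if (!identical(colnames(X), object$feature_names)) {
    stop_qsar("prediction columns do not match training feature names",
              "qsarnest_alignment_error")
  }
  if (!is.null(object$scaler)) X <- scale_with(X, object$scaler)
  entry <- get(object$spec$name, envir = .learner_registry)
  out <- as.numeric(entry$predict(object$inner, X))
  if (length(out) != nrow(X) || anyNA(out) || !all(is.finite(out))) {
    stop_qsar("learner produced non-finite or misaligned predictions",
              "qsarnest_domain_error")
  }
  out
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("<qsar_model> %s fit on %d x %d\n", x$spec$name, x$n_train,
              length(x$feature_names)))
  invisible(x)
}

#' Tune a learner by seeded random search
#'
#' Draws \code{budget} hyperparameter configurations from the spec's grid
#' and returns the one minimizing the mean k-fold cross-validated RMSE
#' (the tuning objective); ties resolve to the first configuration in the
#' seeded draw order.  An empty grid returns the learner defaults.
#'
#' @param spec A [learner_spec()].
#' @param X,y Training data.
#' @param folds Number of CV folds (>= 2), default 5.
#' @param budget Number of configurations to evaluate, default 25.
#' @param seed Integer seed controlling both the draws and the folds.
#' @return List with \code{params} (chosen configuration) and \code{rmse}
#'   (its CV RMSE, NA for an empty grid).
#' @export
tune_learner <- function(spec, X, y, folds = 5, budget = 25, seed = 1) {
  X <- fm_values(X)
  if (folds < 2) stop_qsar("folds must be >= 2", "qsarnest_domain_error")
  if (length(spec$grid) == 0) return(list(params = list(), rmse = NA_real_))
  with_seed(seed, {
    fold_idx <- cv_folds(nrow(X), folds)
    draws <- lapply(seq_len(budget), function(i) sample_grid(spec$grid))
    draws <- unique(draws)
    scores <- vapply(draws, function(par) {
      cv_rmse_subset(X, y, spec, fold_idx, params = par)
    }, numeric(1))
    list(params = draws[[which.min(scores)]], rmse = min(scores))
  })
}

sample_grid <- function(grid) {
  lapply(grid, function(g) {
    if (is.list(g)) {
      lo <- g$min; hi <- g$max
      v <- if (isTRUE(g$log)) exp(stats::runif(1, log(lo), log(hi)))
           else stats::runif(1, lo, hi)
      if (isTRUE(g$integer)) v <- as.integer(round(v))
      v
    } else if (length(g) > 1) {
      g[[sample.int(length(g), 1)]]
    } else {
      g[[1]]
    }
  })
}

take <- function(params, name, default) params[[name]] %||% default

# ---- registry entries -------------------------------------------------------

register_learner(
  "linear",
  fit = function(X, y, params, seed) {
    stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  },
  predict = function(model, X) {
    drop(cbind(1, X) %*% ifelse(is.na(model$coefficients), 0,
                                model$coefficients))
  },
  needs_scaling = FALSE,
  grid = list()
)

register_learner(
  "mean",
  fit = function(X, y, params, seed) list(fallback = mean(y), p = ncol(X)),
  predict = function(model, X) {
    if (model$p == 0) rep(model$fallback, nrow(X)) else rowMeans(X)
  },
  needs_scaling = FALSE,
  grid = list()
)

register_learner(
  "svm_rbf",
  fit = function(X, y, params, seed) {
    e1071::svm(
      x = X, y = y, type = "eps-regression", kernel = "radial",
      cost = take(params, "cost", 1),
      gamma = take(params, "gamma", 1 / max(1, ncol(X))),
      epsilon = take(params, "epsilon", 0.1),
      scale = FALSE
    )
  },
  predict = function(model, X) stats::predict(model, X),
  needs_scaling = TRUE,
  grid = list(cost = list(min = 2^-2, max = 2^6, log = TRUE),
              gamma = list(min = 2^-8, max = 2^2, log = TRUE))
)

register_learner(
  "random_forest",
  fit = function(X, y, params, seed) {
    p <- ncol(X)
    mtry <- max(1L, min(p, floor(take(params, "mtry_frac", 1 / 3) * p)))
    ranger::ranger(
      x = X, y = y,
      num.trees = take(params, "num.trees", 500),
      mtry = mtry,
      min.node.size = take(params, "min.node.size", 5),
      seed = seed, num.threads = 1
    )
  },
  predict = function(model, X) {
    stats::predict(model, data = X, num.threads = 1)$predictions
  },
  needs_scaling = FALSE,
  grid = list(mtry_frac = list(min = 0.1, max = 0.9),
              min.node.size = c(1, 3, 5))
)

register_learner(
  "xgboost",
  fit = function(X, y, params, seed) {
    xgboost::xgboost(
      x = X, y = y,
      nrounds = take(params, "nrounds", 200),
      max_depth = take(params, "max_depth", 4),
      learning_rate = take(params, "learning_rate", 0.1),
      subsample = take(params, "subsample", 1),
      seed = seed, nthreads = 1, verbosity = 0
    )
  },
  predict = function(model, X) stats::predict(model, X),
  needs_scaling = FALSE,
  grid = list(max_depth = list(min = 2, max = 8, integer = TRUE),
              learning_rate = list(min = 0.01, max = 0.3, log = TRUE),
              nrounds = list(min = 100, max = 600, integer = TRUE))
)

# Weighted k-nearest-neighbour regression (in-package implementation).
# Distances are Minkowski with power `distance`; neighbour weights follow
# the usual scheme of normalizing by the (k+1)-th neighbour distance and
# applying a kernel (rectangular = unweighted, triangular, gaussian).
register_learner(
  "kknn",
  fit = function(X, y, params, seed) {
    list(X = X, y = y,
         k = take(params, "k", 7),
         distance = take(params, "distance", 2),
         kernel = take(params, "kernel", "triangular"))
  },
  predict = function(model, X) {
    k <- min(model$k, nrow(model$X))
    apply(X, 1, function(q) {
      d <- (rowSums(abs(sweep(model$X, 2, q, "-"))^model$distance))^
        (1 / model$distance)
      ord <- order(d)
      idx <- ord[seq_len(k)]
      dk1 <- d[ord[min(k + 1, length(d))]]
      dn <- if (dk1 > 0) d[idx] / dk1 else rep(0, k)
      w <- switch(model$kernel,
                  rectangular = rep(1, k),
                  triangular = pmax(1 - dn, 0),
                  gaussian = exp(-2 * dn^2),
                  rep(1, k))
      if (sum(w) == 0) w <- rep(1, k)
      sum(w * model$y[idx]) / sum(w)
    })
  },
  needs_scaling = TRUE,
  grid = list(k = list(min = 3, max = 25, integer = TRUE),
              distance = c(1, 2),
              kernel = c("rectangular", "triangular", "gaussian"))
)

# Bayesian additive regression trees: requires an optional backend that is
# not bundled; the spec is constructible so that pipelines mentioning BART
# can be described, but fitting without a backend raises a typed error.
register_learner(
  "bart",
  fit = function(X, y, params, seed) {
    stop_qsar("learner 'bart' has no available backend",
              "qsarnest_learner_unavailable")
  },
  predict = function(model, X) stop("unreachable"),
  needs_scaling = FALSE,
  grid = list(num_trees = list(min = 50, max = 200, integer = TRUE)),
  available = function() {
    requireNamespace("dbarts", quietly = TRUE) ||
      requireNamespace("BART", quietly = TRUE)
  }
)
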