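#' Genetic-algorithm wrapper feature selection
#'
#' Wrapper search over feature subsets: chromosomes are feature-inclusion
#' bit vectors and the fitness of a chromosome is the mean cross-validated
#' RMSE of a given learner restricted to the encoded subset (lower is
#' better).  Evolution uses tournament selection (size 3), uniform
#' crossover, per-bit flip mutation and elitism of one, so the best fitness
#' never deteriorates across generations.  An all-zero chromosome arising
#' during evolution is repaired by activating one random bit.
#'
#' @param X Feature matrix.
#' @param y Response vector.
#' @param learner_spec A [learner_spec()] used to evaluate subsets.
#' @param pop_size Population size, default 50.
#' @param generations Number of generations, default 30; 0 returns the best
#'   chromosome of the random initial population.
#' @param p_crossover Crossover probability, default 0.9.
#' @param p_mutation Per-bit mutation probability; default 1/p.
#' @param fitness_folds Cross-validation folds for the fitness, default 5.
#' @param init_rate Expected fraction of active bits in initial
#'   chromosomes, default 0.2.
#' @param seed Integer seed; the search is fully reproducible given it.
#' @return A \code{selection_result}; \code{scores} holds the best
#'   chromosome's fitness (CV RMSE) for its features and
#'   \code{params$fitness_trace} the best fitness per generation.
#' @export
ga_select <- function(X, y, learner_spec, pop_size = 50, generations = 30,
                      p_crossover = 0.9, p_mutation = NULL,
                      fitness_folds = 5, init_rate = 0.2, seed = 1) {
  X <- fm_values(X)
  p <- ncol(X)
  nms <- colnames(X) %||% paste0("f", seq_len(p))
  if (is.null(p_mutation)) p_mutation <- 1 / p

  with_seed(seed, {
    folds <- cv_folds(nrow(X), fitness_folds)
    fitness <- function(chrom) {
      cols <- which(chrom == 1L)
      cv_rmse_subset(X[, cols, drop = FALSE], y, learner_spec, folds)
    }
    repair <- function(chrom) {
      if (!any(chrom == 1L)) chrom[sample.int(p, 1)] <- 1L
      chrom
    }

    pop <- lapply(seq_len(pop_size), function(i) {
      repair(as.integer(stats::runif(p) < init_rate))
    })
    fit <- vapply(pop, fitness, numeric(1))
    trace <- min(fit)

    for (gen in seq_len(generations)) {
      elite <- which.min(fit)
      tournament <- function() {
        cand <- sample.int(pop_size, 3)
        cand[which.min(fit[cand])]
      }
      children <- vector("list", pop_size)
      children[[1]] <- pop[[elite]]                     # elitism of 1
      i <- 2L
      while (i <= pop_size) {
        a <- pop[[tournament()]]; b <- pop[[tournament()]]
        if (stats::runif(1) < p_crossover) {
          mask <- stats::runif(p) < 0.5                 # uniform crossover
          tmp <- a
          a <- ifelse(mask, a, b)
          b <- ifelse(mask, b, tmp)
        }
        for (child in list(a, b)) {
          if (i > pop_size) break
          flip <- stats::runif(p) < p_mutation
          child[flip] <- 1L - child[flip]
          children[[i]] <- repair(as.integer(child))
          i <- i + 1L
        }
      }
      pop <- children
      fit <- vapply(pop, fitness, numeric(1))
      trace <- c(trace, min(fit))
    }

    best <- pop[[which.min(fit)]]
    selection_result(
      nms[best == 1L],
      scores = stats::setNames(rep(min(fit), sum(best)), nms[best == 1L]),
      method = "ga",
      params = list(pop_size = pop_size, generations = generations,
                    p_crossover = p_crossover, p_mutation = p_mutation,
                    fitness_folds = fitness_folds,
                    fitness_trace = trace),
      seed = seed
    )
  })
}

# Mean CV RMSE of a learner on a fixed feature subset -- the GA fitness and
# the tuning objective share this primitive.
cv_rmse_subset <- function(X, y, learner_spec, folds, params = NULL) {
  errs <- vapply(folds, function(test_idx) {
    train_idx <- setdiff(seq_len(nrow(X)), test_idx)
    model <- fit_learner(learner_spec, X[train_idx, , drop = FALSE],
                         y[train_idx], params = params)
    rmse(y[test_idx], predict(model, X[test_idx, , drop = FALSE]))
  }, numeric(1))
  mean(errs)
}

# Seeded fold assignment: uniform shuffle, then contiguous blocks.
cv_folds <- function(n, k, seed = NULL) {
  make <- function() {
    perm <- sample.int(n)
    split(perm, cut(seq_len(n), k, labels = FALSE))
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}
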