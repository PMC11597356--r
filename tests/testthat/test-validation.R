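test_that("R-squared, CCC and RMSE match worked examples", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(1.1, 2.0, 2.9)), 0.99)
  expect_error(r_squared(rep(2, 5), rnorm(5)), class = "qsarnest_domain_error")

  expect_equal(ccc(y, y), 1)
  expect_equal(ccc(y, c(2, 3, 4)), 4 / 7)
  # anti-correlated 4-point case, population moments:
  # mx 2.5 my 2.75, sx2 1.25 sy2 0.3125 sxy -0.625
  expect_equal(ccc(c(1, 2, 3, 4), c(3.5, 3, 2.5, 2)), -1.25 / 1.625)
  expect_error(ccc(rep(1, 4), rep(2, 4)), class = "qsarnest_domain_error")

  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(c(1, 2), c(1.5, 2.5)), 0.5)
  expect_equal(rmse(c(0, 0), c(1, -1)), 1)
})

test_that("CCC never exceeds the absolute Pearson correlation", {
  set.seed(55)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    a <- rnorm(n); b <- rnorm(n) * runif(1, 0.1, 5) + rnorm(1)
    expect_lte(ccc(a, b), abs(cor(a, b)) + 1e-12)
  }
})

test_that("metric_set is internally consistent", {
  set.seed(5)
  y <- rnorm(50); yh <- y + rnorm(50, 0, 0.3)
  ms <- metric_set(y, yh)
  expect_equal(ms$r2, r_squared(y, yh))
  expect_equal(ms$ccc, ccc(y, yh))
  expect_equal(ms$rmse, rmse(y, yh))
})

test_that("Rp-squared reproduces the published reconstruction and edge cases", {
  expect_equal(rp_squared(0.701, -0.220), 0.803, tolerance = 2e-3)
  expect_equal(rp_squared(0.719, -0.113), 0.773, tolerance = 2e-3)
  expect_equal(rp_squared(0.754, -0.056), 0.781, tolerance = 2e-3)
  expect_equal(rp_squared(0.6, 0.6), 0)
  expect_warning(out <- rp_squared(0.3, 0.5), "undefined")
  expect_true(is.na(out))
})

test_that("replicate aggregation reproduces published summary rows", {
  m4 <- aggregate_replicates(c(0.857, 0.853, 0.857, 0.843, 0.845))
  expect_identical(m4$mean, 0.851)
  expect_identical(m4$sd, 0.007)
  m20 <- aggregate_replicates(c(0.856, 0.870, 0.868, 0.872, 0.877))
  expect_identical(m20$mean, 0.869)
  expect_identical(aggregate_replicates(rep(0.8, 3))$sd, 0)
  expect_true(is.na(aggregate_replicates(0.8)$sd))
})

test_that("nested CV predicts every compound exactly once, honestly", {
  # noiseless linear truth within the model class: near-perfect recovery
  d <- make_regression(n = 80, p = 6, k = 2, seed = 31, noise_sd = 1e-9)
  cv <- nested_cv(d$X, d$y, learner_spec("linear"),
                  outer_folds = 5, inner_folds = 3, seed = 2)
  expect_gte(cv$metrics$r2, 0.999)
  expect_false(anyNA(cv$oof))
  expect_setequal(unlist(cv$folds), seq_len(80))
  # stored metrics recompute bit-for-bit from the pooled oof vector
  expect_identical(cv$metrics$r2, r_squared(d$y, cv$oof))
  expect_identical(cv$metrics$rmse, rmse(d$y, cv$oof))

  # response independent of the features: no apparent skill
  set.seed(77)
  ynull <- rnorm(200)
  Xn <- matrix(rnorm(200 * 10), 200, 10,
               dimnames = list(NULL, paste0("v", 1:10)))
  cvn <- nested_cv(Xn, ynull, learner_spec("linear"),
                   selector_spec("cmim", k = 3),
                   outer_folds = 5, inner_folds = 3, seed = 3)
  expect_lte(cvn$metrics$r2, 0.1)
})

test_that("nested CV is reproducible and records per-fold choices", {
  d <- make_regression(n = 100, p = 10, k = 2, r_star2 = 0.8, seed = 13)
  a <- nested_cv(d$X, d$y, learner_spec("random_forest"),
                 selector_spec("cmim", k = 4), outer_folds = 4,
                 inner_folds = 3, tune_budget = 3, seed = 5)
  b <- nested_cv(d$X, d$y, learner_spec("random_forest"),
                 selector_spec("cmim", k = 4), outer_folds = 4,
                 inner_folds = 3, tune_budget = 3, seed = 5)
  expect_identical(a$oof, b$oof)
  expect_length(a$per_fold, 4)
  for (f in a$per_fold) expect_gt(length(f$features), 0)
  expect_error(nested_cv(d$X[1:10, ], d$y[1:10], learner_spec("linear"),
                         outer_folds = 10),
               class = "qsarnest_domain_error")
})

test_that("replicate runs summarize mean and sd across seeds", {
  d <- make_regression(n = 90, p = 8, k = 2, r_star2 = 0.8, seed = 19)
  reps <- replicate_nested_cv(d$X, d$y, learner_spec("linear"),
                              selector_spec("cmim", k = 3),
                              outer_folds = 3, inner_folds = 2,
                              seeds = c(1, 2, 3))
  expect_length(reps$results, 3)
  cccs <- vapply(reps$results, function(r) r$metrics$ccc, numeric(1))
  expect_equal(reps$summary$mean[reps$summary$metric == "ccc"],
               qsarnest:::round_half_up(mean(cccs), 3))
  expect_equal(reps$summary$sd[reps$summary$metric == "ccc"],
               qsarnest:::round_half_up(sd(cccs), 3))
})

test_that("y-randomization collapses performance and is seeded", {
  d <- make_regression(n = 90, p = 8, k = 2, r_star2 = 0.85, seed = 37)
  yr <- y_randomize(d$X, d$y, learner_spec("linear"),
                    selector_spec("cmim", k = 3), outer_folds = 3,
                    inner_folds = 2, n_perm = 3, seed = 4)
  expect_lt(yr$rr2_mean, yr$genuine$r2)
  expect_lte(yr$rr2_mean, 0.1)
  yr2 <- y_randomize(d$X, d$y, learner_spec("linear"),
                     selector_spec("cmim", k = 3), outer_folds = 3,
                     inner_folds = 2, n_perm = 3, seed = 4)
  expect_identical(yr$rr2_mean, yr2$rr2_mean)
  # a single permutation: the mean is that run's own r2
  yr1 <- y_randomize(d$X, d$y, learner_spec("linear"),
                     selector_spec("cmim", k = 3), outer_folds = 3,
                     inner_folds = 2, n_perm = 1, seed = 9)
  expect_identical(yr1$rr2_mean, yr1$permuted[[1]]$r2)
  expect_equal(yr1$rp2,
               suppressWarnings(rp_squared(yr1$genuine$r2, yr1$rr2_mean)))
})

test_that("permutation importance ranks the generative feature first", {
  d <- make_regression(n = 150, p = 6, k = 1, r_star2 = 0.9, seed = 41)
  m <- fit_learner(learner_spec("random_forest", seed = 2), d$X, d$y)
  imp <- permutation_importance(m, d$X, d$y, n_repeats = 5, seed = 3)
  expect_equal(names(imp)[1], "inf_1")
  expect_lt(max(abs(imp[setdiff(names(imp), "inf_1")])),
            imp[["inf_1"]] / 2)
  expect_error(permutation_importance(m, d$X, d$y, n_repeats = 0),
               class = "qsarnest_domain_error")
})

test_that("partial dependence mirrors the model's functional form", {
  set.seed(43)
  x <- rnorm(100); z <- rnorm(100)
  X <- cbind(x = x, z = z)
  y <- 2 * x + 0.01 * z
  m <- fit_learner(learner_spec("linear"), X, y)
  pd <- partial_dependence(m, X, "x", grid_size = 10)
  slopes <- diff(pd$yhat) / diff(pd$value)
  expect_equal(slopes, rep(2, length(slopes)), tolerance = 1e-6)
  # binary feature: exactly two grid points
  Xb <- cbind(b = rbinom(100, 1, 0.5), z = z)
  mb <- fit_learner(learner_spec("linear"), Xb, Xb[, "b"] * 3 + z)
  expect_equal(partial_dependence(mb, Xb, "b")$value, c(0, 1))
  expect_error(partial_dependence(m, X, "missing_feature"),
               class = "qsarnest_domain_error")
})
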