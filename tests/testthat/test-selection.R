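test_that("mutual information behaves like a plug-in estimator", {
  set.seed(31)
  x <- rnorm(1000)
  expect_equal(mutual_information(x, x), log(10), tolerance = 1e-9)
  expect_equal(mutual_information(rep(1, 100), rnorm(100)), 0)
  y <- rnorm(5000)
  expect_lt(mutual_information(rnorm(5000), y), 0.02)
  # binary variables keep their two levels
  b <- rbinom(2000, 1, 0.5)
  expect_lt(mutual_information(b, rbinom(2000, 1, 0.5)), 0.01)
  expect_gt(mutual_information(b, b), 0.5)  # ~log(2)
  expect_error(mutual_information(1:3, 1:3), class = "qsarnest_domain_error")
})

test_that("CMIM picks the signal first and discounts exact copies", {
  set.seed(41)
  n <- 600
  x1 <- rnorm(n)
  x3 <- rnorm(n)
  X <- cbind(x1 = x1, x2 = x1, x3 = x3,
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  y <- 2 * x1 + 0.8 * x3 + rnorm(n, 0, 0.5)
  sel <- cmim_select(X, y, k = 2)
  expect_equal(sel$selected[1], "x1")
  # x2 is an exact copy of x1: its conditional MI collapses, x3 outranks it
  expect_equal(sel$selected[2], "x3")
  expect_length(cmim_select(X, y, k = 0)$selected, 0)
  expect_equal(cmim_select(X, y, k = 99)$selected |> length(), ncol(X))
})

test_that("JMIM recovers an XOR-style interaction partner", {
  set.seed(43)
  n <- 800
  # balanced x1 keeps x2 marginally silent; unbalanced x2 gives x1 a
  # marginal edge, so the xor partner is only discoverable jointly
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rbinom(n, 1, 0.7)
  noise <- matrix(rbinom(3 * n, 1, 0.5), n, 3,
                  dimnames = list(NULL, paste0("z", 1:3)))
  y <- 3 * xor(x1, x2) + rnorm(n, 0, 0.2)
  X <- cbind(x1 = x1, x2 = x2, noise)
  sel <- jmim_select(X, y, k = 2)
  expect_equal(sel$selected[1], "x1")
  expect_equal(sel$selected[2], "x2")
  # k = p returns everything, ordered without duplicates
  all_sel <- jmim_select(X, y, k = ncol(X))
  expect_setequal(all_sel$selected, colnames(X))
  expect_false(anyDuplicated(all_sel$selected) > 0)
})

test_that("single informative feature is the first pick for both filters", {
  d <- make_regression(n = 250, p = 12, k = 1, r_star2 = 0.8, seed = 17)
  expect_equal(cmim_select(d$X, d$y, k = 3)$selected[1], "inf_1")
  expect_equal(jmim_select(d$X, d$y, k = 3)$selected[1], "inf_1")
})

test_that("Boruta confirms planted features and rejects noise", {
  d <- make_regression(n = 300, p = 50, k = 5, r_star2 = 0.75, seed = 11)
  sel <- boruta_select(d$X, d$y, max_iter = 50, seed = 7)
  expect_gte(sum(d$truth %in% sel$selected), 5)
  expect_lte(length(setdiff(sel$selected, d$truth)), 1)
  # determinism
  sel2 <- boruta_select(d$X, d$y, max_iter = 50, seed = 7)
  expect_identical(sel$selected, sel2$selected)
  # decisions recorded for every feature
  expect_setequal(names(sel$params$decision), colnames(d$X))
})

test_that("Boruta keeps false confirmations near zero on pure noise", {
  spn <- synthetic_spec(n = 200, p = 30, k_informative = 0, noise_sd = 1,
                        seed = 5)
  Xn <- gen_features(spn)$values
  fps <- vapply(1:3, function(s) {
    y <- with(list(), { set.seed(100 + s); rnorm(200) })
    length(boruta_select(Xn, y, max_iter = 50, seed = s)$selected)
  }, numeric(1))
  expect_lte(mean(fps), 1)
})

test_that("Boruta respects the iteration cap and input contracts", {
  d <- make_regression(n = 60, p = 8, k = 2, r_star2 = 0.7, seed = 2)
  one <- boruta_select(d$X, d$y, max_iter = 1, seed = 3)
  expect_identical(one$selected,
                   boruta_select(d$X, d$y, max_iter = 1, seed = 3)$selected)
  expect_equal(one$params$iterations, 1L)
  Xbad <- d$X; Xbad[1, 1] <- NA
  expect_error(boruta_select(Xbad, d$y), class = "qsarnest_domain_error")
  expect_error(boruta_select(d$X[1:10, ], d$y[1:10]),
               class = "qsarnest_domain_error")
})

test_that("GA fitness prefers the informative subset and never regresses", {
  d <- make_regression(n = 150, p = 12, k = 3, r_star2 = 0.8, seed = 23)
  lin <- learner_spec("linear")
  folds <- qsarnest:::cv_folds(nrow(d$X), 3, seed = 9)
  fit_true <- qsarnest:::cv_rmse_subset(
    d$X[, d$truth, drop = FALSE], d$y, lin, folds)
  fit_noise <- qsarnest:::cv_rmse_subset(
    d$X[, setdiff(colnames(d$X), d$truth)[1:3], drop = FALSE], d$y, lin, folds)
  expect_lt(fit_true, fit_noise)

  sel <- ga_select(d$X, d$y, lin, pop_size = 16, generations = 6,
                   fitness_folds = 3, seed = 5)
  trace <- sel$params$fitness_trace
  expect_true(all(diff(trace) <= 1e-12))          # elitism: non-increasing
  expect_true(all(d$truth %in% sel$selected))
  # determinism and the generations = 0 degenerate case
  expect_identical(sel$selected,
                   ga_select(d$X, d$y, lin, pop_size = 16, generations = 6,
                             fitness_folds = 3, seed = 5)$selected)
  g0 <- ga_select(d$X, d$y, lin, pop_size = 10, generations = 0,
                  fitness_folds = 3, seed = 5)
  expect_length(g0$params$fitness_trace, 1)
  expect_gt(length(g0$selected), 0)
})

test_that("selection results are well-formed", {
  d <- make_regression(n = 100, p = 10, k = 2, r_star2 = 0.8, seed = 3)
  for (sel in list(cmim_select(d$X, d$y, k = 4),
                   jmim_select(d$X, d$y, k = 4))) {
    expect_true(all(sel$selected %in% colnames(d$X)))
    expect_false(anyDuplicated(sel$selected) > 0)
    expect_named(sel$scores)
  }
})
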