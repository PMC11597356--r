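test_that("MACCS fingerprints are deterministic 166-bit structural keys", {
  smi <- c(m = "C", f = "FC(F)(F)c1ccccc1", a = "CCO", b = "CCO")
  fp <- maccs_fingerprints(smi)
  expect_s3_class(fp, "feature_matrix")
  expect_equal(dim(fp), c(4L, 166L))
  expect_true(all(fp$values %in% c(0, 1)))
  # key 42 flags a fluorine atom
  expect_equal(fp$values["f", "MACCS_42"], 1)
  expect_equal(fp$values["a", "MACCS_42"], 0)
  # identical SMILES give identical rows (Tanimoto 1)
  expect_identical(fp$values["a", ], fp$values["b", ])
  # recomputation is bit-identical
  expect_identical(maccs_fingerprints(smi)$values, fp$values)
  expect_error(maccs_fingerprints(c(ok = "CC", bad = "zzz((")),
               class = "qsarnest_parse_error")
  expect_match(tryCatch(maccs_fingerprints(c(ok = "CC", bad = "zzz((")),
                        error = conditionMessage), "bad")
})

test_that("descriptor tables align to the dataset and drop incomplete columns", {
  tab <- data.frame(id = c("c2", "c1", "c3"),
                    d1 = c(1.5, 2.5, 3.5),
                    d2 = c("0.1", "oops", "0.3"),
                    "SpMax_B(p)" = c(4, 5, 6), check.names = FALSE)
  path <- write_activity_csv(tab)
  bm <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(feature = "SpMax_B(p)", block = "Burden eigenvalues"),
                   bm, row.names = FALSE)
  fm <- load_descriptor_table(path, ids = c("c1", "c2", "c3"), block_map = bm)
  expect_equal(rownames(fm$values), c("c1", "c2", "c3"))
  expect_equal(fm$values["c1", "d1"], 2.5)          # reordered to id order
  expect_false("d2" %in% colnames(fm$values))       # non-numeric cell dropped
  expect_equal(unname(fm$dropped["d2"]), "missing values")
  expect_equal(unname(fm$blocks["SpMax_B(p)"]), "Burden eigenvalues")
  expect_error(load_descriptor_table(path, ids = c("c1", "c9")),
               class = "qsarnest_alignment_error")
  # fully numeric table: nothing dropped
  fm2 <- load_descriptor_table(
    write_activity_csv(data.frame(id = c("a", "b"), d = c(1, 2))), c("a", "b"))
  expect_length(fm2$dropped, 0)
})

test_that("low-variance filter removes constant and quasi-constant columns", {
  n <- 100
  X <- cbind(
    const = rep(3, n),
    quasi = c(rep(0, 99), 1),          # ratio 99 > 19, 2% unique
    balanced = rep(c(0, 1), 50),
    spread = seq_len(n)
  )
  out <- drop_low_variance(X)
  expect_setequal(colnames(out$values), c("balanced", "spread"))
  expect_equal(unname(out$dropped["const"]), "constant")
  expect_equal(unname(out$dropped["quasi"]), "quasi-constant")
})

test_that("correlation filter leaves no pair above the cutoff", {
  set.seed(21)
  base <- matrix(rnorm(500 * 8), 500, 8,
                 dimnames = list(NULL, paste0("v", 1:8)))
  planted <- base[, 3] + rnorm(500, 0, 0.33)        # r ~ 0.95 with v3
  X <- cbind(base, planted = planted, dupe = base[, 5])
  out <- drop_correlated(X, cutoff = 0.90)
  # exactly one of each offending pair removed, everything else kept
  expect_equal(ncol(out$values), 8)
  expect_equal(sum(c("v3", "planted") %in% colnames(out$values)), 1)
  expect_equal(sum(c("v5", "dupe") %in% colnames(out$values)), 1)
  # postcondition by exhaustive scan
  expect_lt(max(abs(stats::cor(out$values))[upper.tri(diag(ncol(out$values)))]),
            0.90)
  # three mutually identical columns: two removed
  Y <- cbind(a = base[, 1], b = base[, 1], c = base[, 1], d = base[, 2])
  expect_equal(ncol(drop_correlated(Y)$values), 2)
})

test_that("correlation filter postcondition holds on generated matrices", {
  for (seed in 1:5) {
    d <- make_regression(n = 120, p = 30, k = 3, seed = seed,
                         n_redundant = 4, block_corr = 0.6)
    out <- drop_correlated(d$X, cutoff = 0.9)
    cors <- abs(stats::cor(out$values))
    expect_lt(max(cors[upper.tri(cors)]), 0.9)
  }
})

test_that("scaling learns on training rows only and standardizes them", {
  set.seed(5)
  X <- matrix(rnorm(200, mean = 5, sd = 2), 100, 2,
              dimnames = list(NULL, c("a", "b")))
  train <- 1:60
  sc <- fit_scaler(X, train)
  expect_identical(sc$fit_idx, train)
  Z <- apply_scaler(sc, X)
  expect_equal(unname(colMeans(Z[train, ])), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(Z[train, ], 2, sd)), c(1, 1), tolerance = 1e-9)
  # a value 2 sd above the train mean maps to 2
  X2 <- X; X2[61, "a"] <- sc$mean["a"] + 2 * sc$sd["a"]
  expect_equal(unname(apply_scaler(sc, X2)[61, "a"]), 2, tolerance = 1e-9)
  expect_error(fit_scaler(cbind(k = rep(1, 10)), 1:10),
               class = "qsarnest_domain_error")
  expect_error(apply_scaler(sc, X[, c("b", "a")]),
               class = "qsarnest_alignment_error")
})

test_that("binary feature matrices reject non-binary values", {
  expect_error(feature_matrix(matrix(c(0, 1, 2, 1), 2), kind = "binary"),
               class = "qsarnest_domain_error")
  expect_error(feature_matrix(matrix(1:4, 2,
                                     dimnames = list(NULL, c("x", "x")))),
               class = "qsarnest_domain_error")
})
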