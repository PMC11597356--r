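test_that("pIC50 conversion matches the molar definition and round-trips", {
  expect_identical(to_pic50(10), 8)
  expect_equal(to_pic50(1000), 6)
  expect_equal(to_pic50(0.002), 11.699, tolerance = 5e-4)
  expect_equal(to_pic50(1.5e6), 2.824, tolerance = 5e-4)
  for (p in c(2.824, 8, 11.699)) {
    expect_equal(to_pic50(pic50_to_ic50(p)), p, tolerance = 1e-9)
  }
  expect_error(to_pic50(0), class = "qsarnest_domain_error")
  expect_error(to_pic50(-5), class = "qsarnest_domain_error")
})

test_that("structure standardization strips salts, neutralizes and is stable", {
  expect_identical(standardize_smiles("CCO"),
                   standardize_smiles(standardize_smiles("CCO")))
  # salt and parent acid give the same key
  expect_identical(standardize_smiles("CC(=O)O.[Na+]"),
                   standardize_smiles("CC(=O)O"))
  expect_identical(standardize_smiles("CC(=O)[O-].[Na+]"),
                   standardize_smiles("CC(=O)O"))
  # equal-size fragments resolve deterministically
  expect_identical(standardize_smiles("[NH4+].[Cl-]"),
                   standardize_smiles("[NH4+].[Cl-]"))
  expect_error(standardize_smiles("not_a_smiles"),
               class = "qsarnest_parse_error")
})

test_that("activity tables drop bad rows with logged reasons", {
  path <- write_activity_csv(data.frame(
    id = c("a", "b", "c", "d"),
    smiles = c("CCO", "CCN", "xxxx_bad", "CCC"),
    ic50_nM = c(1000, NA, 10, 0)
  ))
  rec <- read_activity_table(path)
  expect_equal(rec$id, "a")
  expect_equal(rec$pic50, 6)
  log <- attr(rec, "curation_log")
  expect_setequal(log$id, c("b", "c", "d"))
  expect_equal(sort(unique(log$reason)),
               c("missing or non-numeric IC50", "non-positive IC50",
                 "unparsable SMILES"))
  expect_error(read_activity_table(tempfile()), class = "qsarnest_io_error")
  expect_error(read_activity_table(path, ic50_col = "nope"),
               class = "qsarnest_schema_error")
})

test_that("deduplication merges by median IC50 and recomputes pIC50", {
  rec <- data.frame(
    id = c("x1", "x2", "x3", "y1", "y2", "z"),
    smiles = c("OC(=O)c1ccccc1", "c1ccccc1C(O)=O", "C(=O)(O)c1ccccc1",
               "CCOC", "CCOC", "CCCC"),
    ic50_nM = c(1, 10, 100, 10, 1000, 7),
    pic50 = to_pic50(c(1, 10, 100, 10, 1000, 7))
  )
  ds <- deduplicate(rec)
  expect_equal(nrow(ds$records), 3)
  expect_equal(ds$records$ic50_nM[ds$records$id == "x1"], 10)   # odd median
  expect_equal(ds$records$ic50_nM[ds$records$id == "y1"], 505)  # even midpoint
  # pIC50 from the merged IC50, not the mean of pIC50s
  expect_equal(ds$records$pic50[ds$records$id == "y1"], to_pic50(505))
  expect_equal(length(ds$log), 2)
  # identity on a duplicate-free table
  ds2 <- deduplicate(ds$records[, 1:4], standardize = FALSE)
  expect_equal(ds2$records$ic50_nM, ds$records$ic50_nM)
  # conservation: one output record per distinct structure key
  expect_equal(nrow(ds$records), length(unique(standardize_smiles(rec$smiles))))
})

test_that("curation is idempotent", {
  fx <- gen_curation_fixture(seed = 3)
  path <- write_activity_csv(fx$table)
  ds1 <- curate_activity_table(path, seed = 1)
  once <- ds1$records
  ds2 <- deduplicate(once[, c("id", "smiles", "ic50_nM", "pic50")])
  expect_equal(ds2$records$smiles, once$smiles)
  expect_equal(ds2$records$ic50_nM, once$ic50_nM)
})

test_that("train/test split follows the floor rule, deterministically", {
  s <- split_train_test(227, 0.75, seed = 42)
  expect_equal(length(s$train), 170)
  expect_equal(length(s$test), 57)
  expect_equal(split_train_test(4, 0.75, seed = 1)$train |> length(), 3)
  set.seed(99)
  for (i in 1:100) {
    n <- sample(10:500, 1); sd <- sample.int(1e6, 1)
    a <- split_train_test(n, seed = sd)
    b <- split_train_test(n, seed = sd)
    expect_identical(a, b)
    expect_length(intersect(a$train, a$test), 0)
    expect_setequal(c(a$train, a$test), seq_len(n))
  }
  expect_error(split_train_test(1), class = "qsarnest_domain_error")
  expect_error(split_train_test(10, ratio = 1.2), class = "qsarnest_domain_error")
})

test_that("Lipinski failure counts cover 0 through 5", {
  expect_identical(lipinski_failures(422.5, 4.2, 2, 5, 8), 0L)
  expect_identical(lipinski_failures(600, 6, 6, 11, 11), 5L)
  expect_identical(lipinski_failures(501, 5, 5, 10, 10), 1L)
  expect_identical(lipinski_failures(600, 6, 6, 11, five_rules = FALSE), 4L)
  expect_error(lipinski_failures(500, 5, 5, 10), class = "qsarnest_domain_error")
})

test_that("property profiles feed plausible Lipinski inputs", {
  prof <- property_profile(c("CCCCO", "CC(=O)Oc1ccccc1C(=O)O"))
  expect_equal(prof$rotatable_bonds[1], 2)
  expect_gt(prof$mw[2], 150)
  expect_equal(prof$hbd[2], 1)
  expect_error(property_profile("junk((("), class = "qsarnest_parse_error")
})
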