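# qsarnest

Nested cross-validated QSAR regression with applicability-domain-gated
consensus virtual screening.

## What this package is for

Quantitative structure–activity relationship (QSAR) modelling predicts a
compound's potency — here the pIC50, the negative decadic logarithm of the
molar half-maximal inhibitory concentration — from molecular features:
166-bit MACCS structural-key fingerprints or continuous molecular-descriptor
tables. The motivating application is modelling inhibitors of HMG-CoA
reductase, the rate-limiting enzyme of cholesterol biosynthesis, but nothing
in the package is target-specific.

The package covers the full modelling workflow a medicinal-chemistry data
scientist needs to run such a study end to end, with the validation rigor
that small, noisy activity datasets demand:

- **Curation** — read activity CSVs, standardize structures (largest
  covalent fragment, charge neutralization, canonical SMILES so salts merge
  with their parent acids), merge duplicates by median IC50
  (`pIC50 = 9 − log10(IC50 [nM])` recomputed from the merged value), draw a
  3:1 random train/test split (`floor(n·0.75)`: 227 compounds → 170/57),
  and profile drug-likeness (Lipinski failures, MW/ALogP chemical space,
  pairwise Tanimoto diversity).
- **Features** — MACCS fingerprints via Open Babel, pluggable descriptor
  tables from CSV, constant/quasi-constant and |r| > 0.9 correlation
  filters, leakage-safe train-only scaling.
- **Feature selection** — CMIM and JMIM greedy information filters on a
  shared equal-frequency-binned mutual-information estimator, Boruta
  (shadow-feature random-forest testing with Bonferroni-corrected binomial
  decisions), and a genetic-algorithm wrapper scored by cross-validated
  RMSE.
- **Learners** — a uniform registry (RBF-kernel SVM, random forest,
  XGBoost, weighted k-nearest neighbours, linear, column-mean; BART as an
  optional backend) with seeded random-search tuning.
- **Validation** — nested cross-validation (selection and tuning strictly
  inside the outer-training partition; pooled out-of-fold metrics:
  R² as "true q²", Lin's concordance correlation coefficient, RMSE),
  replicate seeds with mean ± sd reporting, y-randomization with the
  validity statistic

  Rp² = √R² · √(R² − Rr²)

  where Rr² is the mean R² of response-permuted reruns of the whole
  pipeline, and model interpretation via permutation importance and
  partial dependence.
- **Ensembling** — leakage-safe stacking on base models' out-of-fold
  predictions, with representative-seed selection (the replicate whose CCC
  is closest to the replicate mean).
- **Screening** — similarity (max Tanimoto > 0.20, strict) and
  isolation-forest applicability domains (AD), AD-gated per-compound
  consensus (mean/median pIC50 and relative standard deviation over trusted
  predictions only), coverage and hit-rate reports.
- **Synthetic data** — a generator for fingerprint/descriptor matrices with
  planted signal, degenerate columns and block correlation, plus a small
  chemically real curation fixture, so the whole pipeline is testable
  without any downloads.

## Worked example

```r
library(qsarnest)

# 1. Curate a raw activity table (here: the built-in chemical fixture)
fx <- tempfile(fileext = ".csv")
gen_curation_fixture(seed = 1, path = fx)
ds <- curate_activity_table(fx, seed = 42)
print(ds)
#> Curated dataset: 24 compounds (18 train / 6 test / 0 unsplit)
#>   6 curation action(s) logged

# 2. Fingerprints and dataset diversity
fp <- maccs_fingerprints(ds$records$smiles, ids = ds$records$id)
pairwise_similarity_summary(fp)
#> Tanimoto similarity over 276 pairs: mean 0.177 (Q1 0.088, Q3 0.250)

# 3. Nested CV of a selection+learning pipeline on synthetic data with a
#    known generative signal fraction of 0.75
spec <- synthetic_spec(n = 300, p = 50, k_informative = 5, r_star2 = 0.75, seed = 7)
fm <- gen_features(spec); resp <- gen_response(fm, spec)
cv <- nested_cv(fm$values, resp$y, learner_spec("svm_rbf"),
                selector_spec("boruta"), outer_folds = 5, inner_folds = 3,
                tune_budget = 8, seed = 1)
print(cv)
#> Nested CV (5 outer x 3 inner folds, seed 1): boruta + svm_rbf
#> R2 = 0.735, CCC = 0.842, RMSE = 0.791

# 4. y-randomization: the same pipeline on permuted responses collapses
yr <- y_randomize(fm$values, resp$y, learner_spec("svm_rbf"),
                  selector_spec("boruta"), outer_folds = 5, inner_folds = 3,
                  tune_budget = 8, genuine = cv, n_perm = 3, seed = 2)
print(yr)
#> y-randomization over 3 permutations:
#>   genuine R2 0.735 | mean permuted Rr2 -0.051 | Rp2 0.760
```

The nested-CV R² of 0.735 sits at the generative signal fraction (0.75):
the pipeline neither leaks (which would inflate it) nor wastes signal.
The permuted runs score below zero — out-of-fold predictions on scrambled
responses are worse than predicting the mean — and Rp² stays close to the
genuine R², the signature of a model that is not a chance artifact.

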