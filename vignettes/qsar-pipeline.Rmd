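---
title: "Methods: nested cross-validated QSAR modelling and AD-gated screening"
author: "qsarnest"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical and
cheminformatic choices behind its functions: what is modelled, which knobs
matter, what the synthetic generator does and does not emulate, and where
the design was genuinely open.

## The modelling problem

The response is pIC50 = −log10 of the molar IC50; since activity tables
carry IC50 in nanomolar, `to_pic50()` computes `9 − log10(IC50_nM)`.
A pIC50 of 8 is an IC50 of 10 nM — the conventional "potent" threshold
used by the screening reports. Features are either 166-bit MACCS
structural keys (each bit flags a predefined substructure) or arbitrary
continuous descriptor tables supplied as CSV. The datasets this pipeline
is built for are small (a few hundred compounds) and noisy, which drives
every validation choice below.

## Curation

Structure standardization is deliberately minimal and deterministic:
parse, keep the largest covalent fragment (measured in heavy atoms; ties
broken by longer canonical SMILES, then lexicographically), neutralize
protonation charges, write canonical SMILES. This reproduces the key
behavior curation needs — a salt and its parent acid collapse to one
structure key — without depending on any vendor's tautomer model.
Tautomer canonicalization is intentionally not applied: open-toolkit
tautomer rules are unstable across versions, and a deterministic key
matters more here than maximal merging.

Duplicates merge to the **median** IC50 (midpoint of the central pair for
even counts), and pIC50 is recomputed from the merged IC50 rather than
averaging pIC50s — medians are robust to the order-of-magnitude outliers
typical of assay aggregation, and the recomputation keeps the
IC50 ↔ pIC50 invariant exact. The train/test split is plain random
(no activity stratification) with `floor(n × ratio)` training compounds,
so 227 compounds at ratio 0.75 give exactly 170/57.

Lipinski profiling uses five checks (MW ≤ 500, ALogP ≤ 5, HBD ≤ 5,
HBA ≤ 10, rotatable bonds ≤ 10) so that failure counts of 0–5 are
representable; `five_rules = FALSE` gives the canonical four-rule count.
The fifth criterion is a configuration choice, not settled chemistry.

## Preprocessing filters

Order: constant/quasi-constant removal, then pairwise-correlation removal,
then (inside each CV training partition) centering/scaling for
scale-sensitive learners. Quasi-constancy uses the near-zero-variance
convention — most-common/second-most-common frequency ratio > 19 **and**
distinct values < 10% of n — defaults chosen because they are the widely
used practice for this filter family; both are exposed. The correlation
filter greedily removes, from the worst |r| > 0.90 pair, the member with
the larger mean absolute correlation to everything else (ties: the
lexicographically later name), and its postcondition — no remaining pair
above the cutoff — is verified by exhaustive scan in the tests. Scaling
statistics are learned on training rows only; tree-based learners declare
`needs_scaling = FALSE` and receive raw features.

## Feature selection

CMIM and JMIM share one mutual-information estimator: equal-frequency
binning (default 10 bins; variables with at most 10 distinct values, e.g.
fingerprint bits, keep their levels) and plug-in entropies, in nats.
Conditional MI is computed on the joint binned table as
I(f; y | s) = I((f,s); y) − I(s; y). Both filters seed with the maximal
marginal MI; CMIM then maximizes the minimum *conditional* MI against the
selected set (so an exact copy of a selected feature scores ~0), JMIM the
minimum *joint* MI (so an interaction partner that is marginally silent
can win once its counterpart is selected). For JMIM the marginal
initialization is discarded after the first pick: joint MI is bounded
below by marginal MI, so keeping it in the running minimum would suppress
exactly the interaction features JMIM exists to find. Ties break to the
lower column index; k defaults to 30.

Boruta shadows the undecided features each iteration (column-permuted
copies, pool padded to at least five shadows late in the run for a stable
max-shadow reference), fits a seeded random forest with permutation
importance, counts a hit when a real feature beats the best shadow, and
decides with a two-sided binomial test at α = 0.05, Bonferroni-corrected
across the undecided features of that round. Permutation importance was
chosen over impurity importance because impurity scores are strictly
positive and drift upward for all features, which inflated false
confirmations in null simulations; with permutation importance the
false-confirmation rate on pure noise stays well below α.

The GA wrapper is standard: inclusion-bit chromosomes, fitness = mean
cross-validated RMSE of a given learner on the encoded subset, tournament
selection of size 3, uniform crossover (p = 0.9), per-bit mutation
(p = 1/p features), elitism of one (hence a non-increasing best-fitness
trace), empty chromosomes repaired by switching on one random bit.
Population 50 × 30 generations are desk-scale defaults; the method is
defined by the fitness, not these counts.

## Learners and tuning

All learners sit behind one registry with a fit/predict contract, seeded
determinism, and internal scaling for scale-sensitive members (SVM,
weighted kNN) — which makes their predictions invariant to affine feature
rescaling. The weighted kNN regressor is implemented in-package
(Minkowski distance, neighbour distances normalized by the (k+1)-th and
kernel-weighted: rectangular/triangular/gaussian). BART is registered but
requires an optional backend; without one it raises a typed
`qsarnest_learner_unavailable` error so pipelines can skip it explicitly.

Hyperparameter search is seeded random search (default budget 25
configurations, here often reduced to 8–10 at test scale) minimizing
inner-CV RMSE, ties to the first draw. Default grids are conventional
ranges: SVM cost 2⁻²–2⁶ and gamma 2⁻⁸–2² (log-uniform), forest mtry
fraction 0.1–0.9, kNN k 3–25, XGBoost depth 2–8 / learning rate
0.01–0.3 (log) / 100–600 rounds.

## Nested cross-validation and its metrics

The outer loop (default 10 folds; seeded shuffle, contiguous blocks, no
stratification) estimates generalization; everything adaptive — filters,
selection, tuning — reruns inside each outer-training partition. Metrics
are computed on the **pooled** out-of-fold vector rather than averaged
per fold: the pooled vector is what stacking consumes, pooled CCC is
well-defined where tiny per-fold CCCs are unstable, and the reference
mean ȳ in R² = 1 − SSE/SST is the mean of the pooled observed values.
This "true q²" can be negative — a model worse than the constant mean —
which is precisely the behavior y-randomization should expose. CCC uses
Lin's population (1/n) moments (sample-moment variant by flag); it
penalizes location/scale shift on top of scatter, making it the more
conservative agreement metric. Replicate runs (default 5 seeds) report
mean and sample sd, rounded half-up to 3 decimals — base `round()`'s
round-half-even would disagree with conventional table reporting on exact
ties.

y-randomization permutes the response (default 20 times; 5 at test scale)
and reruns the entire pipeline per permutation. The validity statistic is
Rp² = √R² · √(R² − Rr²) with Rr² the mean permuted R²; it is reported as
undefined (NA with a warning) when Rr² exceeds the genuine R², rather
than inventing a number.

## Stacking

Meta-features are out-of-fold predictions — the only leakage-safe choice.
One replicate represents each base model: the one whose CCC is closest to
the replicate mean CCC (ties to the earlier seed), i.e. a typical rather
than lucky run. The ensemble is evaluated by nested CV of the meta-learner
on the meta matrix with no selection stage and independently drawn folds;
for deployment, base models are refit on the full training set and the
meta-learner consumes their predictions.

## Applicability domains and screening

For fingerprints: a compound is inside the AD when its **maximum**
Tanimoto similarity to the training set strictly exceeds 0.20. Max is the
strictest common reading of "similarity to the training set"; a
mean-based variant is available by flag since the statistic is a genuine
modelling choice. The strict inequality matters at the boundary and is
tested at an exact-0.20 construction. For descriptors: an in-package
isolation forest (100 trees, subsample 256, split feature drawn from
`ntry = 10` candidates that vary in the node, depth cap ⌈log2 ψ⌉) with
the canonical anomaly score 2^(−E[h]/c(ψ)) and cutoff 0.5. On gaussian
training clouds this accepts the high-80s to low-90s percent of its own
training points depending on n — matching reference implementations of
the algorithm — while a 20-sd outlier scores ~0.7 and is cleanly
rejected.

Screening aggregates, per compound, only the models whose AD accepts it:
mean and median pIC50 and their relative standard deviation
(100·sd/mean, sample sd by default), with RSD flagged undefined below two
trusted predictions and compounds outside every AD retained with
`n_inside = 0` rather than silently dropped. Hit rates are half-up
percentages at two decimals.

## The synthetic generator

`gen_features()`/`gen_response()` emulate the *statistical* structure the
pipeline assumes: block-correlated gaussian descriptors or thresholded-
latent binary bits with marginal frequencies in [0.05, 0.6] (sparse
structural keys), injected constant/quasi-constant/redundant columns for
filter tests, and a sparse linear response with gaussian noise, affinely
mapped to mean 6 / sd 1.5 to span a realistic pIC50 range. Informative
features are kept mutually independent (block correlation applies to the
noise features) so the declared generative signal fraction
R\*² = Var(signal)/(Var(signal)+σ²) is exact, and the mapping is recorded
so truth is preserved. What it does **not** emulate: real structure-
activity landscapes (activity cliffs, scaffold clustering), correlated
informative descriptors, non-gaussian assay noise, or chemically valid
structures at scale (only the small hand-written curation fixture is real
chemistry). Passing tests therefore demonstrate that the machinery is
correct and honest — not that any particular real target is predictable.

Test- and example-scale runs use n = 300, p = 50, 5 informative features,
5 outer × 3 inner folds and 5 seeds — sizes at which nested CV with
Boruta and a tuned SVM comfortably brackets the generative R\*² of 0.75
while keeping a full suite run in minutes on one core.

## Known limitations

- Open Babel's logP is an atomic-contribution estimate; it is not
  numerically identical to other vendors' ALogP, so absolute Lipinski
  counts can differ at the boundary.
- MACCS bit definitions vary slightly across toolkits; keys are stable
  and deterministic within this package but not guaranteed bit-identical
  to other implementations.
- The isolation forest and weighted kNN are compact in-package
  implementations: correct by construction and by test, but not tuned
  for very large libraries (screening is linear in compounds × trees).
- Fold assignment is unstratified; with heavily skewed activity
  distributions, stratified variants would reduce replicate variance but
  are intentionally out of scope.
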