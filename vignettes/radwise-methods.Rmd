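---
title: "Rank-weighted hybrid feature selection: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-weighted hybrid feature selection: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radwise)
```

## The problem

Aptamer-based proteomic assays measure thousands of protein abundances per
serum sample. When samples are drawn before and after a treatment, the
question "which small set of proteins defines the treatment's proteomic
footprint?" is a feature-selection problem with two demands that pull in
opposite directions: the subset must classify treatment status accurately,
and it must be small enough to name, validate, and interpret. A single
selector run once on the full data gives an unstable answer -- rerunning it
on a slightly different subsample returns a different list.

`radwise` addresses the instability by running two complementary selectors
inside every training split of a k-fold cross-validation and aggregating
their choices into per-feature integer weights. Features picked repeatedly,
by both selectors, accumulate high weight; one-off picks accumulate little.
Sweeping a minimum-weight threshold then trades panel size against
cross-validated accuracy explicitly.

## The procedure

Given a samples-by-features table with binary labels (0 = pre-treatment,
1 = post-treatment):

1. **Fold planning.** A seeded, stratified k-fold partition (default
   k = 5). Stratification keeps the class ratio within one sample per fold.
2. **Per-fold selection.** On each fold's training samples only, two
   selectors run:
   - *mRMR*: greedy forward selection of
     `ceiling(log2(p))` features. The first pick maximizes relevance to the
     class; each later pick balances relevance against redundancy with the
     already-selected set.
   - *LASSO*: an L1-penalized linear fit of the numeric 0/1 label over a
     100-point geometric penalty grid spanning three decades below the
     smallest all-zero penalty; the penalty is chosen by internal 10-fold
     cross-validation on squared error and the selected features are
     exactly those with nonzero coefficients.
3. **Rank weighting.** Each selector carries an integer weight equal to its
   rank: by default mRMR = 2 and LASSO = 1 (the ranking
   `rank_fs_methods()` derives from standalone accuracy can replace the
   default on new data). Every time a selector picks a feature in a fold,
   the feature's weight increases by the selector's weight. With 5 folds
   the attainable range is 0 to 15.
4. **Threshold sweep.** For every minimum weight from 15 down to 1, the
   induced candidate set (all features at or above the threshold) is scored
   by five classifiers with cross-validation. Candidate sets are nested, so
   repeated sets reuse their metrics.
5. **Final choice.** The (threshold, classifier) cell with the highest mean
   accuracy wins; exact ties fall to the smaller feature count, then the
   larger threshold, then classifier registration order.

## The selectors in detail

### mRMR estimators

The textbook criterion is defined for discrete variables: relevance and
redundancy are both mutual information, combined as a difference. Abundance
data are continuous, so three estimator modes are provided
(`mrmr_config()`):

- `"fstat"` (default): relevance is the one-way F statistic against the
  class; redundancy is the mean absolute Pearson correlation with the
  selected set; the criterion is the **quotient** F / mean |cor|. The two
  quantities live on incommensurate scales (F is unbounded, |cor| is at
  most 1), so a subtractive combination degenerates into pure relevance
  ranking -- measured on the package's own synthetic panels it selects
  near-duplicate proxies and misses planted groups. The quotient keeps the
  redundancy term binding and is the form established for continuous data
  in widely used mRMR implementations.
- `"fstat-diff"`: the subtractive variant of the same pair, kept for
  comparison.
- `"mi"`: both terms are discrete mutual information after quantile
  discretization (default 10 bins), combined as a difference -- the strict
  information-theoretic criterion, and the mode the exhaustive test oracles
  check step by step. With both terms in nats the difference form is
  internally consistent.

The greedy loop breaks score ties toward the lowest column index, making
every mode deterministic.

### LASSO on a 0/1 response

The selection model is a squared-error LASSO of the numeric 0/1 label, not
a logistic fit: the sparse linear fit *is* the selection criterion, and the
penalized least-squares form has an exact path and fast solvers. Features
are standardized internally, so selection is invariant to positive
rescaling of any column. A logistic variant is available
(`family = "binomial"`) but is not the default. "Selected" means an exactly
nonzero coefficient -- the coordinate-descent solver zeroes inactive
coefficients exactly, so no threshold is involved.

## Classifiers and metrics

Five classifiers with fixed defaults score candidate sets: RBF-kernel SVM
(cost 1), L2-penalized logistic regression (unit inverse regularization),
5-nearest-neighbors, a 100-tree random forest, and real (probability-based)
adaptive boosting of 50 depth-1 stumps with learning rate 1. All stochastic
fits are re-seeded per call (default seed 0), so repeated runs are
byte-identical. SVM and logistic inputs are standardized per fold with
training-fold statistics; trees, boosting and neighbors consume raw values.

Accuracy, precision, recall, specificity and F1 follow their confusion-count
definitions; a zero denominator yields an undefined (`NA`) metric that is
excluded from fold means with a warning rather than silently coded as 0.
AUC uses the Mann-Whitney rank form with midranks for ties, which equals
the trapezoidal ROC area and is invariant under monotone score transforms.
Fold aggregation reports mean and population standard deviation over the k
fold values.

## The synthetic panel generator

`generate_dataset()` emulates the data regime the pipeline targets: paired
pre/post samples for `n_patients` (default 82, hence 164 samples),
log-normal abundances on an RFU-like positive scale (baseline log-mean 8,
log-sd 1), a small planted informative subset (default 8) whose
log-abundance shifts by `effect_log_shift` (default 0.8) in post samples,
`n_proxies_per_informative` (default 2) correlated copies of each
informative feature (log-space correlation 0.9, inheriting an attenuated
shift), independent noise for the rest, and a mild per-sample multiplicative
scale jitter (log-sd 0.05) mimicking residual assay scale wobble after
normalization. Defaults were chosen once as a realistic mid-strength
regime: a 0.8-sd shift gives per-feature AUC near 0.71, strong enough that
selectors should find the planted group structure but weak enough that no
single feature classifies well alone.

What the generator does **not** emulate: plate and hybridization batch
effects, heavy-tailed or heteroscedastic noise, missingness, and
biological correlation structure beyond the planted proxy blocks. Passing
tests on these panels therefore demonstrates correctness of the machinery
and recoverability of planted structure under clean conditions -- not
performance on real assay data.

Ground truth (which features are informative, proxy, or noise) is returned
beside the feature table, never inside it, so it cannot leak into
selection. `planted_recovery_recall()` scores a selection against the
truth, counting a proxy as recovering its parent.

## Numerical and design choices

- **Fold reuse vs. nesting.** By default the sweep evaluates candidate
  sets with the *same* fold plan used for selection -- the single-CV
  protocol. This is deliberate and has a documented cost: a feature
  selected by fold 1's training data is evaluated on folds whose test
  samples were part of that training data, so the grid's accuracies are
  optimistic, increasingly so for low thresholds whose sets aggregate many
  fold-level picks. On null panels (no planted signal) this optimism alone
  can push the chosen set's apparent accuracy far above chance, and on
  signal panels it tilts the accuracy-maximizing rule toward larger
  subsets. An `evaluation_plan` argument accepts a fresh fold plan, which
  decouples the evaluation partition but cannot remove the optimism
  entirely (the union of fold selections has seen every sample). Honest
  generalization estimates for the *final chosen subset* require external
  validation data; the package reports the protocol's numbers as defined
  and documents the caveat rather than silently changing the protocol.
- **Selection rule.** Accuracy drives the final choice; other metrics are
  reported, never optimized. Ties are broken only on exact equality.
- **Empty candidate sets** (thresholds above every accumulated weight) are
  enumerated in the grid with zero features and undefined metrics, but
  never scored.
- **Degenerate inputs.** Zero-variance features get zero relevance and
  undefined correlation treated as zero redundancy; single-class training
  folds abort with the fold and selector named; missing values are
  rejected at load rather than imputed.
- **Determinism.** Every stochastic step (fold assignment, penalty CV,
  classifier fits) derives its seed from the pipeline seed; two runs with
  identical inputs and seed produce byte-identical JSON reports.
- **Patient pairing.** Pre/post pairs from one patient land in different
  folds under the default sample-level stratification, which leaks patient
  identity across folds. `group_by_patient = TRUE` co-assigns each
  patient's samples; it is off by default to mirror plain sample-level
  cross-validation, and the report records which was used.
- **Problem sizes in the test suite.** Unit tests run panels of 20-50
  samples and tens of features; the recovery and null acceptance checks run
  the full default generator (164 samples, 1000 features) across five
  seeds. These sizes were chosen so the full suite completes on a single
  CPU in well under half an hour while still exercising the
  high-dimensional regime (features far exceeding samples).

## Known limitations

- The human-protein filter requires caller-supplied flags; the SomaScan
  ADAT dialect is not parsed directly -- export to CSV/TSV first.
- Aptamers mapping to the same protein are treated as independent columns.
- The fold-change baseline (`heuristic_baseline_select()`) requires
  complete pre/post pairing and makes no multiplicity adjustment; it is a
  comparator, not a recommended selector.
- With strongly correlated feature groups, accumulated weight spreads
  across group members (selectors alternate representatives between
  folds), so high-threshold candidate sets can under-cover groups and the
  accuracy-maximizing rule can prefer larger, lower-threshold sets. The
  weight table and full grid are exported so users can inspect this
  trade-off directly.

## A worked run

```{r example, eval = FALSE}
panel <- generate_dataset(synthetic_spec(
  n_patients = 40, n_features = 300, n_informative = 5, seed = 1
))
res <- run_radwise(panel$table, folds = 5, seed = 1, verbose = TRUE)
res$sweep$chosen
planted_recovery_recall(res$sweep$chosen$features, panel$truth)
write_selection_report(res, "report.json")
```
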