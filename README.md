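# radwise

Rank-based hybrid feature weighting and selection for high-dimensional
proteomic panels with a binary treatment-status outcome.

## The problem

Modern aptamer panels quantify thousands of serum proteins per sample. Given
paired samples drawn before and after a treatment, the analysis goal is a
*small, nameable* protein subset that classifies treatment status with high
cross-validated accuracy. A single feature selector run once is unstable in
this regime (far more features than samples); `radwise` stabilizes the
answer by aggregating two complementary selectors across cross-validation
folds.

## The method

Let `X` be the `n x p` abundance matrix and `y ∈ {0,1}ⁿ` the pre/post
labels. Inside each of `k` folds (default `k = 5`), two selectors run on
the training split only:

- **mRMR** — greedy forward selection of `⌈log₂ p⌉` features maximizing
  class relevance against redundancy with the already-selected set
  `S`. The discrete criterion is
  `f(Xᵢ) = I(Y, Xᵢ) − (1/|S|) Σ_{Xₛ∈S} I(Xₛ, Xᵢ)`;
  for continuous abundances the default estimator is the quotient of the
  one-way F statistic and the mean absolute correlation.
- **LASSO** — `β̂ = argmin_β ‖y − Xβ‖² + λ Σ|βⱼ|` with `λ` chosen by
  10-fold cross-validation on a geometric grid; selected features are those
  with `β̂ⱼ ≠ 0`.

Each selector carries an integer rank weight (default mRMR = 2, LASSO = 1).
Every feature accumulates, over all folds, the weights of the selectors
that picked it — between 0 and `k·(2+1) = 15`. Sweeping a minimum-weight
threshold `w_min` from 15 down to 1 induces nested candidate subsets, each
scored by five classifiers (SVM, logistic regression, KNN, random forest,
AdaBoost) with the standard confusion-matrix metrics plus rank-based AUC.
The final subset maximizes mean accuracy, with ties broken by fewer
features, then larger threshold.

A synthetic generator (`generate_dataset()`) produces paired pre/post
panels with planted informative features and correlated proxies, so the
whole pipeline is testable without any external data.

## Worked example

```r
library(radwise)

panel <- generate_dataset(synthetic_spec(
  n_patients = 40, n_features = 300, n_informative = 5, seed = 1
))
res <- run_radwise(panel$table, folds = 5, seed = 1)
res
#> <sweep_result> thresholds 15..1, 5 classifiers
#>   chosen: w_min = 2, lr, 38 features, mean ACC = 0.9000

planted_recovery_recall(res$sweep$chosen$features, panel$truth)
#> [1] 1
```

The chosen cell says: keeping every feature whose accumulated weight is at
least 2 yields a 38-feature panel whose logistic-regression 5-fold mean
accuracy is 0.90, the best cell of the 15 x 5 grid; that panel covers all
5 planted signal groups (recall 1). The top of the grid shows the
size/accuracy trade-off directly — high thresholds give tiny panels at
lower accuracy:

```r
head(subset(res$sweep$grid, classifier == "lr" & !is.na(ACC),
            c(w_min, n_features, ACC, AUC, F1)), 8)
#>  w_min n_features   ACC   AUC    F1
#>     15          1 0.637 0.759 0.585
#>     14          1 0.637 0.759 0.585
#>     13          1 0.637 0.759 0.585
#>     12          1 0.637 0.759 0.585
#>     11          1 0.637 0.759 0.585
#>     10          4 0.750 0.866 0.755
#>      9          4 0.750 0.866 0.755
#>      8          5 0.787 0.887 0.783
```

`write_selection_report(res, "report.json")` serializes the chosen subset,
the full grid and the configuration; reports are byte-identical across
repeated runs with the same seed. Real data enter through
`load_feature_table()` (CSV/TSV, either orientation, declared label
mapping) and can be pre-filtered to human protein features with
`filter_human_features()`. A thin command-line wrapper lives at
`inst/cli/radwise.R` (subcommands `run` and `synth`).

Note on evaluation: by default the sweep reuses the selection folds (the
single-CV protocol), so grid accuracies are optimistic — see the methods
vignette (`vignettes/radwise-methods.Rmd`) for the analysis and the
`evaluation_plan`/`group_by_patient` switches.

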