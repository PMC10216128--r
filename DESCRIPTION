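Package: radwise
Title: Rank-Based Hybrid Feature Weighting and Selection for Proteomic Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid ensemble feature selection for high-dimensional proteomic
    (and other omics) panels with a binary outcome. Two base selectors -- a
    greedy minimum-redundancy-maximum-relevance (mRMR) criterion and the
    LASSO with cross-validated penalty -- are run inside the training split of
    every cross-validation fold; each feature accumulates an integer weight
    proportional to the rank of the selector that picked it. Sweeping a
    minimum-weight threshold over the accumulated weights and scoring every
    candidate subset with a panel of classifiers yields the smallest feature
    subset with the highest cross-validated accuracy. Includes a synthetic
    paired pre/post-treatment panel generator with planted informative
    features and correlated proxies, a statistical fold-change baseline, and
    a no-selection baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    e1071,
    glmnet,
    jsonlite,
    randomForest,
    rpart,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
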