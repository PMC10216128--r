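# small two-classifier panel keeps sweep tests quick
fast_classifiers <- function() {
  list(lr = classifier_spec("lr"), knn = classifier_spec("knn"))
}

test_that("the sweep enumerates every threshold from w_max down to 1", {
  t <- random_panel(n = 30, p = 12, signal = 2, n_signal = 2, seed = 51)
  plan <- plan_folds(t, k_folds = 5, seed = 0)
  sel <- collect_fold_selections(t, plan, mrmr_cfg = mrmr_config(k = 3),
                                 lasso_cv_folds = 5, seed = 0)
  wt <- accumulate_weights(sel, t$feature_names)
  sw <- sweep_min_weights(t, wt, fast_classifiers(), plan)
  expect_identical(sw$w_max, 15L)
  expect_setequal(unique(sw$grid$w_min), 1:15)
  expect_identical(nrow(sw$grid), 15L * 2L)
  # nesting reflected in grid feature counts
  per_w <- sw$grid$n_features[sw$grid$classifier == "lr"][order(15:1)]
  expect_true(all(diff(sw$grid$n_features[sw$grid$classifier == "lr"]) >= 0))
})

test_that("thresholds inducing the same feature set share identical metrics", {
  t <- random_panel(n = 30, p = 10, signal = 2, n_signal = 2, seed = 53)
  plan <- plan_folds(t, k_folds = 5, seed = 0)
  wt <- make_weight_table(
    setNames(c(15L, 15L, 7L, rep(0L, 7)), t$feature_names), 15L)
  sw <- sweep_min_weights(t, wt, fast_classifiers(), plan)
  g <- sw$grid[sw$grid$classifier == "lr", ]
  # thresholds 8..15 all induce the same two-feature set
  high <- g[g$w_min >= 8, ]
  expect_true(all(high$n_features == 2))
  expect_equal(length(unique(high$ACC)), 1L)
  # 1..7 induce the three-feature set
  low <- g[g$w_min <= 7, ]
  expect_true(all(low$n_features == 3))
  expect_equal(length(unique(low$ACC)), 1L)
})

test_that("empty candidate sets are recorded but never scored", {
  t <- random_panel(n = 30, p = 10, signal = 2, n_signal = 2, seed = 55)
  plan <- plan_folds(t, k_folds = 5, seed = 0)
  wt <- make_weight_table(
    setNames(c(5L, 4L, rep(0L, 8)), t$feature_names), 15L)
  sw <- sweep_min_weights(t, wt, fast_classifiers(), plan)
  g6 <- sw$grid[sw$grid$w_min >= 6, ]
  expect_true(all(g6$n_features == 0L))
  expect_true(all(is.na(g6$ACC)))
  expect_false(anyNA(sw$grid$ACC[sw$grid$w_min <= 5]))
  empty_wt <- make_weight_table(setNames(rep(0L, 10), t$feature_names), 15L)
  expect_error(sweep_min_weights(t, empty_wt, fast_classifiers(), plan),
               "trivial")
})

test_that("final selection follows the lexicographic rule and is permutation-stable", {
  sets <- list(`3` = list(w_min = 3L, features = paste0("f", 1:8)),
               `2` = list(w_min = 2L, features = paste0("f", 1:11)),
               `1` = list(w_min = 1L, features = paste0("f", 1:11)))
  grid <- data.frame(
    w_min = c(3L, 2L, 1L, 3L),
    classifier = c("lr", "lr", "lr", "svm"),
    n_features = c(8L, 11L, 11L, 8L),
    ACC = c(0.964, 0.964, 0.964, 0.95)
  )
  res <- list(grid = grid, sets = sets, classifier_order = c("svm", "lr"))
  ch <- select_final(res)
  expect_identical(ch$w_min, 3L) # same ACC, fewer features wins
  expect_identical(ch$n_features, 8L)

  # equal ACC and equal size: larger threshold wins
  grid2 <- data.frame(
    w_min = c(10L, 9L), classifier = "lr", n_features = 8L, ACC = 0.96
  )
  sets2 <- list(`10` = list(features = paste0("f", 1:8)),
                `9` = list(features = paste0("f", 1:8)))
  ch2 <- select_final(list(grid = grid2, sets = sets2,
                           classifier_order = "lr"))
  expect_identical(ch2$w_min, 10L)

  # classifier registration order breaks the last tie
  grid3 <- data.frame(
    w_min = 5L, classifier = c("knn", "svm"), n_features = 4L, ACC = 0.9
  )
  sets3 <- list(`5` = list(features = paste0("f", 1:4)))
  ch3 <- select_final(list(grid = grid3, sets = sets3,
                           classifier_order = c("svm", "lr", "knn")))
  expect_identical(ch3$classifier, "svm")

  # permutation stability
  set.seed(57)
  for (i in 1:10) {
    perm <- res
    perm$grid <- res$grid[sample(nrow(res$grid)), ]
    expect_identical(select_final(perm), ch)
  }

  # single cell
  ch4 <- select_final(list(
    grid = data.frame(w_min = 2L, classifier = "lr", n_features = 3L, ACC = 0.8),
    sets = list(`2` = list(features = c("a", "b", "c"))),
    classifier_order = "lr"
  ))
  expect_identical(ch4$acc, 0.8)
})

test_that("the fold-change heuristic applies both thresholds", {
  vals <- matrix(1, nrow = 6, ncol = 3,
                 dimnames = list(NULL, c("up_all", "up_some", "flat")))
  # patients x features: post/pre ratios planted directly
  pre <- c(1, 1, 1)
  ratios <- rbind(c(1.6, 1.6, 1.0), c(1.8, 1.2, 1.0), c(1.7, 1.7, 1.0))
  rows <- list()
  for (pat in 1:3) {
    rows[[2 * pat - 1]] <- pre
    rows[[2 * pat]] <- pre * ratios[pat, ]
  }
  vals <- do.call(rbind, rows)
  colnames(vals) <- c("up_all", "up_some", "flat")
  t <- feature_table(vals, labels = rep(c(0L, 1L), 3),
                     patient_ids = rep(paste0("P", 1:3), each = 2))
  expect_identical(
    heuristic_baseline_select(t, 1.5, min_patient_fraction = 1.0),
    "up_all")
  expect_setequal(
    heuristic_baseline_select(t, 1.5, min_patient_fraction = 0.6),
    c("up_all", "up_some"))
  expect_error(heuristic_baseline_select(t, 1.0, 0.5), "> 1")
  expect_error(heuristic_baseline_select(t, 1.5, 0), "fraction")
  t_unpaired <- t
  t_unpaired$labels[2] <- 0L
  expect_error(heuristic_baseline_select(t_unpaired, 1.5, 1), "P1")
})

test_that("the heuristic keeps correlated proxies that redundancy-aware selection drops", {
  panel <- generate_dataset(synthetic_spec(
    n_patients = 40, n_features = 60, n_informative = 3,
    effect_log_shift = 0.9, seed = 61))
  t <- panel$table
  hits <- heuristic_baseline_select(t, 1.3, min_patient_fraction = 0.6)
  truth <- panel$truth
  proxies <- truth$feature[truth$role == "proxy"]
  # the fold-change screen picks up proxies alongside their parents
  expect_gte(length(intersect(hits, proxies)), 2)
  # redundancy-aware greedy selection with the MI criterion covers the
  # planted groups without stacking several members of one group
  sel <- mrmr_rank(t, mrmr_config(k = 3, estimator = "mi"))$feature
  groups <- ifelse(truth$role == "proxy", truth$parent, truth$feature)
  names(groups) <- truth$feature
  expect_gte(length(unique(groups[sel])), 2)
})

test_that("the no-selection baseline reports the full panel size", {
  t <- random_panel(n = 30, p = 15, signal = 2, n_signal = 2, seed = 63)
  plan <- plan_folds(t, k_folds = 5, seed = 0)
  base <- evaluate_no_fs_baseline(t, fast_classifiers(), plan)
  expect_named(base, c("lr", "knn"))
  expect_true(all(vapply(base, `[[`, integer(1), "n_features") == 15L))
  base2 <- evaluate_no_fs_baseline(t, fast_classifiers(), plan)
  expect_identical(base$lr$per_fold, base2$lr$per_fold)
})
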