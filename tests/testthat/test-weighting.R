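test_that("stratified folds balance sizes and class counts", {
  set.seed(1)
  n_pat <- 82
  labels <- rep(c(0L, 1L), n_pat)
  vals <- matrix(rnorm(2 * n_pat * 3), ncol = 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  t <- feature_table(vals, labels,
                     patient_ids = rep(sprintf("P%02d", 1:n_pat), each = 2))
  plan <- plan_folds(t, k_folds = 5, stratified = TRUE, seed = 0)

  sizes <- sort(vapply(plan$assignments, function(a) length(a$test), integer(1)),
                decreasing = TRUE)
  expect_identical(sizes, c(33L, 33L, 33L, 33L, 32L))
  all_test <- sort(unlist(lapply(plan$assignments, `[[`, "test")))
  expect_identical(all_test, seq_len(164L)) # disjoint cover
  for (a in plan$assignments) {
    expect_length(intersect(a$train, a$test), 0)
    cls <- table(factor(t$labels[a$test], levels = c(0, 1)))
    expect_lte(abs(cls[[1]] - cls[[2]]), 1)
  }

  plan2 <- plan_folds(t, k_folds = 5, stratified = TRUE, seed = 0)
  expect_identical(plan, plan2)
  plan3 <- plan_folds(t, k_folds = 5, stratified = TRUE, seed = 1)
  expect_false(identical(plan$assignments, plan3$assignments))
})

test_that("patient grouping never splits a patient across folds", {
  set.seed(2)
  n_pat <- 82
  labels <- rep(c(0L, 1L), n_pat)
  pats <- rep(sprintf("P%02d", 1:n_pat), each = 2)
  t <- feature_table(matrix(rnorm(164 * 2), ncol = 2,
                            dimnames = list(NULL, c("a", "b"))),
                     labels, patient_ids = pats)
  plan <- plan_folds(t, k_folds = 5, group_by_patient = TRUE, seed = 0)
  fold_of <- integer(164)
  for (f in seq_along(plan$assignments)) fold_of[plan$assignments[[f]]$test] <- f
  expect_true(all(tapply(fold_of, pats, function(z) length(unique(z))) == 1))
})

test_that("fold planning rejects degenerate requests", {
  t <- random_panel(n = 12, p = 3, seed = 3)
  expect_error(plan_folds(t, k_folds = 1), ">= 2")
  expect_error(plan_folds(t, k_folds = 7), "at least")
  t$labels <- c(rep(0L, 3), rep(1L, 9))
  expect_error(plan_folds(t, k_folds = 4, stratified = TRUE), "fewer samples")
})

test_that("weight accumulation reproduces the worked extremes and conserves mass", {
  methods <- list(method_rank("mrmr", 2L), method_rank("lasso", 1L))
  records <- list()
  for (f in 1:5) {
    records[[length(records) + 1L]] <-
      list(fold = f, method_id = "mrmr", weight = 2L, features = c("F", "G"))
    records[[length(records) + 1L]] <-
      list(fold = f, method_id = "lasso", weight = 1L,
           features = if (f <= 3) c("F", "H") else "F")
  }
  sel <- make_selections(records, k_folds = 5L, methods = methods)
  wt <- accumulate_weights(sel, c("F", "G", "H", "Z"))
  expect_identical(wt$w_max, 15L)
  expect_identical(unname(wt$weights["F"]), 15L) # both methods, every fold
  expect_identical(unname(wt$weights["G"]), 10L) # mrmr only
  expect_identical(unname(wt$weights["H"]), 3L)  # lasso in 3 folds
  expect_identical(unname(wt$weights["Z"]), 0L)  # never selected
  # conservation: total weight = sum over records of weight * |selection|
  total <- sum(vapply(records, function(r) r$weight * length(r$features),
                      numeric(1)))
  expect_identical(sum(wt$weights), as.integer(total))
  bad <- make_selections(
    list(list(fold = 1, method_id = "mrmr", weight = 2L, features = "Q")),
    5L, methods)
  expect_error(accumulate_weights(bad, c("F", "G")), "not in panel")
})

test_that("candidate sets threshold, order, and nest", {
  wt <- make_weight_table(c(A = 15L, B = 14L, C = 13L, D = 7L, E = 0L), 15L)
  cs <- candidate_set(wt, 13)
  expect_identical(cs$features, c("A", "B", "C"))
  expect_identical(candidate_set(wt, 1)$features, c("A", "B", "C", "D"))
  expect_identical(candidate_set(wt, 15)$features, "A")
  expect_length(candidate_set(wt, 16 - 1)$features, 1)
  expect_error(candidate_set(wt, 0), "w_min")
  expect_error(candidate_set(wt, 16), "w_min")

  # nesting over random weight tables
  set.seed(41)
  for (i in 1:100) {
    w <- setNames(as.integer(sample(0:15, 30, replace = TRUE)),
                  sprintf("f%02d", 1:30))
    wt_i <- make_weight_table(w, 15L)
    sizes <- vapply(1:15, function(v) length(candidate_set(wt_i, v)$features),
                    integer(1))
    expect_true(all(diff(sizes) <= 0))
    for (v in c(3, 9)) {
      expect_true(all(candidate_set(wt_i, v + 1)$features %in%
                        candidate_set(wt_i, v)$features))
    }
  }
})

test_that("fold selections run selectors on training samples only", {
  t <- random_panel(n = 40, p = 30, signal = 2.5, n_signal = 2, seed = 43)
  plan <- plan_folds(t, k_folds = 5, seed = 0)
  sel <- collect_fold_selections(t, plan, mrmr_cfg = mrmr_config(k = 4),
                                 lasso_cv_folds = 5, seed = 0)
  expect_length(sel, 10) # 5 folds x 2 methods
  mrmr_recs <- Filter(function(r) r$method_id == "mrmr", sel)
  expect_true(all(vapply(mrmr_recs, function(r) length(r$features), integer(1)) == 4))
  # the dominant planted feature appears in every selection list
  expect_true(all(vapply(mrmr_recs, function(r) "f01" %in% r$features ||
                           "f02" %in% r$features, logical(1))))
  sel2 <- collect_fold_selections(t, plan, mrmr_cfg = mrmr_config(k = 4),
                                  lasso_cv_folds = 5, seed = 0)
  expect_identical(sel, sel2)
})

test_that("selector ranking orders by accuracy then set size", {
  # one perfectly separating feature: both selectors find it, both reach
  # accuracy 1, so the tie falls to the smaller mean selected-set size
  t <- random_panel(n = 40, p = 10, signal = 10, n_signal = 1, seed = 47)
  plan <- plan_folds(t, k_folds = 5, seed = 0)
  ranked <- rank_fs_methods(t, plan, mrmr_cfg = mrmr_config(k = 5),
                            lasso_cv_folds = 5, seed = 0)
  standalone <- attr(ranked, "standalone")
  expect_identical(standalone$method_id, c("mrmr", "lasso"))
  ids <- vapply(ranked, `[[`, character(1), "method_id")
  ws <- vapply(ranked, `[[`, integer(1), "weight")
  expect_setequal(ws, c(1L, 2L))
  if (standalone$mean_acc[1] == standalone$mean_acc[2]) {
    smaller <- standalone$method_id[which.min(standalone$mean_size)]
    expect_identical(ids[ws == 2L], smaller)
  } else {
    best <- standalone$method_id[which.max(standalone$mean_acc)]
    expect_identical(ids[ws == 2L], best)
  }
  single <- rank_fs_methods(t, plan, method_ids = "mrmr",
                            mrmr_cfg = mrmr_config(k = 5), seed = 0)
  expect_identical(single[[1]]$weight, 1L)
})
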