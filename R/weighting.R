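#' Plan cross-validation folds
#'
#' Deterministic (seeded) k-fold partition of the samples. Stratified by
#' default so each test fold keeps the class ratio within one sample; with
#' `group_by_patient`, all samples of a patient are assigned to the same
#' fold (pre/post pairs from one patient in different folds leak patient
#' identity between train and test -- the default mirrors plain sample-level
#' folding, but the switch is exposed).
#'
#' @param table a [feature_table()].
#' @param k_folds number of folds (default 5).
#' @param stratified preserve the class ratio in every fold.
#' @param group_by_patient keep all samples of a patient in one fold
#'   (requires `patient_ids`).
#' @param seed integer seed.
#' @return an object of class `fold_plan`: `k_folds`, `assignments` (list of
#'   `list(train, test)` index vectors), `stratified`, `group_by_patient`,
#'   `seed`.
#' @export
plan_folds <- function(table, k_folds = 5L, stratified = TRUE,
                       group_by_patient = FALSE, seed = 0L) {
  n <- n_samples(table)
  k_folds <- as.integer(k_folds)
  if (k_folds < 2L) stop("`k_folds` must be >= 2", call. = FALSE)
  if (n < 2L * k_folds) {
    stop("need at least 2 * k_folds samples", call. = FALSE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  fold_of <- integer(n)
  if (group_by_patient) {
    if (is.null(table$patient_ids)) {
      stop("`group_by_patient` requires patient_ids", call. = FALSE)
    }
    patients <- sample(unique(table$patient_ids))
    pf <- ((seq_along(patients) - 1L) %% k_folds) + 1L
    fold_of <- pf[match(table$patient_ids, patients)]
  } else if (stratified) {
    offset <- 0L
    for (cls in c(0L, 1L)) {
      idx <- which(table$labels == cls)
      if (length(idx) < k_folds) {
        stop(sprintf("class %d has fewer samples (%d) than folds (%d)",
                     cls, length(idx), k_folds), call. = FALSE)
      }
      idx <- sample(idx)
      fold_of[idx] <- ((offset + seq_along(idx) - 1L) %% k_folds) + 1L
      offset <- offset + length(idx)
    }
  } else {
    idx <- sample(n)
    fold_of[idx] <- ((seq_len(n) - 1L) %% k_folds) + 1L
  }
  assignments <- lapply(seq_len(k_folds), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
  structure(
    list(k_folds = k_folds, assignments = assignments,
         stratified = stratified, group_by_patient = group_by_patient,
         seed = as.integer(seed)),
    class = "fold_plan"
  )
}

#' Declare a selector and its rank weight
#'
#' Each selector carries a positive integer weight -- its rank among the
#' registered selectors (best-performing selector gets the largest weight).
#' The defaults reproduce the fixed ranking mRMR = 2, LASSO = 1; use
#' [rank_fs_methods()] to derive weights from standalone accuracy on a new
#' dataset.
#'
#' @param method_id `"mrmr"` or `"lasso"`.
#' @param weight positive integer rank weight.
#' @return an object of class `method_rank`.
#' @export
method_rank <- function(method_id = c("mrmr", "lasso"), weight) {
  method_id <- match.arg(method_id)
  weight <- as.integer(weight)
  if (is.na(weight) || weight < 1L) {
    stop("`weight` must be a positive integer", call. = FALSE)
  }
  structure(list(method_id = method_id, weight = weight),
            class = "method_rank")
}

#' Default selector ranking: mRMR = 2, LASSO = 1
#' @return list of two [method_rank()] objects.
#' @export
default_methods <- function() {
  list(method_rank("mrmr", 2L), method_rank("lasso", 1L))
}

# run one selector on a (training) feature table, return feature names
run_selector <- function(method_id, train, mrmr_cfg, lasso_cv_folds, seed) {
  switch(method_id,
    mrmr = mrmr_rank(train, mrmr_cfg)$feature,
    lasso = lasso_select(train, cv_folds = lasso_cv_folds, seed = seed)$selected,
    stop("unknown selector: ", method_id, call. = FALSE)
  )
}

#' Run every selector inside every fold
#'
#' For each fold of the plan, each registered selector is fit on that fold's
#' training samples only; the selected feature lists are recorded per
#' (fold, method) for later weight accumulation.
#'
#' @param table a [feature_table()].
#' @param plan a [plan_folds()] plan.
#' @param methods list of [method_rank()] (default [default_methods()]).
#' @param mrmr_cfg optional [mrmr_config()]; defaults to the F-statistic
#'   estimator with `k = default_k(n_features)`.
#' @param lasso_cv_folds folds for the LASSO penalty cross-validation.
#' @param seed pipeline seed; each fold's LASSO penalty CV uses
#'   `seed + fold` so folds are decoupled but reproducible.
#' @return an object of class `fold_selections`: a list of records
#'   `list(fold, method_id, weight, features)`, with attributes `k_folds`
#'   and `methods`.
#' @export
collect_fold_selections <- function(table, plan, methods = default_methods(),
                                    mrmr_cfg = NULL, lasso_cv_folds = 10L,
                                    seed = 0L) {
  if (is.null(mrmr_cfg)) mrmr_cfg <- mrmr_config(k = default_k(n_features(table)))
  records <- list()
  for (f in seq_len(plan$k_folds)) {
    train <- subset_samples(table, plan$assignments[[f]]$train)
    if (length(unique(train$labels)) < 2L) {
      stop(sprintf("fold %d: training labels are single-class", f),
           call. = FALSE)
    }
    for (m in methods) {
      feats <- tryCatch(
        run_selector(m$method_id, train, mrmr_cfg, lasso_cv_folds, seed + f),
        error = function(e) {
          stop(sprintf("selector '%s' failed on fold %d: %s",
                       m$method_id, f, conditionMessage(e)), call. = FALSE)
        }
      )
      records[[length(records) + 1L]] <- list(
        fold = f, method_id = m$method_id, weight = m$weight, features = feats
      )
    }
  }
  structure(records, class = "fold_selections",
            k_folds = plan$k_folds, methods = methods)
}

#' Accumulate rank-based feature weights across folds and selectors
#'
#' Every time a selector picks a feature in a fold, the feature's weight is
#' incremented by that selector's rank weight. With 5 folds and weights
#' mRMR = 2, LASSO = 1, a feature picked by both selectors in every fold
#' accumulates the maximum weight 15; a feature never picked stays at 0.
#' The total of all weights equals the sum over (fold, method) of the
#' method weight times the size of its selected set (conservation).
#'
#' @param selections a [collect_fold_selections()] result.
#' @param feature_names all feature names of the panel; every selected name
#'   must be among them.
#' @return an object of class `weight_table`: `weights` (named integer
#'   vector over all features), `w_max` (`k_folds * sum(method weights)`),
#'   `provenance` (the selections).
#' @export
accumulate_weights <- function(selections, feature_names) {
  w <- stats::setNames(integer(length(feature_names)), feature_names)
  for (rec in selections) {
    unknown <- setdiff(rec$features, feature_names)
    if (length(unknown)) {
      stop("selected feature not in panel: ", unknown[1L], call. = FALSE)
    }
    w[rec$features] <- w[rec$features] + rec$weight
  }
  methods <- attr(selections, "methods")
  k_folds <- attr(selections, "k_folds")
  w_max <- k_folds * sum(vapply(methods, `[[`, integer(1), "weight"))
  structure(list(weights = w, w_max = as.integer(w_max),
                 provenance = selections),
            class = "weight_table")
}

#' @export
print.weight_table <- function(x, ...) {
  nz <- sum(x$weights > 0)
  cat(sprintf("<weight_table> %d/%d features with weight > 0; w_max = %d\n",
              nz, length(x$weights), x$w_max))
  invisible(x)
}

#' Export a weight table as CSV
#'
#' One row per feature with nonzero weight (feature, weight), ordered by
#' weight descending then name.
#'
#' @param weight_table a [accumulate_weights()] result.
#' @param path output path.
#' @param all include zero-weight features too.
#' @export
write_weight_table <- function(weight_table, path, all = FALSE) {
  w <- weight_table$weights
  if (!all) w <- w[w > 0]
  ord <- order(-w, names(w))
  utils::write.csv(
    data.frame(feature = names(w)[ord], weight = unname(w)[ord]),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Candidate feature set at a minimum-weight threshold
#'
#' Exactly the features with accumulated weight at least `w_min`, ordered by
#' weight descending then name ascending. Raising `w_min` can only shrink
#' the set (nesting). An empty set is valid (the sweep skips scoring it).
#'
#' @param weight_table a [accumulate_weights()] result.
#' @param w_min threshold in `[1, w_max]`.
#' @return an object of class `candidate_set`: `w_min`, `features`,
#'   `weights` (the accumulated weights of the retained features).
#' @export
candidate_set <- function(weight_table, w_min) {
  w_min <- as.integer(w_min)
  if (is.na(w_min) || w_min < 1L || w_min > weight_table$w_max) {
    stop("`w_min` must be in [1, w_max]", call. = FALSE)
  }
  w <- weight_table$weights[weight_table$weights >= w_min]
  ord <- order(-w, names(w))
  structure(
    list(w_min = w_min, features = names(w)[ord], weights = unname(w)[ord]),
    class = "candidate_set"
  )
}

#' Rank selectors by standalone cross-validated accuracy
#'
#' The principled route to the rank weights: each candidate selector is run
#' standalone (select on each fold's training samples, fit the ranking
#' classifier on the selected features, score the test fold) and selectors
#' are ordered by mean accuracy. Weights are rank positions: the best of
#' `m` selectors gets weight `m`, the worst 1. Exact accuracy ties break to
#' the smaller mean selected-set size, then to registration order.
#'
#' @param table a [feature_table()].
#' @param plan a [plan_folds()] plan.
#' @param method_ids character vector of selector ids, registration order.
#' @param ranking_classifier a [classifier_spec()] used for scoring.
#' @param mrmr_cfg,lasso_cv_folds,seed selector configuration as in
#'   [collect_fold_selections()].
#' @return list of [method_rank()] in registration order, with an attribute
#'   `standalone` (data frame of mean accuracy and mean set size per method).
#' @export
rank_fs_methods <- function(table, plan, method_ids = c("mrmr", "lasso"),
                            ranking_classifier = classifier_spec("lr"),
                            mrmr_cfg = NULL, lasso_cv_folds = 10L, seed = 0L) {
  if (!length(method_ids)) stop("need at least one method", call. = FALSE)
  if (is.null(mrmr_cfg)) mrmr_cfg <- mrmr_config(k = default_k(n_features(table)))
  stats_df <- do.call(rbind, lapply(seq_along(method_ids), function(i) {
    id <- method_ids[[i]]
    accs <- sizes <- numeric(plan$k_folds)
    for (f in seq_len(plan$k_folds)) {
      a <- plan$assignments[[f]]
      train <- subset_samples(table, a$train)
      feats <- run_selector(id, train, mrmr_cfg, lasso_cv_folds, seed + f)
      sizes[f] <- length(feats)
      if (!length(feats)) { accs[f] <- NA_real_; next }
      out <- fit_predict(ranking_classifier,
                         train$values[, feats, drop = FALSE], train$labels,
                         table$values[a$test, feats, drop = FALSE])
      accs[f] <- mean(out$pred == table$labels[a$test])
    }
    data.frame(method_id = id, registration = i,
               mean_acc = mean(accs, na.rm = TRUE),
               mean_size = mean(sizes), stringsAsFactors = FALSE)
  }))
  ord <- order(-stats_df$mean_acc, stats_df$mean_size, stats_df$registration)
  m <- length(method_ids)
  weight_of <- integer(m)
  weight_of[ord] <- m:1 # best method gets the largest weight
  out <- lapply(seq_len(m), function(i) {
    method_rank(stats_df$method_id[i], weight_of[i])
  })
  attr(out, "standalone") <- stats_df
  out
}
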