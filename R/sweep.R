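#' Sweep every minimum-weight threshold against every classifier
#'
#' Enumerates thresholds from `w_max` down to 1; for each, the candidate
#' feature set is scored with every classifier via [evaluate_cv()] on the
#' supplied fold plan. Candidate sets are nested, so consecutive thresholds
#' often induce the same set; identical sets reuse the already-computed
#' metrics. Empty candidate sets are recorded in the grid with
#' `n_features = 0` and `NA` metrics but are not scored.
#'
#' @param table a [feature_table()].
#' @param weight_table a [accumulate_weights()] result with at least one
#'   positive weight.
#' @param classifiers named list of [classifier_spec()] objects, in
#'   registration order (default [default_classifiers()]).
#' @param plan a [plan_folds()] plan. By default the same plan that produced
#'   the weights is reused, mirroring a single-CV protocol; note the chosen
#'   subset then sees all samples during selection. Pass a fresh plan for a
#'   nested evaluation.
#' @return an object of class `sweep_result`: `grid` (data frame over
#'   (w_min, classifier) with `n_features` and the mean/sd of each metric),
#'   `reports` (the full [evaluate_cv()] reports keyed by
#'   `"<w_min>:<classifier>"`), `sets` (the candidate set per threshold),
#'   `chosen` (see [select_final()]), `w_max`.
#' @export
sweep_min_weights <- function(table, weight_table,
                              classifiers = default_classifiers(),
                              plan) {
  if (!any(weight_table$weights > 0)) {
    stop("weight table is trivial: no feature was ever selected", call. = FALSE)
  }
  cls_ids <- vapply(classifiers, `[[`, character(1), "id")
  w_max <- weight_table$w_max
  grid_rows <- list()
  reports <- list()
  sets <- list()
  seen <- new.env(parent = emptyenv()) # feature-set key -> metrics rows
  for (w in seq(w_max, 1L)) {
    cs <- candidate_set(weight_table, w)
    sets[[as.character(w)]] <- cs
    nf <- length(cs$features)
    if (nf == 0L) {
      for (id in cls_ids) {
        grid_rows[[length(grid_rows) + 1L]] <- data.frame(
          w_min = w, classifier = id, n_features = 0L,
          ACC = NA_real_, ACC_sd = NA_real_, AUC = NA_real_, F1 = NA_real_,
          PRE = NA_real_, REC = NA_real_, SPEC = NA_real_,
          stringsAsFactors = FALSE
        )
      }
      next
    }
    key <- paste(cs$features, collapse = "\r")
    if (is.null(seen[[key]])) {
      cell <- lapply(cls_ids, function(id) {
        evaluate_cv(table, cs$features, classifiers[[id]], plan)
      })
      names(cell) <- cls_ids
      seen[[key]] <- cell
    }
    cell <- seen[[key]]
    for (id in cls_ids) {
      rep_ <- cell[[id]]
      reports[[paste0(w, ":", id)]] <- rep_
      grid_rows[[length(grid_rows) + 1L]] <- data.frame(
        w_min = w, classifier = id, n_features = nf,
        ACC = rep_$mean[["ACC"]], ACC_sd = rep_$sd[["ACC"]],
        AUC = rep_$mean[["AUC"]], F1 = rep_$mean[["F1"]],
        PRE = rep_$mean[["PRE"]], REC = rep_$mean[["REC"]],
        SPEC = rep_$mean[["SPEC"]], stringsAsFactors = FALSE
      )
    }
  }
  grid <- do.call(rbind, grid_rows)
  rownames(grid) <- NULL
  res <- structure(
    list(grid = grid, reports = reports, sets = sets,
         chosen = NULL, w_max = w_max, classifier_order = cls_ids),
    class = "sweep_result"
  )
  res$chosen <- select_final(res)
  res
}

#' Pick the final threshold, classifier and feature set from a sweep grid
#'
#' Lexicographic rule driven by accuracy: maximize mean accuracy; break ties
#' by the smaller feature count, then the larger threshold, then classifier
#' registration order. Deterministic and stable under permutation of grid
#' rows.
#'
#' @param result a [sweep_min_weights()] result (or a compatible list with
#'   `grid`, `sets` and `classifier_order`).
#' @return list `w_min`, `classifier`, `n_features`, `acc`, `features`.
#' @export
select_final <- function(result) {
  grid <- result$grid
  g <- grid[!is.na(grid$ACC) & grid$n_features > 0L, , drop = FALSE]
  if (!nrow(g)) stop("no scored cells in the sweep grid", call. = FALSE)
  cls_rank <- match(g$classifier, result$classifier_order)
  ord <- order(-g$ACC, g$n_features, -g$w_min, cls_rank)
  top <- g[ord[1L], ]
  feats <- result$sets[[as.character(top$w_min)]]$features
  list(
    w_min = top$w_min,
    classifier = top$classifier,
    n_features = top$n_features,
    acc = top$ACC,
    features = feats
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  ch <- x$chosen
  cat(sprintf(
    "<sweep_result> thresholds %d..1, %d classifiers\n  chosen: w_min = %d, %s, %d features, mean ACC = %.4f\n",
    x$w_max, length(x$classifier_order), ch$w_min, ch$classifier,
    ch$n_features, ch$acc
  ))
  invisible(x)
}

#' Statistical fold-change baseline selector
#'
#' The threshold heuristic a panel analyst would try first: for each
#' feature, compute the post/pre abundance ratio within every patient and
#' keep the features whose ratio exceeds `fold_change_threshold` in at least
#' a fraction `min_patient_fraction` of patients. A ratio threshold of 1.5
#' corresponds to selecting features elevated by more than 50% after
#' treatment. Redundant correlated proxies all pass together -- the
#' redundancy-aware selector exists precisely to avoid that.
#'
#' @param table a [feature_table()] with `patient_ids`, exactly one pre
#'   (label 0) and one post (label 1) sample per patient.
#' @param fold_change_threshold ratio threshold, > 1 (default 1.5).
#' @param min_patient_fraction required fraction of patients in (0, 1].
#' @return character vector of selected feature names.
#' @export
heuristic_baseline_select <- function(table, fold_change_threshold = 1.5,
                                      min_patient_fraction) {
  if (is.null(table$patient_ids)) {
    stop("patient pairing requires `patient_ids`", call. = FALSE)
  }
  if (fold_change_threshold <= 1) {
    stop("`fold_change_threshold` must be > 1", call. = FALSE)
  }
  if (min_patient_fraction <= 0 || min_patient_fraction > 1) {
    stop("`min_patient_fraction` must be in (0, 1]", call. = FALSE)
  }
  pats <- unique(table$patient_ids)
  pre_idx <- post_idx <- integer(length(pats))
  bad <- character(0)
  for (i in seq_along(pats)) {
    rows <- which(table$patient_ids == pats[i])
    pre <- rows[table$labels[rows] == 0L]
    post <- rows[table$labels[rows] == 1L]
    if (length(pre) != 1L || length(post) != 1L) {
      bad <- c(bad, pats[i])
    } else {
      pre_idx[i] <- pre
      post_idx[i] <- post
    }
  }
  if (length(bad)) {
    stop("patients without exactly one pre and one post sample: ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  ratio <- table$values[post_idx, , drop = FALSE] /
    table$values[pre_idx, , drop = FALSE]
  frac <- colMeans(ratio > fold_change_threshold)
  table$feature_names[frac >= min_patient_fraction]
}

#' Cross-validated baseline with no feature selection
#'
#' Scores every classifier on the full feature panel with the same fold
#' plan, for comparison against the post-selection grid.
#'
#' @param table a [feature_table()].
#' @param classifiers named list of [classifier_spec()] objects.
#' @param plan a [plan_folds()] plan.
#' @return named list of [evaluate_cv()] reports, one per classifier, with
#'   `n_features` equal to the full panel size.
#' @export
evaluate_no_fs_baseline <- function(table, classifiers = default_classifiers(),
                                    plan) {
  lapply(classifiers, function(spec) {
    evaluate_cv(table, table$feature_names, spec, plan)
  })
}
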