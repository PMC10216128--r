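#' Confusion counts from predictions and labels
#'
#' @param pred predicted 0/1 labels.
#' @param labels true 0/1 labels (1 = positive, post-treatment class).
#' @return list with integer fields `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(pred, labels) {
  pred <- as.integer(pred)
  labels <- as.integer(labels)
  stopifnot(length(pred) == length(labels))
  list(
    TP = sum(pred == 1L & labels == 1L),
    TN = sum(pred == 0L & labels == 0L),
    FP = sum(pred == 1L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L)
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1 from the
#' four confusion counts. A metric whose denominator is zero is undefined
#' and reported as `NA` -- deliberately distinct from 0 -- and later excluded
#' from fold means with a warning.
#'
#' @param counts a list with nonnegative fields `TP`, `TN`, `FP`, `FN`
#'   (see [confusion_counts()]).
#' @return named numeric vector `ACC`, `PRE`, `REC`, `SPEC`, `F1` (`NA`
#'   where undefined).
#' @export
compute_metrics <- function(counts) {
  with(counts, {
    if (any(c(TP, TN, FP, FN) < 0)) {
      stop("confusion counts must be nonnegative", call. = FALSE)
    }
    total <- TP + TN + FP + FN
    if (total == 0) stop("no evaluated samples", call. = FALSE)
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    acc <- (TP + TN) / total
    pre <- ratio(TP, TP + FP)
    rec <- ratio(TP, TP + FN)
    spec <- ratio(TN, TN + FP)
    f1 <- if (is.na(pre) || is.na(rec) || (pre + rec) == 0) {
      NA_real_
    } else {
      2 * pre * rec / (pre + rec)
    }
    c(ACC = acc, PRE = pre, REC = rec, SPEC = spec, F1 = f1)
  })
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney formulation with midranks for tied scores; equal to the
#' trapezoidal area under the empirical ROC curve, and invariant under any
#' strictly increasing transform of the scores.
#'
#' @param scores per-sample real decision scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\], or `NA` if only one class is present.
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated evaluation of a feature subset
#'
#' For each fold of the plan, fits the classifier on the training rows
#' restricted to `features` and scores the test rows; reports per-fold
#' metrics plus their mean and standard deviation across folds. The standard
#' deviation is the population form over the k fold values. Undefined
#' per-fold metrics (zero denominators) are dropped from the mean with a
#' warning.
#'
#' @param table a [feature_table()].
#' @param features character vector of feature names to use (non-empty,
#'   all present in the table).
#' @param classifier a [classifier_spec()].
#' @param plan a [plan_folds()] fold plan.
#' @return an object of class `metrics_report`: `per_fold` (data frame with
#'   one row per fold: ACC, PRE, REC, SPEC, F1, AUC), `mean`, `sd` (named
#'   vectors), `n_features`, `classifier`.
#' @export
evaluate_cv <- function(table, features, classifier, plan) {
  if (length(features) == 0L) {
    stop("`features` must be non-empty", call. = FALSE)
  }
  missing_feats <- setdiff(features, table$feature_names)
  if (length(missing_feats)) {
    stop("features not in table: ", paste(utils::head(missing_feats, 5), collapse = ", "),
         call. = FALSE)
  }
  x <- table$values[, features, drop = FALSE]
  y <- table$labels
  rows <- lapply(seq_along(plan$assignments), function(f) {
    a <- plan$assignments[[f]]
    out <- fit_predict(classifier, x[a$train, , drop = FALSE], y[a$train],
                       x[a$test, , drop = FALSE])
    m <- compute_metrics(confusion_counts(out$pred, y[a$test]))
    c(m, AUC = rank_auc(out$score, y[a$test]))
  })
  per_fold <- as.data.frame(do.call(rbind, rows))
  per_fold$fold <- seq_len(nrow(per_fold))
  metric_cols <- c("ACC", "PRE", "REC", "SPEC", "F1", "AUC")
  if (anyNA(per_fold[metric_cols])) {
    warning("undefined metrics in some folds (zero denominator); excluded from means",
            call. = FALSE)
  }
  mu <- vapply(per_fold[metric_cols], mean, numeric(1), na.rm = TRUE)
  sdv <- vapply(per_fold[metric_cols], pop_sd, numeric(1))
  structure(
    list(per_fold = per_fold, mean = mu, sd = sdv,
         n_features = length(features), classifier = classifier$id),
    class = "metrics_report"
  )
}

# population standard deviation over fold values, NA-dropping
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s on %d features over %d folds\n",
              x$classifier, x$n_features, nrow(x$per_fold)))
  print(round(rbind(mean = x$mean, sd = x$sd), 4))
  invisible(x)
}
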