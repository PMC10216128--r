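#' Run the full rank-weighted hybrid selection pipeline
#'
#' End-to-end orchestration: optional human-protein filter, fold planning,
#' per-fold selector runs, rank-weight accumulation, minimum-weight
#' threshold sweep across the classifier panel, and final subset choice.
#' Deterministic given (table, configuration, seed).
#'
#' @param table a [feature_table()].
#' @param folds cross-validation folds for selection and evaluation
#'   (default 5).
#' @param seed pipeline seed (default 0); drives fold assignment, the LASSO
#'   penalty CV, and the classifiers.
#' @param methods list of [method_rank()] (default mRMR = 2, LASSO = 1);
#'   ignored when `auto_rank_methods = TRUE`.
#' @param auto_rank_methods derive the selector weights from standalone
#'   accuracy via [rank_fs_methods()] instead of using the fixed default.
#' @param mrmr_k number of features the mRMR stage selects per fold;
#'   `NULL` means `default_k(n_features)`.
#' @param mrmr_estimator estimator pair for [mrmr_config()].
#' @param lasso_cv_folds folds for the LASSO penalty CV (default 10).
#' @param classifiers named list of [classifier_spec()]; default all five.
#' @param stratified,group_by_patient fold options, see [plan_folds()].
#' @param filter_human apply [filter_human_features()] first.
#' @param no_fs_baseline also score every classifier on the full panel.
#' @param evaluation_plan optional separate [plan_folds()] plan for the
#'   sweep; by default the selection plan is reused (single-CV protocol).
#' @param verbose log stage progress to stderr.
#' @return an object of class `radwise_result`: `sweep` (a
#'   [sweep_min_weights()] result), `weight_table`, `plan`, `methods`,
#'   `baselines` (when requested), `config` (the resolved configuration).
#' @export
run_radwise <- function(table,
                        folds = 5L,
                        seed = 0L,
                        methods = default_methods(),
                        auto_rank_methods = FALSE,
                        mrmr_k = NULL,
                        mrmr_estimator = c("fstat", "fstat-diff", "mi"),
                        lasso_cv_folds = 10L,
                        classifiers = default_classifiers(),
                        stratified = TRUE,
                        group_by_patient = FALSE,
                        filter_human = FALSE,
                        no_fs_baseline = FALSE,
                        evaluation_plan = NULL,
                        verbose = FALSE) {
  mrmr_estimator <- match.arg(mrmr_estimator)
  log_stage <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  if (filter_human) {
    log_stage("[filter] restricting to human protein features")
    table <- filter_human_features(table)
  }
  k <- if (is.null(mrmr_k)) default_k(n_features(table)) else as.integer(mrmr_k)
  mrmr_cfg <- mrmr_config(k = k, estimator = mrmr_estimator)
  log_stage("[folds] planning %d folds (seed %d)", folds, seed)
  plan <- plan_folds(table, k_folds = folds, stratified = stratified,
                     group_by_patient = group_by_patient, seed = seed)
  if (auto_rank_methods) {
    log_stage("[rank] ranking selectors by standalone accuracy")
    methods <- rank_fs_methods(table, plan, mrmr_cfg = mrmr_cfg,
                               lasso_cv_folds = lasso_cv_folds, seed = seed)
  }
  log_stage("[select] running %d selectors in %d folds", length(methods), folds)
  selections <- collect_fold_selections(table, plan, methods = methods,
                                        mrmr_cfg = mrmr_cfg,
                                        lasso_cv_folds = lasso_cv_folds,
                                        seed = seed)
  weight_table <- accumulate_weights(selections, table$feature_names)
  log_stage("[sweep] %d thresholds x %d classifiers",
            weight_table$w_max, length(classifiers))
  eval_plan <- if (is.null(evaluation_plan)) plan else evaluation_plan
  sweep <- sweep_min_weights(table, weight_table, classifiers, eval_plan)
  baselines <- NULL
  if (no_fs_baseline) {
    log_stage("[baseline] scoring the full %d-feature panel", n_features(table))
    baselines <- list(no_fs = evaluate_no_fs_baseline(table, classifiers, eval_plan))
  }
  config <- list(
    folds = as.integer(folds), seed = as.integer(seed),
    methods = lapply(methods, function(m) list(method_id = m$method_id,
                                               weight = m$weight)),
    mrmr_k = k, mrmr_estimator = mrmr_estimator,
    lasso_cv_folds = as.integer(lasso_cv_folds),
    classifiers = names(classifiers),
    stratified = stratified, group_by_patient = group_by_patient,
    filter_human = filter_human,
    nested_evaluation = !is.null(evaluation_plan)
  )
  log_stage("[done] chosen w_min = %d (%s, %d features) in %.1f s",
            sweep$chosen$w_min, sweep$chosen$classifier,
            sweep$chosen$n_features,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  structure(
    list(sweep = sweep, weight_table = weight_table, plan = plan,
         methods = methods, baselines = baselines, config = config),
    class = "radwise_result"
  )
}

#' @export
print.radwise_result <- function(x, ...) {
  print(x$sweep)
  invisible(x)
}

#' Write the selection report as JSON
#'
#' Serializes the chosen threshold/classifier/feature set, the full
#' (threshold x classifier) metric grid, the accumulated weights of the
#' selected features, and the configuration. Byte-stable given identical
#' inputs, so repeated seeded runs produce byte-identical reports.
#'
#' @param result a [run_radwise()] result (a [sweep_min_weights()] result is
#'   also accepted; it carries no config).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_selection_report <- function(result, path) {
  if (inherits(result, "radwise_result")) {
    sweep <- result$sweep
    config <- result$config
    weights <- result$weight_table$weights
  } else if (inherits(result, "sweep_result")) {
    sweep <- result
    config <- NULL
    weights <- NULL
  } else {
    stop("`result` must be a radwise_result or sweep_result", call. = FALSE)
  }
  ch <- sweep$chosen
  payload <- list(
    chosen = list(
      w_min = ch$w_min,
      classifier = ch$classifier,
      n_features = ch$n_features,
      mean_accuracy = ch$acc,
      selected_features = as.list(ch$features)
    ),
    w_max = sweep$w_max,
    grid = sweep$grid,
    selected_feature_weights = if (!is.null(weights)) {
      as.list(weights[ch$features])
    },
    config = config
  )
  payload <- payload[!vapply(payload, is.null, logical(1))]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read back a selection report
#'
#' @param path a JSON file written by [write_selection_report()].
#' @return the report as a list (grid as a data frame).
#' @export
read_selection_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
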