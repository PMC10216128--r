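#' Assemble and validate a feature table
#'
#' The central container of the package: a numeric samples-by-features
#' abundance matrix with a binary label per sample. Values are expected to be
#' normalized upstream (e.g. SomaScan RFU after assay normalization); the
#' package performs no calibration of its own. Labels code treatment status:
#' `0` = pre-treatment (negative class), `1` = post-treatment (positive
#' class).
#'
#' @param values numeric matrix, `n_samples x n_features`, no missing values.
#' @param labels per-sample class labels; must contain exactly the values
#'   `{0, 1}` with both classes present.
#' @param sample_ids unique sample identifiers (defaults to row names).
#' @param feature_names unique feature identifiers (defaults to column names).
#' @param patient_ids optional per-sample patient identifiers, used for
#'   patient-grouped fold assignment and for the paired fold-change baseline.
#' @param feature_meta optional data frame of per-feature annotation, one row
#'   per feature; a logical column `is_human_protein` enables
#'   [filter_human_features()].
#'
#' @return An object of class `feature_table`: a list with elements `values`,
#'   `labels`, `sample_ids`, `feature_names`, `patient_ids`, `feature_meta`.
#' @export
feature_table <- function(values, labels,
                          sample_ids = rownames(values),
                          feature_names = colnames(values),
                          patient_ids = NULL,
                          feature_meta = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "missing value in `values` at sample %d, feature %d; impute or drop before loading",
      bad[[1L]], bad[[2L]]
    ), call. = FALSE)
  }
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(n))
  if (is.null(feature_names)) feature_names <- paste0("feature_", seq_len(p))
  sample_ids <- as.character(sample_ids)
  feature_names <- as.character(feature_names)
  if (length(sample_ids) != n) {
    stop("length of `sample_ids` must equal nrow(values)", call. = FALSE)
  }
  if (length(feature_names) != p) {
    stop("length of `feature_names` must equal ncol(values)", call. = FALSE)
  }
  if (anyDuplicated(feature_names)) {
    dup <- unique(feature_names[duplicated(feature_names)])
    stop("duplicate feature names: ", paste(utils::head(dup, 5L), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  labels <- validate_labels(labels, n)
  if (!is.null(patient_ids)) {
    patient_ids <- as.character(patient_ids)
    if (length(patient_ids) != n) {
      stop("length of `patient_ids` must equal nrow(values)", call. = FALSE)
    }
  }
  if (!is.null(feature_meta)) {
    feature_meta <- as.data.frame(feature_meta)
    if (nrow(feature_meta) != p) {
      stop("`feature_meta` must have one row per feature", call. = FALSE)
    }
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(
    list(
      values = values,
      labels = labels,
      sample_ids = sample_ids,
      feature_names = feature_names,
      patient_ids = patient_ids,
      feature_meta = feature_meta
    ),
    class = "feature_table"
  )
}

validate_labels <- function(labels, n) {
  labels <- as.integer(labels)
  if (length(labels) != n) {
    stop("length of `labels` must equal the number of samples", call. = FALSE)
  }
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must take exactly the values {0, 1}", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in the labels", call. = FALSE)
  }
  labels
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d samples x %d features (%d pre / %d post)\n",
    nrow(x$values), ncol(x$values), sum(x$labels == 0L), sum(x$labels == 1L)
  ))
  if (!is.null(x$patient_ids)) {
    cat(sprintf("  patients: %d\n", length(unique(x$patient_ids))))
  }
  if (!is.null(x$feature_meta)) {
    cat("  feature_meta:", paste(names(x$feature_meta), collapse = ", "), "\n")
  }
  invisible(x)
}

n_samples <- function(table) nrow(table$values)
n_features <- function(table) ncol(table$values)

#' Subset the samples of a feature table
#'
#' @param table a [feature_table()].
#' @param idx integer sample indices to keep.
#' @return a `feature_table` restricted to the given samples. Label
#'   validation is relaxed (a subset may be single-class); callers that need
#'   both classes check explicitly.
#' @keywords internal
subset_samples <- function(table, idx) {
  out <- table
  out$values <- table$values[idx, , drop = FALSE]
  out$labels <- table$labels[idx]
  out$sample_ids <- table$sample_ids[idx]
  if (!is.null(table$patient_ids)) out$patient_ids <- table$patient_ids[idx]
  out
}

#' Load a feature table from a delimited file
#'
#' Reads a CSV or TSV abundance table and returns a validated
#' [feature_table()]. The canonical layout is rows-are-samples with an id
#' column first, a label column, an optional patient column, and one numeric
#' column per feature. The transposed layout (rows-are-features, columns are
#' samples) is supported through `orientation = "features"`, in which case
#' the label "column" is the row of the table whose id equals `label_column`.
#'
#' @param path file path; delimiter is inferred from the extension (`.csv`
#'   comma, anything else tab) unless `sep` is given.
#' @param label_column name of the label column (or label row when
#'   `orientation = "features"`).
#' @param orientation `"samples"` (default) when rows are samples,
#'   `"features"` when rows are features.
#' @param patient_column optional name of a patient-id column.
#' @param label_map optional named vector mapping label strings to 0/1, e.g.
#'   `c(pre = 0, post = 1)`. Without it, labels must already be numeric 0/1;
#'   string labels are never guessed.
#' @param sep field separator override.
#' @return a [feature_table()].
#' @export
load_feature_table <- function(path, label_column,
                               orientation = c("samples", "features"),
                               patient_column = NULL,
                               label_map = NULL,
                               sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           row.names = 1L, stringsAsFactors = FALSE,
                           comment.char = "")
  if (orientation == "features") {
    raw <- as.data.frame(t(as.matrix(raw)), check.names = FALSE,
                         stringsAsFactors = FALSE)
  }
  if (!label_column %in% names(raw)) {
    stop(sprintf("label column '%s' not found in %s", label_column, path),
         call. = FALSE)
  }
  labels_raw <- raw[[label_column]]
  if (!is.null(label_map)) {
    unknown <- setdiff(unique(as.character(labels_raw)), names(label_map))
    if (length(unknown)) {
      stop("label values not covered by `label_map`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    labels <- unname(label_map[as.character(labels_raw)])
  } else {
    labels <- suppressWarnings(as.numeric(labels_raw))
    if (anyNA(labels)) {
      stop("labels are not numeric 0/1; supply `label_map` to declare the mapping",
           call. = FALSE)
    }
  }
  patient_ids <- NULL
  drop_cols <- label_column
  if (!is.null(patient_column)) {
    if (!patient_column %in% names(raw)) {
      stop(sprintf("patient column '%s' not found", patient_column),
           call. = FALSE)
    }
    patient_ids <- as.character(raw[[patient_column]])
    drop_cols <- c(drop_cols, patient_column)
  }
  feat <- raw[, setdiff(names(raw), drop_cols), drop = FALSE]
  for (j in seq_along(feat)) {
    col <- suppressWarnings(as.numeric(feat[[j]]))
    if (anyNA(col) && !anyNA(feat[[j]])) {
      bad <- which(is.na(col))[1L]
      stop(sprintf("non-numeric value in feature '%s', sample '%s'",
                   names(feat)[j], rownames(raw)[bad]), call. = FALSE)
    }
    feat[[j]] <- col
  }
  feature_table(
    values = as.matrix(feat),
    labels = labels,
    sample_ids = rownames(raw),
    feature_names = names(feat),
    patient_ids = patient_ids
  )
}

#' Keep only features flagged as human proteins
#'
#' Large aptamer panels carry non-human and non-protein control targets;
#' analysis restricts to human protein features before selection. Requires
#' `feature_meta$is_human_protein`.
#'
#' @param table a [feature_table()] with `feature_meta$is_human_protein`.
#' @return the table restricted to flagged features, order preserved.
#' @export
filter_human_features <- function(table) {
  meta <- table$feature_meta
  if (is.null(meta) || is.null(meta$is_human_protein)) {
    stop(paste(
      "feature_meta with an `is_human_protein` flag is required;",
      "either supply the flags or skip the human-protein filter"
    ), call. = FALSE)
  }
  keep <- which(as.logical(meta$is_human_protein))
  if (!length(keep)) {
    stop("no features flagged as human proteins: the filtered panel would be empty",
         call. = FALSE)
  }
  out <- table
  out$values <- table$values[, keep, drop = FALSE]
  out$feature_names <- table$feature_names[keep]
  out$feature_meta <- meta[keep, , drop = FALSE]
  out
}

#' Write a feature table to CSV
#'
#' Inverse of [load_feature_table()] in the rows-are-samples orientation.
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @param label_column,patient_column column names used in the file.
#' @export
write_feature_table <- function(table, path, label_column = "label",
                                patient_column = "patient") {
  df <- data.frame(row.names = table$sample_ids, check.names = FALSE)
  df[[label_column]] <- table$labels
  if (!is.null(table$patient_ids)) df[[patient_column]] <- table$patient_ids
  df <- cbind(df, as.data.frame(table$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = TRUE)
  invisible(path)
}
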