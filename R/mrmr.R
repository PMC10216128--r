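#' Mutual information of a discrete joint distribution
#'
#' Computes `I(X, Y) = sum p(x, y) log(p(x, y) / (p(x) p(y)))` from a matrix
#' of joint counts, with the convention `0 * log(0 / .) = 0`. Symmetric in
#' its two variables and nonnegative.
#'
#' @param joint_counts nonnegative matrix of co-occurrence counts; rows index
#'   levels of one variable, columns levels of the other.
#' @param log_base `"natural"` (nats) or `"2"` (bits).
#' @return nonnegative scalar.
#' @export
mutual_information <- function(joint_counts, log_base = c("natural", "2")) {
  log_base <- match.arg(log_base)
  m <- as.matrix(joint_counts)
  if (any(m < 0)) stop("joint counts must be nonnegative", call. = FALSE)
  total <- sum(m)
  if (total <= 0) stop("joint count matrix is all zero", call. = FALSE)
  p <- m / total
  px <- rowSums(p)
  py <- colSums(p)
  expected <- outer(px, py)
  nz <- p > 0
  val <- sum(p[nz] * log(p[nz] / expected[nz]))
  if (log_base == "2") val <- val / log(2)
  max(val, 0) # clamp tiny negative rounding noise
}

#' Default mRMR panel size
#'
#' The logarithmic heuristic for the number of features the mRMR stage
#' selects per fold: `ceiling(log2(n_features))`, with a floor of 1. For a
#' 7289-feature panel this gives 13.
#'
#' @param n_features number of features in the panel (>= 1).
#' @return positive integer.
#' @export
default_k <- function(n_features) {
  if (length(n_features) != 1L || is.na(n_features) || n_features < 1) {
    stop("`n_features` must be a single integer >= 1", call. = FALSE)
  }
  max(1L, as.integer(ceiling(log2(n_features))))
}

#' mRMR selector configuration
#'
#' Three estimator modes are provided. The default, `"fstat"`, scores
#' relevance with the one-way F statistic of the feature against the binary
#' class and redundancy with the absolute Pearson correlation against
#' already-selected features, combined as the quotient
#' `F(X_i) / mean(|cor(X_i, X_s)|, X_s in S)` -- the standard continuous
#' mRMR criterion (the F statistic and a correlation are on incommensurate
#' scales, so subtracting them would leave the redundancy term inoperative;
#' the quotient keeps it binding). `"fstat-diff"` is the subtractive variant
#' of the same pair, provided for comparison. The `"mi"` mode discretizes
#' each feature into `n_bins` quantile bins and uses discrete mutual
#' information for both terms with the difference form
#' `I(Y, X_i) - mean(I(X_s, X_i))`: both terms share MI units, so the
#' difference is the strict information-theoretic criterion.
#'
#' @param k number of features to select.
#' @param estimator `"fstat"`, `"fstat-diff"` or `"mi"`.
#' @param n_bins quantile bins for the `"mi"` estimator (>= 2).
#' @param log_base logarithm base for the `"mi"` estimator.
#' @return an object of class `mrmr_config`.
#' @export
mrmr_config <- function(k, estimator = c("fstat", "fstat-diff", "mi"), n_bins = 10L,
                        log_base = c("natural", "2")) {
  estimator <- match.arg(estimator)
  log_base <- match.arg(log_base)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  structure(
    list(k = as.integer(k), estimator = estimator,
         n_bins = as.integer(n_bins), log_base = log_base),
    class = "mrmr_config"
  )
}

# One-way F statistic of each column of x against binary y; zero-variance
# columns get relevance 0 so they are never preferred to informative ones.
fstat_relevance <- function(x, y) {
  n <- length(y)
  g1 <- y == 1L
  n1 <- sum(g1)
  n0 <- n - n1
  m1 <- colMeans(x[g1, , drop = FALSE])
  m0 <- colMeans(x[!g1, , drop = FALSE])
  mt <- colMeans(x)
  ss_between <- n1 * (m1 - mt)^2 + n0 * (m0 - mt)^2
  ss_total <- colSums(sweep(x, 2L, mt)^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  f <- (ss_between / 1) / (ss_within / (n - 2))
  f[!is.finite(f) | ss_total <= 0] <- 0
  f
}

# Quantile-bin a numeric vector into at most n_bins codes. Vectors with few
# distinct values are already discrete: keep their levels as-is (quantile
# breaks falling on the values themselves would merge adjacent levels).
quantile_bin <- function(x, n_bins) {
  ux <- sort(unique(x))
  if (length(ux) <= n_bins) return(match(x, ux))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                               names = FALSE, type = 7))
  if (length(br) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

mi_pair <- function(a, b, log_base) {
  mutual_information(table(a, b), log_base = log_base)
}

#' Greedy minimum-redundancy-maximum-relevance ranking
#'
#' Forward selection of `k` features: the first pick maximizes relevance to
#' the class alone (the redundancy term over an empty selected set
#' contributes nothing); each later pick maximizes the configured
#' relevance/redundancy criterion against the features already selected.
#' Ties break to the lowest column index, making the ranking deterministic.
#'
#' @param table a [feature_table()].
#' @param config an [mrmr_config()]; defaults to the F-statistic estimator
#'   with `k = default_k(n_features)`.
#' @return a data frame with columns `feature` (in selection order) and
#'   `score` (the criterion value at the step the feature was picked).
#' @export
mrmr_rank <- function(table, config = NULL) {
  x <- table$values
  y <- validate_labels(table$labels, nrow(x))
  p <- ncol(x)
  if (is.null(config)) config <- mrmr_config(k = default_k(p))
  k <- config$k
  if (k > p) stop("`k` cannot exceed the number of features", call. = FALSE)

  if (config$estimator %in% c("fstat", "fstat-diff")) {
    relevance <- fstat_relevance(x, y)
    # feature-feature redundancy computed lazily, one selected column at a time
    redundancy_against <- function(sel_idx) {
      r <- suppressWarnings(abs(stats::cor(x, x[, sel_idx])))
      r[!is.finite(r)] <- 0
      as.numeric(r)
    }
  } else {
    bins <- apply(x, 2L, quantile_bin, n_bins = config$n_bins)
    relevance <- vapply(
      seq_len(p), function(j) mi_pair(bins[, j], y, config$log_base), numeric(1)
    )
    redundancy_against <- function(sel_idx) {
      vapply(seq_len(p),
             function(j) mi_pair(bins[, j], bins[, sel_idx], config$log_base),
             numeric(1))
    }
  }

  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(p)
  remaining <- rep(TRUE, p)
  quotient <- config$estimator == "fstat"
  for (step in seq_len(k)) {
    crit <- if (length(selected) == 0L) {
      relevance
    } else if (quotient) {
      # floor the mean redundancy so near-zero denominators stay stable
      relevance / pmax(red_sum / length(selected), 1e-4)
    } else {
      relevance - red_sum / length(selected)
    }
    crit[!remaining] <- -Inf
    pick <- which(crit == max(crit))[1L] # lowest index wins ties
    selected <- c(selected, pick)
    scores <- c(scores, crit[pick])
    remaining[pick] <- FALSE
    if (step < k) red_sum <- red_sum + redundancy_against(pick)
  }
  data.frame(
    feature = table$feature_names[selected],
    score = scores,
    stringsAsFactors = FALSE
  )
}
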