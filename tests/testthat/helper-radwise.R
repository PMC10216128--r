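# Shared fixtures and independent oracles for the test suite.
# Oracles are written as direct, loop-based transcriptions of the defining
# formulas so they stay independent of the package's vectorized paths.

# tiny deterministic feature table: 4 samples x 3 features, labels 0,0,1,1
tiny_table <- function() {
  values <- matrix(
    c(1.0, 2.0, 3.0,
      1.5, 1.8, 2.9,
      4.0, 5.0, 6.0,
      4.2, 5.5, 6.1),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("s", 1:4), c("fA", "fB", "fC"))
  )
  feature_table(values, labels = c(0, 0, 1, 1))
}

# random labelled panel with a controllable signal in the first features
random_panel <- function(n = 40, p = 20, signal = 0, n_signal = 2, seed = 1) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  if (n_signal > 0 && signal > 0) {
    x[labels == 1L, seq_len(n_signal)] <- x[labels == 1L, seq_len(n_signal)] + signal
  }
  colnames(x) <- sprintf("f%02d", seq_len(p))
  feature_table(x, labels = labels)
}

# direct cell-by-cell transcription of the mutual information sum
mi_oracle <- function(m, base = exp(1)) {
  total <- sum(m)
  px <- rowSums(m) / total
  py <- colSums(m) / total
  acc <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] > 0) {
        pxy <- m[i, j] / total
        acc <- acc + pxy * log(pxy / (px[i] * py[j]), base = base)
      }
    }
  }
  acc
}

# brute-force AUC: fraction of positive-negative pairs ranked correctly,
# ties counted half
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  acc <- 0
  for (a in pos) {
    for (b in neg) {
      acc <- acc + (a > b) + 0.5 * (a == b)
    }
  }
  acc / (length(pos) * length(neg))
}

# step-wise exhaustive greedy mRMR on discrete columns, difference form with
# discrete MI for both terms; ties to the lowest column index
mrmr_oracle <- function(x, y, k) {
  p <- ncol(x)
  mi <- function(a, b) mi_oracle(as.matrix(table(a, b)))
  rel <- vapply(seq_len(p), function(j) mi(x[, j], y), numeric(1))
  selected <- integer(0)
  for (step in seq_len(k)) {
    remaining <- setdiff(seq_len(p), selected)
    crit <- vapply(remaining, function(j) {
      if (!length(selected)) return(rel[j])
      red <- mean(vapply(selected, function(s) mi(x[, s], x[, j]), numeric(1)))
      rel[j] - red
    }, numeric(1))
    selected <- c(selected, remaining[which.max(crit)])
  }
  selected
}

# centered orthonormal design scaled so glmnet's internal standardization is
# the identity: colMeans 0, colSums(x^2) = n, t(x) %*% x = n * I
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * (p + 2)), n))))[, 2:(p + 1)]
  x <- q * sqrt(n)
  colnames(x) <- paste0("f", seq_len(p))
  x
}

# a weight_table built directly from a named integer weight vector
make_weight_table <- function(weights, w_max) {
  structure(list(weights = weights, w_max = as.integer(w_max),
                 provenance = NULL),
            class = "weight_table")
}

# fold_selections built directly from a list of records
make_selections <- function(records, k_folds, methods) {
  structure(records, class = "fold_selections",
            k_folds = k_folds, methods = methods)
}
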