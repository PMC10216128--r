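#' Classifier specification
#'
#' The five classifiers used to score candidate feature subsets, with fixed
#' default hyperparameters and a fixed seed so repeated runs are identical:
#' \describe{
#'   \item{svm}{RBF-kernel support vector machine, cost 1, gamma `1/p` on
#'     standardized inputs; AUC from the decision margin.}
#'   \item{lr}{L2-penalized logistic regression with unit inverse
#'     regularization strength (ridge penalty `1/n` on the \pkg{glmnet}
#'     scale); AUC from the predicted probability.}
#'   \item{knn}{5 nearest neighbors, Euclidean (Minkowski p = 2) distance,
#'     uniform vote weights.}
#'   \item{rf}{random forest, 100 trees, Gini impurity, unlimited depth.}
#'   \item{adaboost}{real (probability-based) adaptive boosting of 50
#'     depth-1 decision stumps, learning rate 1.}
#' }
#' Inputs to `svm` and `lr` are standardized per fold (train statistics
#' applied to test); tree, boosting and neighbor models consume raw values.
#'
#' @param id one of `"svm"`, `"lr"`, `"knn"`, `"rf"`, `"adaboost"`.
#' @param seed integer seed applied before every stochastic fit (default 0).
#' @param standardize standardize features within each fold before fitting;
#'   defaults to `TRUE` for `svm` and `lr`.
#' @param params named list of hyperparameter overrides.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(id = c("svm", "lr", "knn", "rf", "adaboost"),
                            seed = 0L,
                            standardize = id %in% c("svm", "lr"),
                            params = list()) {
  id <- match.arg(id)
  defaults <- switch(id,
    svm = list(cost = 1),
    lr = list(C = 1, tol = 1e-4),
    knn = list(k = 5L),
    rf = list(ntree = 100L),
    adaboost = list(n_stages = 50L, learning_rate = 1)
  )
  defaults[names(params)] <- params
  structure(
    list(id = id, seed = as.integer(seed), standardize = isTRUE(standardize),
         params = defaults),
    class = "classifier_spec"
  )
}

#' The default classifier panel
#'
#' @param seed seed shared by all five specs.
#' @return named list of [classifier_spec()] objects in registration order
#'   (svm, lr, knn, rf, adaboost).
#' @export
default_classifiers <- function(seed = 0L) {
  ids <- c("svm", "lr", "knn", "rf", "adaboost")
  stats::setNames(lapply(ids, classifier_spec, seed = seed), ids)
}

# Fit on (x_train, y_train), score x_test. Returns list(pred = 0/1 integer,
# score = continuous, higher = more positive-class).
fit_predict <- function(spec, x_train, y_train, x_test) {
  if (spec$standardize) {
    mu <- colMeans(x_train)
    sdv <- apply(x_train, 2L, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    x_train <- sweep(sweep(x_train, 2L, mu), 2L, sdv, "/")
    x_test <- sweep(sweep(x_test, 2L, mu), 2L, sdv, "/")
  }
  set.seed(spec$seed)
  switch(spec$id,
    svm = predict_svm(spec, x_train, y_train, x_test),
    lr = predict_lr(spec, x_train, y_train, x_test),
    knn = predict_knn(spec, x_train, y_train, x_test),
    rf = predict_rf(spec, x_train, y_train, x_test),
    adaboost = predict_adaboost(spec, x_train, y_train, x_test)
  )
}

predict_svm <- function(spec, x_train, y_train, x_test) {
  yf <- factor(y_train, levels = c(0, 1))
  fit <- e1071::svm(x_train, yf, kernel = "radial", cost = spec$params$cost,
                    scale = FALSE)
  pr <- stats::predict(fit, x_test, decision.values = TRUE)
  dv <- as.numeric(attr(pr, "decision.values"))
  # e1071 orients the margin toward the first class seen in training
  dv_name <- colnames(attr(pr, "decision.values"))[1L]
  if (identical(dv_name, "0/1")) dv <- -dv
  list(pred = as.integer(as.character(pr)), score = dv)
}

predict_lr <- function(spec, x_train, y_train, x_test) {
  # ridge-penalized logistic fit; lambda = 1/(n*C) matches a unit inverse
  # regularization strength on the mean-log-likelihood scale
  if (ncol(x_train) < 2L) { # glmnet requires >= 2 columns; pad with a constant
    x_train <- cbind(x_train, 0)
    x_test <- cbind(x_test, 0)
  }
  lam <- 1 / (nrow(x_train) * spec$params$C)
  fit <- glmnet::glmnet(x_train, factor(y_train, levels = c(0, 1)),
                        family = "binomial", alpha = 0,
                        lambda = c(lam * 10, lam), thresh = spec$params$tol * 1e-3,
                        standardize = FALSE)
  prob <- as.numeric(stats::predict(fit, x_test, s = lam, type = "response"))
  list(pred = as.integer(prob > 0.5), score = prob)
}

predict_knn <- function(spec, x_train, y_train, x_test) {
  pr <- class::knn(x_train, x_test, factor(y_train, levels = c(0, 1)),
                   k = spec$params$k, prob = TRUE)
  win <- attr(pr, "prob")
  prob1 <- ifelse(pr == "1", win, 1 - win)
  list(pred = as.integer(as.character(pr)), score = prob1)
}

predict_rf <- function(spec, x_train, y_train, x_test) {
  fit <- randomForest::randomForest(x_train, factor(y_train, levels = c(0, 1)),
                                    ntree = spec$params$ntree)
  prob <- stats::predict(fit, x_test, type = "prob")[, "1"]
  list(pred = as.integer(prob > 0.5), score = as.numeric(prob))
}

# Real AdaBoost (probability-based boosting, the binary case of SAMME.R)
# over depth-1 rpart stumps.
predict_adaboost <- function(spec, x_train, y_train, x_test) {
  n <- nrow(x_train)
  w <- rep(1 / n, n)
  ysgn <- ifelse(y_train == 1L, 1, -1)
  df_train <- as.data.frame(x_train)
  names(df_train) <- paste0("V", seq_len(ncol(x_train)))
  df_test <- as.data.frame(x_test)
  names(df_test) <- names(df_train)
  df_train$.y <- factor(y_train, levels = c(0, 1))
  eps <- 1e-8
  f_test <- numeric(nrow(x_test))
  f_train <- numeric(n)
  ctrl <- rpart::rpart.control(maxdepth = 1, minsplit = 2, minbucket = 1,
                               cp = 0, xval = 0, maxcompete = 0,
                               maxsurrogate = 0, usesurrogate = 0)
  for (m in seq_len(spec$params$n_stages)) {
    stump <- rpart::rpart(.y ~ ., data = df_train, weights = w,
                          method = "class", control = ctrl)
    if (nrow(stump$frame) < 2L) break # no split found: nothing left to learn
    p1_tr <- pmin(pmax(stats::predict(stump, df_train)[, "1"], eps), 1 - eps)
    p1_te <- pmin(pmax(stats::predict(stump, df_test)[, "1"], eps), 1 - eps)
    h_tr <- 0.5 * spec$params$learning_rate * log(p1_tr / (1 - p1_tr))
    h_te <- 0.5 * spec$params$learning_rate * log(p1_te / (1 - p1_te))
    f_train <- f_train + h_tr
    f_test <- f_test + h_te
    w <- w * exp(-ysgn * h_tr)
    s <- sum(w)
    if (!is.finite(s) || s <= 0) break
    w <- w / s
  }
  list(pred = as.integer(f_test > 0), score = f_test)
}
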