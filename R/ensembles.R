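#' Train a tree-ensemble classifier
#'
#' Uniform interface over the three ensembles used for risk
#' classification: random forests (`"RF"`, via randomForest), AdaBoost
#' (`"ADA-B"`, SAMME boosting of depth-2 rpart trees implemented here),
#' and gradient boosting (`"GB"`, via xgboost, binary logistic
#' objective). All run single-threaded and are deterministic under a
#' fixed RNG state.
#'
#' @param X Numeric feature matrix with column names.
#' @param y Logical labels.
#' @param algorithm `"RF"`, `"ADA-B"`, or `"GB"`.
#' @param n_trees Number of trees / boosting rounds (default 100).
#' @param seed Optional integer seed.
#' @return An object of class `ntra_ensemble`.
#' @export
train_ensemble <- function(X, y, algorithm = c("RF", "ADA-B", "GB"),
                           n_trees = 100L, seed = NULL) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  y <- as.logical(y)
  stopifnot(nrow(X) == length(y), !is.null(colnames(X)))
  if (!is.null(seed)) set.seed(seed)
  model <- switch(algorithm,
    "RF" = randomForest::randomForest(
      x = X, y = factor(y, levels = c(FALSE, TRUE)), ntree = n_trees),
    "GB" = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3L,
                    eta = 0.1, nthread = 1L),
      data = xgboost::xgb.DMatrix(X, label = as.numeric(y), nthread = 1L),
      nrounds = n_trees, verbose = 0),
    "ADA-B" = adaboost_fit(X, y, n_rounds = n_trees))
  structure(list(algorithm = algorithm, model = model,
                 features = colnames(X)), class = "ntra_ensemble")
}

#' Predict positive-class scores from a trained ensemble
#'
#' RF returns the fraction of tree votes for the positive class, GB the
#' logistic predicted probability, AdaBoost the weight-normalized vote
#' share; all lie in `[0, 1]` and threshold naturally at 0.5.
#'
#' @param object A [train_ensemble] model.
#' @param X Feature matrix with the training columns.
#' @return Numeric scores in `[0, 1]`.
#' @export
predict_scores <- function(object, X) {
  stopifnot(inherits(object, "ntra_ensemble"))
  X <- as.matrix(X)[, object$features, drop = FALSE]
  switch(object$algorithm,
    "RF" = unname(predict(object$model, X, type = "prob")[, "TRUE"]),
    "GB" = unname(predict(object$model,
                          xgboost::xgb.DMatrix(X, nthread = 1L))),
    "ADA-B" = adaboost_predict(object$model, X))
}

#' Per-feature importances of a trained ensemble
#'
#' Normalized to sum to 1. RF uses mean decrease in Gini impurity, GB
#' the split gain, AdaBoost the boosting-weight-weighted rpart variable
#' importance. Features never used by the model get importance 0.
#'
#' @param object A [train_ensemble] model.
#' @return Named numeric vector over the training features, summing to 1.
#' @export
feature_importances <- function(object) {
  stopifnot(inherits(object, "ntra_ensemble"))
  imp <- setNames(numeric(length(object$features)), object$features)
  raw <- switch(object$algorithm,
    "RF" = {
      gi <- randomForest::importance(object$model)[, "MeanDecreaseGini"]
      gi
    },
    "GB" = {
      tab <- xgboost::xgb.importance(model = object$model)
      setNames(tab$Gain, tab$Feature)
    },
    "ADA-B" = object$model$importance)
  raw <- raw[names(raw) %in% names(imp)]
  imp[names(raw)] <- raw
  if (sum(imp) <= 0)
    stop("ensemble reports no positive feature importance", call. = FALSE)
  imp / sum(imp)
}

# ---- AdaBoost (SAMME, two-class) on shallow rpart trees --------------

adaboost_fit <- function(X, y, n_rounds = 100L, maxdepth = 2L) {
  n <- nrow(X)
  dat <- data.frame(X)
  dat$.y <- factor(y, levels = c(FALSE, TRUE))
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  importance <- setNames(numeric(ncol(X)), colnames(X))
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = 0, xval = 0,
                               minsplit = 5L, minbucket = 2L)
  for (t in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                        control = ctrl)
    pred <- predict(fit, dat, type = "class")
    miss <- pred != dat$.y
    err <- sum(w[miss])
    if (err >= 0.5) break          # weak learner no better than chance
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    learners[[length(learners) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    vi <- fit$variable.importance
    if (!is.null(vi)) {
      vi <- vi[names(vi) %in% names(importance)]
      importance[names(vi)] <- importance[names(vi)] + alpha * vi
    }
    if (err <= 1e-10) break        # perfect learner: nothing left to boost
    w <- w * exp(alpha * (2 * as.numeric(miss) - 1))
    w <- w / sum(w)
  }
  if (!length(learners))
    stop("AdaBoost found no weak learner better than chance", call. = FALSE)
  list(learners = learners, alphas = alphas, importance = importance)
}

adaboost_predict <- function(model, X) {
  dat <- data.frame(X)
  votes <- vapply(model$learners, function(fit)
    as.numeric(predict(fit, dat, type = "class") == "TRUE"), numeric(nrow(dat)))
  votes <- matrix(votes, nrow = nrow(dat))
  drop(votes %*% model$alphas) / sum(model$alphas)
}
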