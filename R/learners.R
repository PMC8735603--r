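#' Learner families for bivariate models
#'
#' An ESM fits every bivariate predictor combination with each learner
#' family and averages them by skill. Two families are provided:
#'
#' * `maxent_learner()`: a maximum-entropy-style presence-background
#'   classifier implemented as an L1-penalized logistic regression
#'   (`glmnet`) on an expanded feature set of the two predictors — linear,
#'   quadratic, and pairwise-product terms. The penalty is selected on a
#'   held-out-fold deviance path (`cv.glmnet`, `lambda.min`) unless a fixed
#'   `regularization` (lambda) is supplied. Case weights are honoured.
#' * `rf_learner()`: a probability random forest (`ranger`), i.e. bagged
#'   decision trees whose prediction is the mean presence frequency across
#'   trees. Case weights are honoured; `n_trees` defaults to 500.
#' * `constant_learner()`: predicts a fixed probability everywhere; used for
#'   exactness tests of the ensemble averaging arithmetic.
#'
#' @param regularization optional fixed non-negative lambda; `NULL` (default)
#'   selects lambda by 5-fold held-out deviance.
#' @param n_trees number of trees for the random forest (default 500).
#' @param p fixed probability for `constant_learner()`.
#' @return A learner description object (class `esm_learner`).
#' @name learners
NULL

#' @rdname learners
#' @export
maxent_learner <- function(regularization = NULL) {
  if (!is.null(regularization) && regularization < 0)
    stop("`regularization` must be >= 0", call. = FALSE)
  structure(list(regularization = regularization),
            class = c("maxent_learner", "esm_learner"))
}

#' @rdname learners
#' @export
rf_learner <- function(n_trees = 500) {
  if (n_trees < 1) stop("`n_trees` must be >= 1", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees)),
            class = c("rf_learner", "esm_learner"))
}

#' @rdname learners
#' @export
constant_learner <- function(p = 0.5) {
  stopifnot(p >= 0, p <= 1)
  structure(list(p = p), class = c("constant_learner", "esm_learner"))
}

#' Fit a learner on a feature matrix
#'
#' @param learner an `esm_learner` description.
#' @param X numeric matrix of predictor values (two columns for a bivariate
#'   model).
#' @param y 0/1 labels (1 = presence).
#' @param weights per-row case weights.
#' @param seed integer seed making the fit deterministic.
#' @return A fitted learner; see [predict_prob()].
#' @export
fit_learner <- function(learner, X, y, weights, seed = 1L) {
  if (length(unique(y)) < 2)
    stop("training labels are single-class", call. = FALSE)
  if (!all(is.finite(X)))
    stop("non-finite feature values", call. = FALSE)
  UseMethod("fit_learner")
}

#' Predict presence probability from a fitted learner
#'
#' @param fit a fitted learner from [fit_learner()].
#' @param X numeric matrix with the same columns the learner was fitted on.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(fit, X) UseMethod("predict_prob")

expand_features <- function(X) {
  stopifnot(ncol(X) == 2)
  cbind(z1 = X[, 1], z2 = X[, 2],
        z1_sq = X[, 1]^2, z2_sq = X[, 2]^2,
        z1_z2 = X[, 1] * X[, 2])
}

#' @export
fit_learner.maxent_learner <- function(learner, X, y, weights, seed = 1L) {
  F <- expand_features(as.matrix(X))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  # glmnet warns when a class has < 8 rows; routine here, since rare-species
  # training data carry as few as 5 presences
  if (is.null(learner$regularization)) {
    foldid <- sample(rep(seq_len(5), length.out = nrow(F)))
    cvfit <- suppressWarnings(
      glmnet::cv.glmnet(F, y, family = "binomial", weights = weights,
                        alpha = 1, foldid = foldid))
    lambda <- cvfit$lambda.min
    fit <- cvfit$glmnet.fit
  } else {
    lambda <- learner$regularization
    fit <- suppressWarnings(
      glmnet::glmnet(F, y, family = "binomial", weights = weights,
                     alpha = 1, lambda = lambda))
  }
  structure(list(fit = fit, lambda = lambda, vars = colnames(X)),
            class = "fitted_maxent")
}

#' @export
predict_prob.fitted_maxent <- function(fit, X) {
  F <- expand_features(as.matrix(X))
  as.vector(stats::predict(fit$fit, newx = F, s = fit$lambda,
                           type = "response"))
}

#' @export
fit_learner.rf_learner <- function(learner, X, y, weights, seed = 1L) {
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = c(0, 1))
  rf <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    probability = TRUE, num.trees = learner$n_trees,
    case.weights = weights, seed = as.integer(seed), num.threads = 1
  )
  structure(list(fit = rf, vars = colnames(X)), class = "fitted_rf")
}

#' @export
predict_prob.fitted_rf <- function(fit, X) {
  p <- stats::predict(fit$fit, data = as.data.frame(X),
                      num.threads = 1)$predictions
  as.vector(p[, "1"])
}

#' @export
fit_learner.constant_learner <- function(learner, X, y, weights, seed = 1L) {
  structure(list(p = learner$p, vars = colnames(X)), class = "fitted_constant")
}

#' @export
predict_prob.fitted_constant <- function(fit, X) {
  rep(fit$p, nrow(as.matrix(X)))
}
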