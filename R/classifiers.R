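#' Class-probability predictions from a fitted base classifier
#'
#' @param object a fitted classifier from [fit_logistic()], [fit_svm_rbf()]
#'   or [fit_random_forest()].
#' @param X query feature matrix.
#' @return `n x 2` matrix of class probabilities (columns: class 0, class 1).
#' @export
predict_proba <- function(object, X) UseMethod("predict_proba")

#' Logistic regression base classifier
#'
#' Ridge-penalized logistic regression with penalty `lambda = 1/n`, the
#' glmnet equivalent of the default L2-regularized formulation (C = 1) most
#' off-the-shelf implementations use; the light penalty also keeps the fit
#' well-defined on separable embeddings.
#'
#' @param X numeric feature matrix.
#' @param y 0/1 labels.
#' @return object of class `cfg_logistic`.
#' @export
fit_logistic <- function(X, y) {
  X <- as_numeric_matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("single-class training data")
  fit <- glmnet::glmnet(X, factor(y, levels = c(0L, 1L)), family = "binomial",
                        alpha = 0, lambda = 1 / nrow(X), standardize = FALSE)
  structure(list(fit = fit), class = "cfg_logistic")
}

#' @export
predict_proba.cfg_logistic <- function(object, X) {
  p1 <- as.numeric(predict(object$fit, as_numeric_matrix(X), type = "response"))
  cbind(1 - p1, p1)
}

#' RBF-kernel support vector machine base classifier
#'
#' Soft-margin SVM solved exactly on the dual quadratic program (via
#' quadprog), with the usual defaults `C = 1` and
#' `gamma = 1 / (p * var(X))`. Class probabilities come from Platt scaling:
#' a logistic sigmoid fitted to the decision values of the training data.
#'
#' @param X numeric feature matrix.
#' @param y 0/1 labels.
#' @param C box constraint.
#' @param gamma RBF width; `NULL` for the `1 / (p * var(X))` default.
#' @return object of class `cfg_svm`.
#' @export
fit_svm_rbf <- function(X, y, C = 1, gamma = NULL) {
  X <- as_numeric_matrix(X)
  y01 <- as.integer(y)
  if (length(unique(y01)) < 2L) stop("single-class training data")
  ypm <- ifelse(y01 == 1L, 1, -1)
  n <- nrow(X)
  if (is.null(gamma)) {
    v <- stats::var(as.vector(X))
    gamma <- if (v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
  }
  K <- rbf_kernel(X, X, gamma)
  Dmat <- (ypm %o% ypm) * K + diag(1e-8, n)
  Amat <- cbind(ypm, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat, rep(1, n), Amat, bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  sv <- which(alpha > 1e-8)
  coefs <- alpha[sv] * ypm[sv]
  # bias from margin support vectors (fallback: all SVs)
  margin <- sv[alpha[sv] < C - 1e-6]
  if (!length(margin)) margin <- sv
  f_nob <- K[, sv, drop = FALSE] %*% coefs
  b <- mean(ypm[margin] - f_nob[margin])
  f_train <- as.numeric(f_nob + b)
  # Platt scaling on training decision values
  platt <- suppressWarnings(
    stats::glm(y01 ~ f_train, family = stats::binomial())
  )
  structure(
    list(X_sv = X[sv, , drop = FALSE], coefs = coefs, b = b, gamma = gamma,
         platt = stats::coef(platt)),
    class = "cfg_svm"
  )
}

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' @export
predict_proba.cfg_svm <- function(object, X) {
  X <- as_numeric_matrix(X)
  f <- as.numeric(
    rbf_kernel(X, object$X_sv, object$gamma) %*% object$coefs + object$b
  )
  p1 <- plogis(object$platt[1] + object$platt[2] * f)
  cbind(1 - p1, p1)
}

#' Random forest base classifier
#'
#' Gini CART forest grown in compiled code: bootstrap resamples,
#' `floor(sqrt(p))` features tried per split, unbounded depth,
#' `min_samples_split = 2`. The tuned tree count for this problem is 70.
#' Probabilities are the per-tree leaf class fractions averaged over trees.
#' Deterministic given `seed`.
#'
#' @param X numeric feature matrix.
#' @param y 0/1 labels.
#' @param ntree number of trees (default 70).
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param seed integer seed for bootstraps and feature subsampling.
#' @param max_depth recursion cap (effectively unbounded by default).
#' @return object of class `cfg_forest`.
#' @export
fit_random_forest <- function(X, y, ntree = 70L, mtry = NULL, seed = 1L,
                              max_depth = 50L) {
  X <- as_numeric_matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("single-class training data")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- rf_fit_cpp(X, y, as.integer(ntree), as.integer(mtry), 2L,
                      as.integer(max_depth), as.integer(seed))
  structure(list(trees = trees, ntree = ntree), class = "cfg_forest")
}

#' @export
predict_proba.cfg_forest <- function(object, X) {
  p1 <- rf_predict_cpp(object$trees, as_numeric_matrix(X))
  cbind(1 - p1, p1)
}
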