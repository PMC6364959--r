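# Bespoke elastic net trained by coordinate descent (src/elnet.cpp).

#' Fit the elastic-net regression by coordinate descent
#'
#' Minimises `sum((y - b0 - X beta)^2) + alpha*lambda*||beta||_2^2 +
#' (lambda*(1-alpha)/2)*||beta||_1` exactly as the model is specified: the
#' mixing weight `alpha` multiplies the ridge term and `(1-alpha)/2` the
#' lasso term (mapping to the common glmnet convention is documented in the
#' methods vignette). The intercept is unpenalised. Callers are expected to
#' pass features standardized with training-fold statistics.
#'
#' @param X Numeric matrix (n x p), no missing entries.
#' @param y Numeric response vector: the continuous change in pain.
#' @param alpha Mixing weight in \[0, 1\].
#' @param lambda Overall penalty strength >= 0.
#' @param tol Convergence tolerance on the largest coordinate update
#'   (default 1e-7).
#' @param max_iter Iteration cap; non-convergence is an error.
#' @param beta_init Optional warm start.
#' @return Object of class `elnet_fit`: coefficients (named when X has
#'   column names), intercept, hyperparameters, iterations.
#' @export
fit_elasticnet <- function(X, y, alpha = 0.3, lambda = 0.05, tol = 1e-7,
                           max_iter = 100000L, beta_init = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X) || !all(is.finite(X))) {
    stop("X must be a finite numeric matrix (impute before fitting)")
  }
  if (!all(is.finite(y))) stop("y must be finite")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (lambda < 0) stop("lambda must be >= 0")
  if (is.null(beta_init)) beta_init <- numeric(ncol(X))
  res <- .elnet_cd(X, y, alpha, lambda, beta_init, mean(y), tol,
                   as.integer(max_iter))
  if (!res$converged) {
    stop("coordinate descent did not converge after ", res$iterations,
         " iterations (tol = ", tol, ")")
  }
  beta <- as.numeric(res$beta)
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, intercept = res$b0, alpha = alpha,
                 lambda = lambda, iterations = res$iterations),
            class = "elnet_fit")
}

#' @export
predict.elnet_fit <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$coefficients) + object$intercept
}

#' @export
print.elnet_fit <- function(x, ...) {
  cat(sprintf("<elnet_fit> alpha=%g lambda=%g, %d/%d non-zero, %d iterations\n",
              x$alpha, x$lambda, sum(x$coefficients != 0),
              length(x$coefficients), x$iterations))
  invisible(x)
}

#' Elastic-net objective value
#'
#' The exact quantity [fit_elasticnet()] minimises; exposed so that
#' independent optimisers can be compared on objective value.
#'
#' @inheritParams fit_elasticnet
#' @param beta Coefficient vector.
#' @param b0 Intercept.
#' @return Scalar objective value.
#' @export
elnet_objective <- function(X, y, beta, b0, alpha, lambda) {
  .elnet_objective_cpp(as.matrix(X), y, as.numeric(beta), b0, alpha, lambda)
}

#' Binary worsened/improved labels from the continuous pain change
#'
#' Positive class (worsened) is `delta > 0`; zero change counts as not
#' worsened.
#'
#' @param delta Numeric vector of pain changes.
#' @return Integer 0/1 vector (NA propagates).
#' @export
binarize_response <- function(delta) {
  as.integer(delta > 0)
}
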