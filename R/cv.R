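# Nested cross-validation for the elastic net: outer folds estimate
# generalization (fold-wise ROC/AUC), inner folds on each outer-train set
# select (alpha, lambda). All preprocessing (imputation, standardization)
# is refit inside each training set -- never on data used for scoring.

#' Stratified k-fold assignments
#'
#' Shuffles indices within each class and deals them round-robin so every
#' fold has a near-equal class mix. Deterministic given the seed.
#'
#' @param labels 0/1 or logical class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k.
#' @export
make_stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Default hyperparameter grid
#'
#' alpha over 0, 0.1, ..., 1 and lambda over {0.001, 0.005, 0.01, 0.05,
#' 0.1, 0.5}; the published selected values (0.3, 0.05) lie inside it.
#'
#' @return data.frame with columns alpha, lambda.
#' @export
default_hyper_grid <- function() {
  expand.grid(alpha = seq(0, 1, by = 0.1),
              lambda = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5))
}

#' Nested cross-validated elastic net
#'
#' Outer `k_outer`-fold CV stratified by the binary worsened label; within
#' each outer training set an inner `k_inner`-fold grid search picks the
#' (alpha, lambda) maximising inner mean AUC (ties go to the first grid
#' row). The winning model is refit on the full outer-train and its
#' continuous predicted change scores the held-out fold against the binary
#' label. The mean ROC is computed by vertical averaging over a fixed
#' 101-point false-positive-rate grid.
#'
#' @param X Raw feature matrix (may contain NA; imputed per fold).
#' @param delta Continuous response (change in pain).
#' @param grid Hyperparameter data.frame (alpha, lambda).
#' @param k_outer,k_inner Fold counts.
#' @param seed Integer seed controlling fold assignment.
#' @param time_point Optional label carried through to reports.
#' @param tol,max_iter Passed to [fit_elasticnet()].
#' @return Object of class `cv_result`: per-fold AUCs, mean and SD, chosen
#'   hyperparameters per fold, per-fold and vertically averaged ROC
#'   curves, per-fold and averaged coefficient vectors (on the
#'   standardized scale), and the outer fold assignment.
#' @export
nested_cv <- function(X, delta, grid = default_hyper_grid(), k_outer = 10L,
                      k_inner = 5L, seed = 1L, time_point = NA_character_,
                      tol = 1e-7, max_iter = 100000L) {
  X <- as.matrix(X)
  keep <- !is.na(delta)
  X <- X[keep, , drop = FALSE]
  delta <- delta[keep]
  n <- nrow(X)
  if (n < k_outer) stop("need at least k_outer observations, got ", n)
  labels <- binarize_response(delta)
  fold <- make_stratified_folds(labels, k_outer, seed)

  fpr_grid <- seq(0, 1, length.out = 101L)
  fold_auc <- rep(NA_real_, k_outer)
  fold_roc <- vector("list", k_outer)
  fold_coef <- vector("list", k_outer)
  fold_hyper <- data.frame(fold = seq_len(k_outer), alpha = NA_real_,
                           lambda = NA_real_)

  for (f in seq_len(k_outer)) {
    test <- fold == f
    if (length(unique(labels[test])) < 2L) {
      warning("outer fold ", f, " has a single class; skipped")
      next
    }
    Xtr_raw <- X[!test, , drop = FALSE]
    ytr <- delta[!test]
    ltr <- labels[!test]

    # inner grid search on the outer-train only
    inner_fold <- make_stratified_folds(ltr, k_inner,
                                        child_seed(seed, 100L + f))
    score <- matrix(NA_real_, nrow(grid), k_inner)
    for (g in seq_len(k_inner)) {
      ival <- inner_fold == g
      if (length(unique(ltr[ival])) < 2L) next
      prep <- impute_standardize(Xtr_raw[!ival, , drop = FALSE],
                                 Xtr_raw[ival, , drop = FALSE])
      for (h in seq_len(nrow(grid))) {
        fit <- fit_elasticnet(prep$train, ytr[!ival], grid$alpha[h],
                              grid$lambda[h], tol = tol,
                              max_iter = max_iter)
        pr <- predict(fit, prep$test)
        score[h, g] <- suppressWarnings(compute_auc(pr, ltr[ival])$auc)
      }
    }
    mean_score <- rowMeans(score, na.rm = TRUE)
    best <- which.max(mean_score) # ties: first grid row
    fold_hyper$alpha[f] <- grid$alpha[best]
    fold_hyper$lambda[f] <- grid$lambda[best]

    prep <- impute_standardize(Xtr_raw, X[test, , drop = FALSE])
    fit <- fit_elasticnet(prep$train, ytr, grid$alpha[best],
                          grid$lambda[best], tol = tol, max_iter = max_iter)
    pr <- predict(fit, prep$test)
    res <- compute_auc(pr, labels[test])
    fold_auc[f] <- res$auc
    fold_roc[[f]] <- res$roc
    fold_coef[[f]] <- fit$coefficients
  }

  ok <- !is.na(fold_auc)
  if (!any(ok)) stop("all outer folds degenerate; cannot cross-validate")
  tpr_mat <- vapply(fold_roc[ok], interp_roc, numeric(length(fpr_grid)),
                    fpr_grid = fpr_grid)
  coef_mat <- do.call(cbind, fold_coef[ok])
  structure(list(
    time_point = time_point,
    fold_auc = fold_auc,
    mean_auc = mean(fold_auc[ok]),
    sd_auc = stats::sd(fold_auc[ok]),
    hyper = fold_hyper,
    fold_roc = fold_roc,
    mean_roc = data.frame(fpr = fpr_grid, tpr = rowMeans(tpr_mat)),
    coefficients = rowMeans(coef_mat),
    fold_coefficients = coef_mat,
    fold = fold, n = n
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result%s> mean AUC %.3f (SD %.3f) over %d folds, n=%d\n",
              if (is.na(x$time_point)) "" else paste0(": ", x$time_point),
              x$mean_auc, x$sd_auc, sum(!is.na(x$fold_auc)), x$n))
  invisible(x)
}

#' Rank features by averaged elastic-net coefficient magnitude
#'
#' Non-zero mean coefficients sorted by absolute value, signed values
#' retained; zero-weight features are omitted.
#'
#' @param x A `cv_result` or a named numeric coefficient vector.
#' @return data.frame with feature, coefficient, rank. Empty (with a
#'   warning) when every coefficient is zero.
#' @export
rank_coefficients <- function(x) {
  coefs <- if (inherits(x, "cv_result")) x$coefficients else x
  nz <- coefs[coefs != 0]
  if (!length(nz)) {
    warning("all coefficients are zero; nothing to rank")
    return(data.frame(feature = character(0), coefficient = numeric(0),
                      rank = integer(0)))
  }
  ord <- order(abs(nz), decreasing = TRUE)
  data.frame(feature = names(nz)[ord], coefficient = unname(nz[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
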