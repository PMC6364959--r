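test_that("zero penalty coincides with least squares", {
  inst <- random_instance(50, 5, seed = 1)
  fit <- fit_elasticnet(inst$X, inst$y, alpha = 0.3, lambda = 0)
  ols <- stats::lm.fit(cbind(1, inst$X), inst$y)$coefficients
  expect_lt(max(abs(fit$coefficients - ols[-1])), 1e-6)
  expect_lt(abs(fit$intercept - ols[1]), 1e-6)
})

test_that("alpha = 1 matches the closed-form ridge solution", {
  for (s in 1:3) {
    inst <- random_instance(40, 6, seed = 10 + s)
    for (lam in c(0.05, 1, 10)) {
      fit <- fit_elasticnet(inst$X, inst$y, alpha = 1, lambda = lam)
      rid <- oracle_ridge(inst$X, inst$y, lam)
      expect_lt(max(abs(fit$coefficients - rid$beta)), 1e-6)
      expect_lt(abs(fit$intercept - rid$b0), 1e-6)
    }
  }
})

test_that("coordinate descent matches the proximal-gradient oracle", {
  for (s in 1:5) {
    inst <- random_instance(20, 8, seed = 100 + s)
    fit <- fit_elasticnet(inst$X, inst$y, alpha = 0.3, lambda = 0.05)
    orc <- oracle_elnet_fista(inst$X, inst$y, 0.3, 0.05)
    o_fit <- elnet_objective(inst$X, inst$y, fit$coefficients, fit$intercept,
                             0.3, 0.05)
    o_orc <- oracle_objective(inst$X, inst$y, orc$beta, orc$b0, 0.3, 0.05)
    expect_lt(abs(o_fit - o_orc), 1e-8)
    # and the R-side objective agrees with the compiled one
    expect_equal(o_fit, oracle_objective(inst$X, inst$y, fit$coefficients,
                                         fit$intercept, 0.3, 0.05),
                 tolerance = 1e-12)
  }
})

test_that("penalty drives coefficients to zero and input is validated", {
  inst <- random_instance(30, 4, seed = 3)
  big <- fit_elasticnet(inst$X, inst$y, alpha = 0.3, lambda = 1e7)
  expect_true(all(big$coefficients == 0))
  expect_equal(big$intercept, mean(inst$y), tolerance = 1e-6)
  # penalty term is non-decreasing in lambda at fixed beta
  b <- stats::rnorm(4)
  pen <- function(lam) {
    elnet_objective(inst$X * 0, inst$y * 0, b, 0, 0.3, lam)
  }
  lams <- c(0, 0.01, 0.1, 1, 10)
  expect_true(all(diff(vapply(lams, pen, numeric(1))) >= 0))
  Xbad <- inst$X
  Xbad[1, 1] <- NA
  expect_error(fit_elasticnet(Xbad, inst$y), "finite")
  expect_error(fit_elasticnet(inst$X, inst$y, alpha = 2), "alpha")
  expect_error(fit_elasticnet(inst$X, inst$y, max_iter = 2L), "converge")
})

test_that("compute_auc equals the all-pairs brute force", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(compute_auc(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(compute_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(31)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(stats::rnorm(n), sample(0:2, 1)) # induce ties
    expect_equal(compute_auc(scores, labels)$auc, oracle_auc(scores, labels),
                 info = i)
  }
  expect_warning(out <- compute_auc(1:3, c(1, 1, 1)), "one class")
  expect_true(is.na(out$auc))
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(17)
  scores <- stats::rnorm(60)
  labels <- sample(0:1, 60, replace = TRUE)
  base <- compute_auc(scores, labels)$auc
  for (f in list(function(x) 3 * x + 2, exp, function(x) x^3)) {
    expect_equal(compute_auc(f(scores), labels)$auc, base)
  }
})

test_that("binarize_response uses delta > 0 with ties negative", {
  expect_identical(binarize_response(c(0.5, 0, -1, NA)),
                   c(1L, 0L, 0L, NA))
})

test_that("nested_cv is deterministic and finds planted signal", {
  set.seed(7)
  n <- 300
  X <- matrix(stats::rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  delta <- X[, 1] * 2 + stats::rnorm(n, 0, 0.3)
  grid <- data.frame(alpha = c(0.3, 1), lambda = c(0.05, 0.1))
  cv1 <- nested_cv(X, delta, grid, k_outer = 5L, k_inner = 3L, seed = 11L)
  cv2 <- nested_cv(X, delta, grid, k_outer = 5L, k_inner = 3L, seed = 11L)
  expect_identical(cv1$fold_auc, cv2$fold_auc)
  expect_identical(cv1$fold, cv2$fold)
  expect_gt(cv1$mean_auc, 0.95)
  expect_equal(cv1$mean_auc, mean(cv1$fold_auc, na.rm = TRUE))
  rc <- rank_coefficients(cv1)
  expect_identical(rc$feature[1], "f1")
  # mean ROC is a proper curve on the fixed grid
  expect_identical(nrow(cv1$mean_roc), 101L)
  expect_true(all(diff(cv1$mean_roc$tpr) >= -1e-12))
})

test_that("a label-copy feature leaked into the test folds cannot help", {
  set.seed(21)
  n <- 240
  X <- matrix(stats::rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  delta <- X[, 1] + stats::rnorm(n, 0, 2) # weak signal
  labels <- binarize_response(delta)
  grid <- data.frame(alpha = 0.3, lambda = 0.05)
  base <- nested_cv(X, delta, grid, k_outer = 5L, k_inner = 3L, seed = 4L)
  # after fold assignment, poison fold 1's rows only: its training data
  # (folds 2-5) carry pure noise in the extra column, its held-out rows a
  # label copy. Per-fold preprocessing must not let it help.
  fold <- make_stratified_folds(labels, 5L, seed = 4L)
  z <- stats::rnorm(n)
  z[fold == 1L] <- labels[fold == 1L]
  X2 <- cbind(X, leak = z)
  leak <- nested_cv(X2, delta, grid, k_outer = 5L, k_inner = 3L, seed = 4L)
  expect_identical(leak$fold, fold) # same folds, so the poison aligns
  expect_lt(leak$fold_auc[1], base$fold_auc[1] + 0.05)
})

test_that("rank_coefficients handles the all-zero case", {
  v <- c(a = 0, b = 0)
  expect_warning(rc <- rank_coefficients(v), "zero")
  expect_identical(nrow(rc), 0L)
  rc <- rank_coefficients(c(a = 0, b = -2, c = 1))
  expect_identical(rc$feature, c("b", "c"))
  expect_identical(rc$coefficient, c(-2, 1))
})
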