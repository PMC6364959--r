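# Comparator baselines run through the same outer folds as the elastic
# net. Backends are pluggable: each is a function(Xtr, ytr, ltr, Xte, seed)
# returning a numeric score per test row. No suitable SVM / random-forest
# package ships in the supported environment, so compact self-contained
# implementations (batch-subgradient linear SVM; bagged CART trees) back
# the standard model names; a missing backend yields an "unavailable" row,
# never a failure.

# -- linear support vector classifier (batch subgradient on hinge loss) ------
svc_backend <- function(Xtr, ytr, ltr, Xte, seed,
                        lambda = 1e-3, iters = 300L) {
  y <- ifelse(ltr == 1L, 1, -1)
  n <- nrow(Xtr); p <- ncol(Xtr)
  w <- numeric(p); b <- 0
  for (t in seq_len(iters)) {
    eta <- 1 / (lambda * t)
    margin <- y * (drop(Xtr %*% w) + b)
    viol <- margin < 1
    gw <- lambda * w - colSums(Xtr[viol, , drop = FALSE] * y[viol]) / n
    gb <- -sum(y[viol]) / n
    w <- w - eta * gw
    b <- b - eta * gb
  }
  drop(Xte %*% w) + b
}

# -- compact CART + bagging ---------------------------------------------------

# grow one tree on (X, y); `criterion` is "gini" (y in {0,1}) or "variance"
grow_tree <- function(X, y, criterion, max_depth, min_node, mtry) {
  impurity <- if (criterion == "gini") {
    function(y) { p <- mean(y); 2 * p * (1 - p) * length(y) }
  } else {
    function(y) if (length(y) < 2L) 0 else stats::var(y) * (length(y) - 1)
  }
  build <- function(idx, depth) {
    y_node <- y[idx]
    leaf <- list(leaf = TRUE, value = mean(y_node))
    if (depth >= max_depth || length(idx) < 2L * min_node ||
        length(unique(y_node)) == 1L) {
      return(leaf)
    }
    feats <- sample.int(ncol(X), mtry)
    best <- list(gain = 1e-12)
    node_imp <- impurity(y_node)
    for (j in feats) {
      xj <- X[idx, j]
      qs <- unique(stats::quantile(xj, probs = seq(0.1, 0.9, by = 0.1),
                                   names = FALSE, type = 1))
      for (thr in qs) {
        left <- xj <= thr
        nl <- sum(left)
        if (nl < min_node || length(idx) - nl < min_node) next
        gain <- node_imp - impurity(y_node[left]) - impurity(y_node[!left])
        if (gain > best$gain) best <- list(gain = gain, j = j, thr = thr)
      }
    }
    if (is.null(best$j)) return(leaf)
    left <- X[idx, best$j] <= best$thr
    list(leaf = FALSE, j = best$j, thr = best$thr,
         left = build(idx[left], depth + 1L),
         right = build(idx[!left], depth + 1L))
  }
  build(seq_len(nrow(X)), 0L)
}

predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  walk <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$value; return() }
    left <- X[idx, node$j] <= node$thr
    walk(node$left, idx[left])
    walk(node$right, idx[!left])
  }
  walk(tree, seq_len(nrow(X)))
  out
}

bagged_forest <- function(Xtr, ytr, Xte, criterion, seed, n_trees = 25L,
                          max_depth = 5L, min_node = 5L) {
  set.seed(seed)
  mtry <- max(1L, if (criterion == "gini") floor(sqrt(ncol(Xtr)))
              else floor(ncol(Xtr) / 3))
  preds <- matrix(0, nrow(Xte), n_trees)
  for (b in seq_len(n_trees)) {
    boot <- sample.int(nrow(Xtr), replace = TRUE)
    tree <- grow_tree(Xtr[boot, , drop = FALSE], ytr[boot], criterion,
                      max_depth, min_node, mtry)
    preds[, b] <- predict_tree(tree, Xte)
  }
  rowMeans(preds)
}

rf_classifier_backend <- function(Xtr, ytr, ltr, Xte, seed, ...) {
  bagged_forest(Xtr, as.numeric(ltr), Xte, "gini", seed, ...)
}

rf_regressor_backend <- function(Xtr, ytr, ltr, Xte, seed, ...) {
  bagged_forest(Xtr, ytr, Xte, "variance", seed, ...)
}

default_backends <- function() {
  list(
    "Support Vector Classifier" = svc_backend,
    "Random Forest Classifier" = rf_classifier_backend,
    "Random Forest Regressor" = rf_regressor_backend
  )
}

#' Cross-validated comparison of prediction models
#'
#' Runs the comparator backends and the bespoke elastic net through the same
#' stratified outer folds and reports mean (SD) fold AUC per model -- the
#' four-model comparison layout. Backends receive fold-standardized features
#' and return a ranking score for the held-out fold. A backend set to NULL
#' is reported as unavailable rather than failing.
#'
#' @param X Raw feature matrix (NA allowed; per-fold imputation).
#' @param delta Continuous change-in-pain response.
#' @param k_outer Outer fold count.
#' @param seed Integer seed (fold assignment and backend randomness).
#' @param grid Elastic-net hyperparameter grid for the nested search.
#' @param k_inner Inner fold count for the elastic net.
#' @param backends Named list of backend functions
#'   (`function(Xtr, ytr, ltr, Xte, seed)`); defaults to the built-ins.
#' @param cv An optional precomputed `cv_result` for the elastic net with
#'   the same X/delta/k_outer/seed (avoids refitting).
#' @return data.frame: model, mean_auc, sd_auc, n_folds, available.
#' @export
run_comparators <- function(X, delta, k_outer = 10L, seed = 1L,
                            grid = default_hyper_grid(), k_inner = 5L,
                            backends = default_backends(), cv = NULL) {
  X <- as.matrix(X)
  keep <- !is.na(delta)
  X <- X[keep, , drop = FALSE]
  delta <- delta[keep]
  labels <- binarize_response(delta)
  fold <- make_stratified_folds(labels, k_outer, seed)

  rows <- list()
  for (nm in names(backends)) {
    fn <- backends[[nm]]
    if (is.null(fn)) {
      rows[[nm]] <- data.frame(model = nm, mean_auc = NA_real_,
                               sd_auc = NA_real_, n_folds = 0L,
                               available = FALSE)
      next
    }
    aucs <- rep(NA_real_, k_outer)
    for (f in seq_len(k_outer)) {
      test <- fold == f
      if (length(unique(labels[test])) < 2L) next
      prep <- impute_standardize(X[!test, , drop = FALSE],
                                 X[test, , drop = FALSE])
      sc <- fn(prep$train, delta[!test], labels[!test], prep$test,
               child_seed(seed, 200L + f))
      aucs[f] <- suppressWarnings(compute_auc(sc, labels[test])$auc)
    }
    rows[[nm]] <- data.frame(model = nm, mean_auc = mean(aucs, na.rm = TRUE),
                             sd_auc = stats::sd(aucs[!is.na(aucs)]),
                             n_folds = sum(!is.na(aucs)), available = TRUE)
  }
  if (is.null(cv)) {
    cv <- nested_cv(X, delta, grid = grid, k_outer = k_outer,
                    k_inner = k_inner, seed = seed)
  }
  rows[["Elastic Net"]] <- data.frame(
    model = "Elastic Net", mean_auc = cv$mean_auc, sd_auc = cv$sd_auc,
    n_folds = sum(!is.na(cv$fold_auc)), available = TRUE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
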