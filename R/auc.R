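#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' AUC is the fraction of (positive, negative) pairs in which the positive
#' scores higher, with ties counted 1/2 -- computed via the rank-sum
#' identity. ROC points come from a threshold sweep over the unique scores
#' (predict positive when score >= threshold), anchored at (0,0) and (1,1).
#'
#' @param scores Numeric ranking scores (higher = more likely positive).
#' @param labels 0/1 or logical labels.
#' @return List with `auc` and `roc` (data.frame fpr, tpr). With only one
#'   class present, `auc` is NA with a warning.
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    warning("only one class present; AUC undefined")
    return(list(auc = NA_real_, roc = data.frame(fpr = c(0, 1),
                                                 tpr = c(0, 1))))
  }
  r <- rank(scores) # average ranks handle ties as 1/2 wins
  auc <- (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / npos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / nneg,
                numeric(1))
  list(auc = auc, roc = data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)))
}

# interpolate a fold ROC at fixed false-positive rates (vertical averaging)
interp_roc <- function(roc, fpr_grid) {
  stats::approx(roc$fpr, roc$tpr, xout = fpr_grid, ties = max, rule = 2)$y
}
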