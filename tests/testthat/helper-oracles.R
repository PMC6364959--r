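# Independent oracles. These deliberately re-derive results by brute force
# (full enumeration, generic optimisers, closed forms) and stay independent
# of the package's implementation paths.

# --- NegEx oracle: enumerate every (concept, trigger, terminator) span ------

oracle_all_spans <- function(tokens, phrases) {
  out <- NULL
  n <- length(tokens)
  for (ph in phrases) {
    pt <- strsplit(ph, " ", fixed = TRUE)[[1]]
    L <- length(pt)
    if (L > n) next
    for (s in seq_len(n - L + 1L)) {
      if (all(tokens[s:(s + L - 1L)] == pt)) {
        out <- rbind(out, c(s, s + L - 1L))
      }
    }
  }
  out
}

# sentence label by exhaustive enumeration; mirrors the documented rule, not
# the package's scanning code
oracle_classify <- function(sentence, lexicon, window = 5L) {
  toks <- painpheno::preprocess(sentence)
  if (length(toks) != 1L) stop("oracle expects one sentence")
  raw <- toks[[1]]$tokens
  keep <- toks[[1]]$keep
  view_idx <- which(keep)
  view <- raw[keep]

  cm <- oracle_all_spans(view, lexicon$concept)
  if (!is.null(cm)) {
    # longest-match: drop spans contained in a longer matched span, then
    # greedy left-to-right non-overlap
    len <- cm[, 2] - cm[, 1]
    ord <- order(cm[, 1], -len)
    cm <- cm[ord, , drop = FALSE]
    sel <- NULL
    last_end <- 0L
    for (r in seq_len(nrow(cm))) {
      if (cm[r, 1] > last_end) {
        sel <- rbind(sel, cm[r, ])
        last_end <- cm[r, 2]
      }
    }
    cm <- sel
    cm <- cbind(view_idx[cm[, 1]], view_idx[cm[, 2]]) # raw-scale spans
  }
  if (is.null(cm)) return("NoMention")

  ex <- oracle_all_spans(raw, lexicon$exclusion)
  if (!is.null(ex)) {
    for (r in seq_len(nrow(cm))) {
      for (q in seq_len(nrow(ex))) {
        if (cm[r, 1] <= ex[q, 2] && ex[q, 1] <= cm[r, 2]) return("NoMention")
      }
    }
  }

  pre <- oracle_all_spans(raw, lexicon$pre_neg)
  post <- oracle_all_spans(raw, lexicon$post_neg)
  term <- oracle_all_spans(raw, lexicon$termination)
  term_between <- function(a, b) {
    if (is.null(term)) return(FALSE)
    any(term[, 1] > a & term[, 2] < b)
  }
  negated <- logical(nrow(cm))
  for (r in seq_len(nrow(cm))) {
    cs <- cm[r, 1]; ce <- cm[r, 2]
    if (!is.null(pre)) {
      for (q in seq_len(nrow(pre))) {
        gap <- cs - pre[q, 2] - 1L
        if (pre[q, 2] < cs && gap >= 0L && gap <= window &&
            !term_between(pre[q, 2], cs)) negated[r] <- TRUE
      }
    }
    if (!is.null(post)) {
      for (q in seq_len(nrow(post))) {
        gap <- post[q, 1] - ce - 1L
        if (post[q, 1] > ce && gap >= 0L && gap <= window &&
            !term_between(ce, post[q, 1])) negated[r] <- TRUE
      }
    }
  }
  if (all(negated)) "Negated" else "Affirmed"
}

# --- elastic net oracle: FISTA proximal gradient ----------------------------

# minimises sum((y - b0 - X b)^2) + alpha*lambda*||b||_2^2 +
# lambda*(1-alpha)/2*||b||_1 with unpenalised intercept
oracle_elnet_fista <- function(X, y, alpha, lambda, iters = 50000L,
                               tol = 1e-12) {
  Xa <- cbind(1, X)
  p <- ncol(X)
  L <- 2 * (max(eigen(crossprod(Xa), symmetric = TRUE,
                      only.values = TRUE)$values) + alpha * lambda)
  cpen <- lambda * (1 - alpha) / 2
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  b <- numeric(p + 1L)
  z <- b
  tk <- 1
  for (it in seq_len(iters)) {
    r <- y - drop(Xa %*% z)
    grad <- -2 * drop(crossprod(Xa, r))
    grad[-1] <- grad[-1] + 2 * alpha * lambda * z[-1]
    bn <- z - grad / L
    bn[-1] <- soft(bn[-1], cpen / L)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- bn + (tk - 1) / tn * (bn - b)
    if (max(abs(bn - b)) < tol && it > 10L) { b <- bn; break }
    b <- bn
    tk <- tn
  }
  list(b0 = b[1], beta = b[-1])
}

oracle_objective <- function(X, y, beta, b0, alpha, lambda) {
  sum((y - b0 - drop(X %*% beta))^2) + alpha * lambda * sum(beta^2) +
    lambda * (1 - alpha) / 2 * sum(abs(beta))
}

# closed-form ridge (alpha = 1): centred normal equations
oracle_ridge <- function(X, y, lambda) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  beta <- solve(crossprod(Xc) + diag(lambda, ncol(X)), crossprod(Xc, yc))
  list(beta = drop(beta),
       b0 = mean(y) - drop(colMeans(X) %*% beta))
}

# --- AUC oracle: all-pairs count --------------------------------------------

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
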