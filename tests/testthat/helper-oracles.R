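# Independent oracles used to freeze expected values. Each one is a direct,
# slow transcription of the defining formula, deliberately sharing no code
# with the implementation under test.

# Pearson correlation of two vectors by explicit summation.
oracle_pearson <- function(a, b) {
  n <- length(a)
  am <- sum(a) / n
  bm <- sum(b) / n
  num <- sum((a - am) * (b - bm))
  den <- sqrt(sum((a - am)^2)) * sqrt(sum((b - bm)^2))
  num / den
}

# Plug-in mutual information by double loop over the joint table (nats).
oracle_mi <- function(a, b) {
  ua <- unique(a)
  ub <- unique(b)
  n <- length(a)
  mi <- 0
  for (x in ua) {
    for (y in ub) {
      pxy <- sum(a == x & b == y) / n
      if (pxy > 0) {
        mi <- mi + pxy * log(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
      }
    }
  }
  mi
}

# Greedy mRMR (MID) by exhaustive re-evaluation with oracle_mi.
oracle_mrmr_mid <- function(X, y, n_features) {
  p <- ncol(X)
  rel <- sapply(seq_len(p), function(j) oracle_mi(X[, j], y))
  sel <- which.max(rel)
  while (length(sel) < n_features) {
    rest <- setdiff(seq_len(p), sel)
    score <- sapply(rest, function(j) {
      rel[j] - mean(sapply(sel, function(s) oracle_mi(X[, j], X[, s])))
    })
    sel <- c(sel, rest[which.max(score)])
  }
  sel
}

# Brute-force weighted-kNN imputation of a single cell.
oracle_impute_cell <- function(X, i, f, k, eps = 1e-8) {
  n <- nrow(X)
  d <- rep(NA_real_, n)
  for (j in seq_len(n)[-i]) {
    co <- !is.na(X[i, ]) & !is.na(X[j, ])
    if (any(co)) d[j] <- sqrt(sum((X[i, co] - X[j, co])^2))
  }
  cand <- which(!is.na(X[, f]) & !is.na(d))
  nb <- cand[order(d[cand], cand)][seq_len(min(k, length(cand)))]
  w <- 1 / (eps + d[nb])
  sum(w * X[nb, f]) / sum(w)
}

# Confusion-table metrics straight from the definitions (0-convention for
# empty denominators, NA for single-class Mcc).
oracle_confusion_metrics <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  div <- function(a, b) if (b == 0) 0 else a / b
  sn <- div(tp, tp + fn)
  sp <- div(tn, tn + fp)
  pre <- div(tp, tp + fp)
  f1 <- if (pre + sn == 0) 0 else 2 * pre * sn / (pre + sn)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (tp + fn == 0 || tn + fp == 0) {
    NA_real_
  } else if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  list(Acc = (tp + tn) / n, Mcc = mcc, Pre = pre, Sn = sn, Sp = sp,
       Bal_Acc = (sn + sp) / 2, F1 = f1)
}

# Trapezoid-rule AUC over the empirical ROC (threshold sweep).
oracle_auc_trapezoid <- function(y, s) {
  ths <- sort(unique(s), decreasing = TRUE)
  tpr <- c(0, sapply(ths, function(t) sum(s >= t & y == 1) / sum(y == 1)), 1)
  fpr <- c(0, sapply(ths, function(t) sum(s >= t & y == 0) / sum(y == 0)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Choquet integral by direct expansion of the telescoping sum, with the
# suffix-set measure built by its own lambda fold.
oracle_choquet <- function(scores, densities, lam) {
  ord <- order(scores, seq_along(scores))
  s <- scores[ord]
  m <- length(s)
  mu_of <- function(idx) {
    mu <- 0
    for (g in densities[idx]) mu <- mu + g + lam * mu * g
    mu
  }
  total <- 0
  prev <- 0
  for (i in seq_len(m)) {
    total <- total + (s[i] - prev) * mu_of(ord[i:m])
    prev <- s[i]
  }
  total
}

# Newman modularity of a partition from a binary adjacency.
oracle_modularity <- function(A, membership) {
  m2 <- sum(A) # twice the edge count
  if (m2 == 0) return(0)
  deg <- rowSums(A)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(A[idx, idx]) / m2 - (sum(deg[idx]) / m2)^2
  }
  q
}

mean_offdiag <- function(M) {
  (sum(M) - sum(diag(M))) / (length(M) - nrow(M))
}
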