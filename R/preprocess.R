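#' Column-wise min-max normalization to \[0, 1\]
#'
#' Each column is mapped by `(x - min) / (max - min)`. Constant columns carry
#' no information about the range and map to 0 by convention, which keeps the
#' operation idempotent.
#'
#' @param X numeric matrix (samples in rows), no missing values.
#' @return matrix of the same shape with every column in \[0, 1\].
#' @export
minmax_normalize <- function(X) {
  X <- as_numeric_matrix(X)
  if (nrow(X) < 1L) stop("need at least one row")
  if (anyNA(X)) stop("missing values present; impute before normalizing")
  mins <- apply(X, 2, min)
  spans <- apply(X, 2, max) - mins
  out <- sweep(X, 2, mins, "-")
  nz <- spans > 0
  if (any(nz)) out[, nz] <- sweep(out[, nz, drop = FALSE], 2, spans[nz], "/")
  out[, !nz] <- 0
  out
}

#' Discretize expression into under/baseline/over-expression
#'
#' Columns are z-scored; entries with `z < -z_cut` become -1
#' (under-expression), `z > z_cut` become +1 (over-expression), the rest 0
#' (baseline). Zero-variance columns are all baseline. The symmetric cutoff
#' `z_cut = 1` is the package default (the ternary coding itself fixes only
#' the sign convention, not the cutoff).
#'
#' @param X numeric matrix of expression values (samples in rows).
#' @param z_cut positive z-score cutoff.
#' @return integer-valued matrix over \{-1, 0, 1\}.
#' @export
discretize_expression <- function(X, z_cut = 1) {
  X <- as_numeric_matrix(X)
  if (anyNA(X)) stop("missing values present; impute before discretizing")
  stopifnot(is.numeric(z_cut), length(z_cut) == 1L, z_cut > 0)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  out <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
  nz <- which(sdv > 0)
  if (length(nz)) {
    Z <- sweep(sweep(X[, nz, drop = FALSE], 2, mu[nz], "-"), 2, sdv[nz], "/")
    out[, nz] <- (Z > z_cut) - (Z < -z_cut)
  }
  out
}

#' Weighted k-nearest-neighbour imputation
#'
#' Each missing cell is replaced by the weighted average of the `k` nearest
#' rows that observe the feature, where distances are Euclidean over the
#' features co-observed by the two rows and weights are `1 / (eps + dist)`.
#' Observed cells are returned untouched.
#'
#' @param X numeric matrix with `NA` for missing cells; every row must
#'   observe at least one feature and every feature must be observed in at
#'   least one row.
#' @param k number of neighbours (default 5).
#' @param eps additive constant protecting against division by zero for
#'   coincident rows.
#' @return the completed matrix.
#' @export
impute_knn_weighted <- function(X, k = 5, eps = 1e-8) {
  X <- as_numeric_matrix(X)
  stopifnot(k >= 1)
  if (!anyNA(X)) return(X)
  obs <- !is.na(X)
  if (any(colSums(obs) == 0L)) {
    stop("feature(s) missing in all rows cannot be imputed: ",
         paste(colnames(X)[colSums(obs) == 0L], collapse = ", "))
  }
  if (any(rowSums(obs) == 0L)) stop("row(s) with no observed values")
  out <- X
  need <- which(rowSums(!obs) > 0L)
  n <- nrow(X)
  for (i in need) {
    # squared distances to every other row over co-observed features
    d2 <- rep(NA_real_, n)
    for (j in seq_len(n)[-i]) {
      co <- obs[i, ] & obs[j, ]
      if (any(co)) d2[j] <- sum((X[i, co] - X[j, co])^2)
    }
    d <- sqrt(d2)
    for (f in which(!obs[i, ])) {
      cand <- which(obs[, f] & !is.na(d))
      if (!length(cand)) {
        warning("no neighbour observes feature ", colnames(X)[f],
                " for row ", rownames(X)[i], "; using feature mean")
        out[i, f] <- mean(X[obs[, f], f])
        next
      }
      nb <- cand[order(d[cand], cand)][seq_len(min(k, length(cand)))]
      w <- 1 / (eps + d[nb])
      out[i, f] <- sum(w * X[nb, f]) / sum(w)
    }
  }
  out
}

# Plug-in mutual information (nats) between two integer-coded vectors
# (codes in 1..na / 1..nb). The coding is hoisted out so greedy selection
# can reuse it across the O(p^2) pairwise calls.
mi_coded <- function(a, na, b, nb) {
  n <- length(a)
  pj <- matrix(tabulate((a - 1L) * nb + b, nbins = na * nb) / n,
               nrow = nb, ncol = na) # column index = a, row index = b
  pa <- colSums(pj)
  pb <- rowSums(pj)
  pe <- outer(pb, pa)
  pos <- pj > 0
  sum(pj[pos] * log(pj[pos] / pe[pos]))
}

code_discrete <- function(v) match(v, sort(unique(v)))

mi_discrete <- function(a, b) {
  a <- code_discrete(a)
  b <- code_discrete(b)
  mi_coded(a, max(a), b, max(b))
}

#' mRMR feature selection (greedy forward, discrete mutual information)
#'
#' Minimum-redundancy maximum-relevance selection with the MID (difference)
#' criterion: at each step the feature maximizing
#' `I(f; y) - mean_{s in S} I(f; s)` joins the selected set `S`, starting
#' from the feature of maximal label relevance. Mutual information is the
#' plug-in estimate on empirical joint frequencies, so `X` must be
#' discrete-valued (the GE/CNA alphabets) or pre-binned. Ties break to the
#' lowest feature index, making the ordering deterministic.
#'
#' @param X discrete-valued numeric matrix (samples in rows).
#' @param y binary label vector aligned with rows of `X`.
#' @param n_features number of features to select.
#' @param variant `"MID"` (difference, default) or `"MIQ"` (quotient).
#' @return integer vector of selected column indices in selection order.
#' @export
mrmr_select <- function(X, y, n_features, variant = c("MID", "MIQ")) {
  X <- as_numeric_matrix(X)
  variant <- match.arg(variant)
  y <- as.integer(y)
  p <- ncol(X)
  stopifnot(length(y) == nrow(X), n_features >= 1, n_features <= p)
  if (length(unique(y)) < 2L) stop("constant labels: relevance undefined")
  codes <- lapply(seq_len(p), function(j) code_discrete(X[, j]))
  nlev <- vapply(codes, max, integer(1))
  yc <- code_discrete(y)
  nyc <- max(yc)
  rel <- vapply(seq_len(p), function(j) {
    mi_coded(codes[[j]], nlev[j], yc, nyc)
  }, numeric(1))
  selected <- integer(n_features)
  selected[1L] <- which.max(rel) # first max = lowest index on ties
  if (n_features > 1L) {
    red_sum <- rep(0, p)
    remaining <- setdiff(seq_len(p), selected[1L])
    for (m in 2:n_features) {
      last <- selected[m - 1L]
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(j) {
          mi_coded(codes[[j]], nlev[j], codes[[last]], nlev[last])
        }, numeric(1))
      score <- if (variant == "MID") {
        rel[remaining] - red_sum[remaining] / (m - 1L)
      } else {
        rel[remaining] / (red_sum[remaining] / (m - 1L) + .Machine$double.eps)
      }
      pick <- remaining[which.max(score)]
      selected[m] <- pick
      remaining <- setdiff(remaining, pick)
    }
  }
  selected
}

# Rank-based ROC AUC (equivalent to the trapezoid rule on the empirical ROC,
# with average ranks handling ties).
auc_rank <- function(y_true, y_score) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1L)
  n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(y_score)
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Search the mRMR feature count by proxy-classifier AUC
#'
#' Evaluates each candidate count on a stratified holdout with a fast
#' ridge-logistic proxy classifier and returns the candidate with maximal
#' validation ROC-AUC, ties going to the smaller count. Greedy mRMR
#' orderings are nested, so the full ordering is computed once and candidate
#' counts are evaluated as prefixes.
#'
#' @param X discrete-valued numeric matrix.
#' @param y binary labels aligned with rows.
#' @param candidates integer vector of counts to try (values above `ncol(X)`
#'   are capped); the conventional sweep is 100 to 500 in steps of 100.
#' @param seed integer seed for the stratified split.
#' @param val_fraction holdout fraction (default 0.2).
#' @return the chosen feature count (integer).
#' @export
search_feature_count <- function(X, y, candidates, seed = 1L,
                                 val_fraction = 0.2) {
  X <- as_numeric_matrix(X)
  y <- as.integer(y)
  stopifnot(length(candidates) >= 1)
  candidates <- sort(unique(pmin(as.integer(candidates), ncol(X))))
  if (length(candidates) == 1L) return(candidates)
  ord <- mrmr_select(X, y, max(candidates))
  val <- stratified_holdout(y, val_fraction, seed)
  tr <- setdiff(seq_len(nrow(X)), val)
  aucs <- vapply(candidates, function(nf) {
    sel <- ord[seq_len(nf)]
    Xtr <- X[tr, sel, drop = FALSE]
    if (ncol(Xtr) == 1L) Xtr <- cbind(Xtr, Xtr) # glmnet needs >= 2 columns
    fit <- glmnet::glmnet(Xtr, factor(y[tr]), family = "binomial",
                          alpha = 0, lambda = 0.01, standardize = FALSE)
    Xv <- X[val, sel, drop = FALSE]
    if (ncol(Xv) == 1L) Xv <- cbind(Xv, Xv)
    s <- as.numeric(predict(fit, Xv, type = "response"))
    auc_rank(y[val], s)
  }, numeric(1))
  candidates[which.max(aucs)] # first max = smallest candidate on ties
}

#' SMOTE oversampling of the minority class
#'
#' Synthetic minority points are drawn on segments between a random minority
#' sample and one of its `k` nearest minority neighbours:
#' `x + u * (x_n - x)` with `u ~ Uniform(0, 1)`. Original rows are preserved
#' verbatim and synthetic rows are appended until the classes balance.
#' Intended for the training partition only; oversampling before a
#' train/test split leaks test information.
#'
#' @param X numeric feature matrix (samples in rows).
#' @param y binary labels aligned with rows.
#' @param k number of minority neighbours (reduced with a warning when the
#'   minority class is smaller than `k + 1`).
#' @param seed integer seed.
#' @return list with balanced `X` and `y`; synthetic rows carry suffixed
#'   rownames.
#' @export
smote_oversample <- function(X, y, k = 5, seed = 1L) {
  X <- as_numeric_matrix(X)
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X))
  tab <- table(factor(y, levels = c(0L, 1L)))
  if (tab[1] == tab[2]) return(list(X = X, y = y))
  minority <- as.integer(names(tab)[which.min(tab)])
  n_min <- min(tab)
  n_new <- abs(tab[1] - tab[2])
  idx_min <- which(y == minority)
  Xmin <- X[idx_min, , drop = FALSE]
  if (n_min == 1L) {
    warning("single minority sample: falling back to duplication")
    synth <- Xmin[rep(1L, n_new), , drop = FALSE]
  } else {
    if (n_min <= k) {
      warning(sprintf("minority count %d <= k = %d; reducing k to %d",
                      n_min, k, n_min - 1L))
      k <- n_min - 1L
    }
    nn <- FNN::get.knn(Xmin, k = k)$nn.index
    synth <- with_seed(seed, {
      base <- sample.int(n_min, n_new, replace = TRUE)
      pick <- sample.int(k, n_new, replace = TRUE)
      u <- runif(n_new)
      nb <- nn[cbind(base, pick)]
      Xmin[base, , drop = FALSE] +
        u * (Xmin[nb, , drop = FALSE] - Xmin[base, , drop = FALSE])
    })
  }
  if (!is.null(rownames(X))) {
    rownames(synth) <- sprintf("synth_%04d", seq_len(nrow(synth)))
  }
  list(
    X = rbind(X, synth),
    y = c(y, rep(minority, n_new))
  )
}
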