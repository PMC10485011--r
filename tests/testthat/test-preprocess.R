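test_that("minmax_normalize maps columns to [0,1] with the stated conventions", {
  X <- cbind(a = c(2, 4, 6), b = c(3, 3, 3), c = c(1, 2, 4))
  out <- minmax_normalize(X)
  expect_equal(out[, "a"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(out[, "b"], c(0, 0, 0), ignore_attr = TRUE) # degenerate range
  expect_equal(out[, "c"], c(0, 1 / 3, 1), ignore_attr = TRUE)
  expect_error(minmax_normalize(cbind(c(1, NA))), "missing")
})

test_that("minmax_normalize is idempotent on its own output", {
  set.seed(101)
  for (i in 1:5) {
    X <- matrix(rnorm(60, sd = 10), 12, 5)
    X[, 3] <- 7 # constant column
    once <- minmax_normalize(X)
    expect_equal(minmax_normalize(once), once, tolerance = 1e-12)
    expect_true(all(once >= 0 & once <= 1))
  }
})

test_that("discretize_expression follows the column z-score rule", {
  # hand z-score oracle for (0,0,0,0,10): mean 2, sd sqrt(20)
  x <- c(0, 0, 0, 0, 10)
  z <- (x - mean(x)) / sd(x)
  expected <- ifelse(z > 1, 1, ifelse(z < -1, -1, 0))
  expect_equal(as.vector(discretize_expression(cbind(x))), expected)
  # outlier gets +1, all-equal column is all baseline
  X <- cbind(c(1, 1, 1, 1, 100), rep(5, 5))
  out <- discretize_expression(X)
  expect_equal(out[5, 1], 1)
  expect_equal(out[, 2], rep(0, 5), ignore_attr = TRUE)
  expect_true(all(out %in% c(-1, 0, 1)))
})

test_that("discretize_expression extreme counts shrink as z_cut grows", {
  set.seed(7)
  X <- matrix(rnorm(400), 40, 10)
  cuts <- c(0.5, 1, 1.5, 2, 3)
  n_extreme <- sapply(cuts, function(zc) sum(discretize_expression(X, zc) != 0))
  expect_true(all(diff(n_extreme) <= 0))
})

test_that("impute_knn_weighted reproduces the brute-force oracle", {
  X <- rbind(
    c(1.0, 2.0, 3.0),
    c(1.1, NA, 3.2),
    c(5.0, 6.0, 7.0),
    c(0.9, 2.1, 2.9)
  )
  out <- impute_knn_weighted(X, k = 2)
  expect_equal(out[2, 2], oracle_impute_cell(X, 2, 2, k = 2), tolerance = 1e-12)
  expect_equal(out[-2, ], X[-2, ]) # observed cells untouched
  # complete input is the identity
  expect_identical(impute_knn_weighted(X[-2, ]), X[-2, ])
  # a zero-distance duplicate row dominates the weighted average
  Y <- rbind(c(1, 2, 3), c(1, 2, NA), c(10, 20, 30))
  expect_equal(impute_knn_weighted(Y, k = 1)[2, 3], 3, tolerance = 1e-6)
  # unimputable feature
  Z <- rbind(c(1, NA), c(2, NA))
  expect_error(impute_knn_weighted(Z), "missing in all rows")
})

test_that("mrmr_select ranks relevance first and penalizes redundancy", {
  set.seed(11)
  n <- 80
  y <- rep(c(0L, 1L), n / 2)
  noisy_copy <- function(v, flip = 0.2) {
    ifelse(runif(n) < flip, 1L - v, v)
  }
  f1 <- noisy_copy(y, 0.05) # strongest single feature
  X <- cbind(
    f1 = f1,
    f2 = f1,                        # exact duplicate of f1
    f3 = noisy_copy(y, 0.10),       # independent informative
    f4 = sample(0:1, n, TRUE),
    f5 = sample(0:1, n, TRUE),
    f6 = sample(0:1, n, TRUE)
  )
  sel <- mrmr_select(X, y, 6)
  expect_equal(sel[1], 1L) # max relevance, tie broken to lowest index
  # redundancy pushes the duplicate below the independent informative one
  expect_lt(which(sel == 3L), which(sel == 2L))
  # full ordering is a permutation and matches the exhaustive oracle
  expect_setequal(sel, 1:6)
  expect_equal(sel, oracle_mrmr_mid(X, y, 6))
  expect_error(mrmr_select(X, rep(1L, n), 2), "constant")
})

test_that("mrmr_select with n = 1 is the argmax of label MI (exhaustive scan)", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60
    y <- sample(0:1, n, TRUE)
    X <- matrix(sample(-1:1, n * 8, TRUE), n, 8)
    X[, 4] <- ifelse(runif(n) < 0.15, sample(-1:1, n, TRUE), y)
    best <- which.max(sapply(seq_len(ncol(X)), function(j) oracle_mi(X[, j], y)))
    expect_equal(mrmr_select(X, y, 1), best)
  }
})

test_that("search_feature_count prefers the informative prefix", {
  expect_equal(search_feature_count(matrix(0:1, 10, 4), rep(0:1, 5), 3), 3L)
  wins <- 0
  for (seed in 1:10) {
    set.seed(seed + 300)
    n <- 120
    y <- rep(c(0L, 1L), n / 2)
    X <- matrix(sample(-1:1, n * 60, TRUE), n, 60)
    for (j in 1:10) X[, j] <- ifelse(runif(n) < 0.1, sample(-1:1, n, TRUE), y)
    pick <- search_feature_count(X, y, c(10, 60), seed = seed)
    if (pick == 10L) wins <- wins + 1
  }
  expect_gte(wins, 6) # majority across seeds
})

test_that("smote_oversample balances classes with convex-combination points", {
  b <- blob_data(n_per = 30)
  y <- c(rep(0L, 30), rep(1L, 10))
  X <- b$X[1:40, ]
  out <- smote_oversample(X, y, k = 3, seed = 9)
  expect_equal(sum(out$y == 0L), sum(out$y == 1L))
  expect_equal(out$X[1:40, ], X, ignore_attr = TRUE) # originals verbatim
  # every synthetic row is a convex combination of two minority originals
  minority <- X[y == 1L, ]
  synth <- out$X[-(1:40), , drop = FALSE]
  for (i in seq_len(nrow(synth))) {
    s <- synth[i, ]
    ok <- FALSE
    for (a in seq_len(nrow(minority))) {
      for (bb in seq_len(nrow(minority))) {
        d <- minority[bb, ] - minority[a, ]
        if (sum(d^2) == 0) {
          if (sum((s - minority[a, ])^2) < 1e-18) ok <- TRUE
        } else {
          u <- sum((s - minority[a, ]) * d) / sum(d^2)
          if (u >= -1e-9 && u <= 1 + 1e-9 &&
              sum((minority[a, ] + u * d - s)^2) < 1e-18) {
            ok <- TRUE
          }
        }
        if (ok) break
      }
      if (ok) break
    }
    expect_true(ok)
  }
})

test_that("smote_oversample handles degenerate minorities", {
  X <- matrix(rnorm(20), 10, 2)
  y <- c(rep(0L, 8), 1L, 1L)
  expect_warning(out <- smote_oversample(X, y, k = 5, seed = 1), "reducing k")
  expect_equal(sum(out$y == 1L), 8)
  # coincident minority points: synthetic points equal that point
  X2 <- rbind(matrix(rnorm(12), 6, 2), c(3, 3), c(3, 3))
  y2 <- c(rep(0L, 6), 1L, 1L)
  out2 <- suppressWarnings(smote_oversample(X2, y2, k = 1, seed = 2))
  synth <- out2$X[-(1:8), , drop = FALSE]
  expect_true(all(abs(sweep(synth, 2, c(3, 3))) < 1e-12))
  # balanced input returned unchanged
  yb <- rep(c(0L, 1L), 5)
  expect_identical(smote_oversample(X, yb, seed = 3)$X, X)
  # single minority sample falls back to duplication
  y1 <- c(rep(0L, 9), 1L)
  expect_warning(out3 <- smote_oversample(X, y1, seed = 4), "duplication")
  expect_true(all(out3$X[11:18, 1] == X[10, 1]))
})
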