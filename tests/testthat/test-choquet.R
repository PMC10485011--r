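test_that("fuzzy_densities divides scores by their sum", {
  expect_equal(fuzzy_densities(c(0.8, 0.8, 0.8)), rep(1 / 3, 3))
  expect_equal(fuzzy_densities(c(1, 1)), c(0.5, 0.5))
  expect_equal(fuzzy_densities(c(0.7, 0.8, 0.9)), c(7, 8, 9) / 24)
  expect_error(fuzzy_densities(c(0.5, 0)), "positive")
  expect_error(fuzzy_densities(c(0.5, -1)), "positive")
  # unnormalized densities pass through (general-lambda regime)
  expect_equal(fuzzy_densities(c(0.7, 0.8), normalize = FALSE), c(0.7, 0.8))
})

test_that("solve_lambda finds the interaction root of the measure equation", {
  # densities summing to 1 force additivity
  expect_identical(solve_lambda(c(1, 1, 1) / 3), 0)
  expect_identical(solve_lambda(fuzzy_densities(c(0.8, 0.85, 0.9))), 0)
  # (0.2, 0.3, 0.4): factoring lambda out of the cubic leaves
  # 0.024 lambda^2 + 0.26 lambda - 0.1 = 0, positive root by the formula
  lam <- solve_lambda(c(0.2, 0.3, 0.4))
  closed <- (-0.26 + sqrt(0.26^2 + 4 * 0.024 * 0.1)) / (2 * 0.024)
  expect_equal(lam, closed, tolerance = 1e-10)
  # sum > 1: root in (-1, 0)
  lam2 <- solve_lambda(c(0.5, 0.5, 0.5))
  expect_true(lam2 > -1 && lam2 < 0)
  # residual oracle over random density vectors, both regimes
  set.seed(2024)
  for (i in 1:100) {
    g <- runif(3, 0.05, 0.6)
    l <- solve_lambda(g)
    expect_lt(abs(prod(1 + l * g) - 1 - l), 1e-12)
  }
  expect_error(solve_lambda(0.5), "at least two")
  expect_error(solve_lambda(c(0.5, 1.2)), "strictly in")
})

test_that("subset_measure honours the boundary conditions and fold rule", {
  g <- c(0.25, 0.35, 0.40)
  lam <- solve_lambda(g) # 0: sums to 1
  expect_equal(subset_measure(integer(0), g, lam), 0) # empty set
  expect_equal(subset_measure(1:3, g, lam), 1, tolerance = 1e-9) # full set
  expect_equal(subset_measure(c(1, 2), g, lam), 0.60, tolerance = 1e-12)
  expect_equal(subset_measure(2, g, lam), 0.35)
  # general lambda: full set still 1, pairwise rule explicit
  g2 <- c(0.2, 0.3, 0.4)
  l2 <- solve_lambda(g2)
  expect_equal(subset_measure(1:3, g2, l2), 1, tolerance = 1e-9)
  expect_equal(subset_measure(c(1, 3), g2, l2),
               0.2 + 0.4 + l2 * 0.2 * 0.4, tolerance = 1e-12)
  expect_error(subset_measure("C9", c(A = 0.5, B = 0.4), 0), "unknown")
})

test_that("the measure is monotone over the full 3-classifier lattice", {
  set.seed(77)
  for (rep in 1:20) {
    g <- runif(3, 0.05, 0.7)
    lam <- solve_lambda(g)
    subsets <- lapply(0:7, function(m) which(bitwAnd(m, c(1L, 2L, 4L)) > 0))
    mu <- sapply(subsets, subset_measure, densities = g, lam = lam)
    for (a in 1:8) {
      for (b in 1:8) {
        if (all(subsets[[a]] %in% subsets[[b]])) {
          expect_lte(mu[a], mu[b] + 1e-12)
        }
      }
    }
  }
})

test_that("choquet_integral telescopes correctly and stays bounded", {
  fm <- fuzzy_measure(c(0.3, 0.3, 0.4) * 2) # normalizes to (0.3, 0.3, 0.4)
  expect_equal(fm$lam, 0)
  # all-equal scores: integral = the score (measure of full set is 1)
  expect_equal(choquet_integral(c(0.7, 0.7, 0.7), fm), 0.7, tolerance = 1e-12)
  # additive case equals the density-weighted mean
  expect_equal(choquet_integral(c(0.2, 0.5, 0.9), fm),
               sum(c(0.2, 0.5, 0.9) * c(0.3, 0.3, 0.4)), tolerance = 1e-12)
  expect_equal(choquet_integral(c(0.2, 0.5, 0.9), fm), 0.57, tolerance = 1e-12)
  expect_error(choquet_integral(c(0.9, 0.2, 0.5), fm), "sorted")
  # boundedness and agreement with the direct-expansion oracle
  set.seed(55)
  for (i in 1:1000) {
    acc <- runif(3, 0.3, 1)
    fmr <- fuzzy_measure(acc, normalize = (i %% 2 == 0))
    s <- runif(3)
    ord <- order(s, 1:3)
    v <- choquet_integral(s[ord], fmr, order = ord)
    expect_gte(v, min(s) - 1e-12)
    expect_lte(v, max(s) + 1e-12)
    expect_equal(v, oracle_choquet(s, fmr$densities, fmr$lam), tolerance = 1e-12)
  }
})

test_that("ensemble_predict fuses per sample and per class", {
  set.seed(10)
  n <- 25
  p1 <- runif(n)
  M <- cbind(1 - p1, p1)
  rownames(M) <- sprintf("S%03d", 1:n)
  fm <- fuzzy_measure(c(LR = 0.8, SVM = 0.7, RF = 0.9))
  # unanimous classifiers: fused equals the individual classifier
  fused <- ensemble_predict(list(LR = M, SVM = M, RF = M), fm)
  expect_equal(fused$fused_p1, p1, tolerance = 1e-10)
  expect_equal(fused$label, as.integer(p1 > 0.5))
  # additive (lambda = 0) case: accuracy-weighted mean of confidences
  mats <- lapply(1:3, function(j) {
    q <- runif(n)
    cbind(1 - q, q)
  })
  names(mats) <- c("LR", "SVM", "RF")
  g <- fm$densities
  fused2 <- ensemble_predict(mats, fm)
  wmean <- g[1] * mats$LR[, 2] + g[2] * mats$SVM[, 2] + g[3] * mats$RF[, 2]
  # per-class fusion then renormalization: p1 / (p0 + p1) with p0 + p1 = 1
  expect_equal(fused2$fused_p1, unname(wmean), tolerance = 1e-10)
  # swapping classifier ids together with their scores changes nothing
  fm_sw <- fuzzy_measure(c(SVM = 0.7, LR = 0.8, RF = 0.9))
  fused3 <- ensemble_predict(mats[c("SVM", "LR", "RF")], fm_sw)
  expect_equal(fused3$fused_p1, fused2$fused_p1, tolerance = 1e-12)
  expect_error(ensemble_predict(mats[1:2], fm), "missing classifier")
})

test_that("raising one classifier's class confidence never lowers the fusion", {
  set.seed(70)
  for (rep in 1:50) {
    acc <- runif(3, 0.4, 1)
    fm <- fuzzy_measure(acc, normalize = (rep %% 2 == 0))
    s <- runif(3)
    j <- sample(1:3, 1)
    s2 <- s
    s2[j] <- min(1, s2[j] + runif(1, 0, 0.3))
    ch <- function(v) {
      ord <- order(v, 1:3)
      choquet_integral(v[ord], fm, order = ord)
    }
    expect_gte(ch(s2), ch(s) - 1e-12)
  }
})

test_that("score fixtures behave at the agreement extremes", {
  fx1 <- generate_score_fixture(200, 3, agreement_level = 1, seed = 3)
  M <- fx1$scores$scores
  expect_equal(M[[1]], M[[2]], ignore_attr = TRUE)
  expect_equal(rowSums(M[[1]]), rep(1, 200), ignore_attr = TRUE)
  fm <- fuzzy_measure(c(C1 = 0.85, C2 = 0.85, C3 = 0.85))
  fused <- ensemble_predict(fx1$scores, fm)
  expect_equal(fused$fused_p1, unname(M[[1]][, 2]), tolerance = 1e-10)

  # independent errors: fusion beats the best individual classifier
  fx0 <- generate_score_fixture(2000, 3, agreement_level = 0, seed = 8)
  ind_acc <- sapply(fx0$scores$scores, function(S) {
    mean(as.integer(S[, 2] > 0.5) == fx0$labels)
  })
  fused0 <- ensemble_predict(fx0$scores, fuzzy_measure(ind_acc))
  fused_acc <- mean(fused0$label == fx0$labels)
  expect_gte(fused_acc, max(ind_acc) - 0.02)
})

test_that("score tables round-trip through TSV", {
  fx <- generate_score_fixture(12, 3, 0.5, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scores_tsv(fx$scores, f)
  back <- read_scores_tsv(f)
  expect_equal(back$scores$C2, fx$scores$scores$C2, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(rownames(back$scores$C2), rownames(fx$scores$scores$C2))
})
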