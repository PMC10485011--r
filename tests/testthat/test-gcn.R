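# Build a tiny sample_graph by hand from an explicit adjacency and feature
# matrix (bypassing the correlation threshold machinery).
manual_graph <- function(A, X, add_self_loops = TRUE) {
  structure(
    list(
      node_ids = rownames(X) %||% as.character(seq_len(nrow(X))),
      A = A, degree = rowSums(A),
      A_norm = normalize_adjacency(A, add_self_loops),
      X = X, threshold = NA_real_, R = NULL
    ),
    class = "sample_graph"
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("gcn_forward matches hand matrix-product arithmetic", {
  # one isolated node, identity weights, rectifier: propagation is identity
  g1 <- manual_graph(matrix(0, 1, 1), matrix(c(2, 3), 1, 2))
  m1 <- gcn_init(2, gcn_config(hidden_sizes = 2L, seed = 1))
  m1$weights[[1]] <- diag(2)
  out1 <- gcn_forward(g1, m1)
  expect_equal(out1$activations[[1]], matrix(c(2, 3), 1, 2), tolerance = 1e-12)

  # 2-node toy with one edge and self-loops: A_norm is all 1/2
  A <- matrix(c(0, 1, 1, 0), 2)
  X <- diag(2)
  g2 <- manual_graph(A, X)
  m2 <- gcn_init(2, gcn_config(hidden_sizes = 2L, seed = 1))
  W0 <- matrix(c(1, -2, 0.5, 3), 2, 2)
  W1 <- matrix(c(0.2, -1, 1.5, 0.4), 2, 2)
  m2$weights <- list(W0, W1)
  out2 <- gcn_forward(g2, m2)
  An <- matrix(0.5, 2, 2)
  H1 <- pmax(An %*% (X %*% W0), 0)
  Z2 <- An %*% (H1 %*% W1)
  P <- exp(Z2) / rowSums(exp(Z2))
  expect_equal(out2$activations[[1]], H1, tolerance = 1e-12)
  expect_equal(out2$probs, P, tolerance = 1e-12)
})

test_that("softmax rows sum to 1 and relu embeddings are nonnegative", {
  set.seed(99)
  X <- two_community_matrix(n_per = 6, p = 12)
  g <- sample_graph(X, threshold = 0.2)
  cfg <- gcn_config(hidden_sizes = c(7L, 5L), seed = 2)
  model <- gcn_init(ncol(X), cfg)
  out <- gcn_forward(g, model)
  expect_equal(unname(rowSums(out$probs)), rep(1, nrow(X)), tolerance = 1e-12)
  E <- extract_embeddings(g, model)
  expect_equal(dim(E), c(nrow(X), 5L)) # width = last hidden size
  expect_true(all(E >= 0))
  expect_identical(rownames(E), rownames(X))
})

test_that("gcn_loss reproduces closed forms and a summation oracle", {
  y <- c(1, 0, 1, 1)
  expect_lt(gcn_loss(y, y), 1e-10) # perfect predictions
  expect_equal(gcn_loss(y, rep(0.5, 4)), log(2), tolerance = 1e-12)
  set.seed(4)
  p <- runif(6, 0.05, 0.95)
  yy <- rbinom(6, 1, 0.5)
  oracle <- -mean(yy * log(p) + (1 - yy) * log(1 - p))
  expect_equal(gcn_loss(yy, p), oracle, tolerance = 1e-10)
  # l2 term
  m <- gcn_init(3, gcn_config(hidden_sizes = 2L, seed = 1))
  pen <- 0.01 / 2 * sum(sapply(m$weights, function(w) sum(w^2)))
  expect_equal(gcn_loss(yy, p, m, 0.01), oracle + pen, tolerance = 1e-10)
  expect_error(gcn_loss(numeric(0), numeric(0)), "empty")
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(31)
  X <- matrix(rnorm(15), 5, 3)
  A <- matrix(0, 5, 5)
  A[1, 2] <- A[2, 3] <- A[3, 4] <- A[4, 5] <- A[1, 5] <- 1
  A <- 1 * ((A + t(A)) > 0)
  g <- manual_graph(A, X)
  cfg <- gcn_config(hidden_sizes = c(4L, 3L), l2_coeff = 1e-3, seed = 6)
  model <- gcn_init(3, cfg)
  y <- c(1, 0, 1, 0, 1)
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  P <- as.matrix(g$A_norm)
  res <- choqfuzgcn:::gcn_gradients(P, X, model, y, mask, cfg$l2_coeff)
  h <- 1e-5
  for (k in seq_along(model$weights)) {
    num <- model$weights[[k]] * 0
    for (idx in seq_along(num)) {
      mp <- model; mp$weights[[k]][idx] <- mp$weights[[k]][idx] + h
      mm <- model; mm$weights[[k]][idx] <- mm$weights[[k]][idx] - h
      lp <- choqfuzgcn:::gcn_gradients(P, X, mp, y, mask, cfg$l2_coeff)$loss
      lm <- choqfuzgcn:::gcn_gradients(P, X, mm, y, mask, cfg$l2_coeff)$loss
      num[idx] <- (lp - lm) / (2 * h)
    }
    rel <- abs(res$grads[[k]] - num) / pmax(abs(num), 1e-6)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("training reduces loss on separable data and is deterministic", {
  for (seed in 1:5) {
    X <- two_community_matrix(n_per = 8, p = 10, strength = 2, seed = seed)
    g <- sample_graph(X, threshold = 0.2)
    y <- rep(c(1, 0), each = 8)
    cfg <- gcn_config(hidden_sizes = c(8L, 4L), epochs = 30L, seed = seed)
    model <- train_gcn(g, y, seq_len(16), cfg)
    expect_true(all(is.finite(model$loss_trace)))
    expect_lt(model$loss_trace[30], model$loss_trace[1])
  }
  # epochs = 0 returns the initialized model unchanged
  X <- two_community_matrix(n_per = 4, p = 6)
  g <- sample_graph(X, threshold = 0.2)
  cfg0 <- gcn_config(hidden_sizes = 3L, epochs = 0L, seed = 3)
  m0 <- train_gcn(g, rep(c(1, 0), each = 4), 1:8, cfg0)
  expect_identical(m0$weights, gcn_init(6, cfg0)$weights)
  # same seed twice: bitwise-identical weights
  cfg1 <- gcn_config(hidden_sizes = 3L, epochs = 15L, seed = 9)
  w1 <- train_gcn(g, rep(c(1, 0), each = 4), 1:8, cfg1)$weights
  w2 <- train_gcn(g, rep(c(1, 0), each = 4), 1:8, cfg1)$weights
  expect_identical(w1, w2)
})

test_that("compiled and reference training engines agree", {
  X <- two_community_matrix(n_per = 8, p = 10, seed = 41)
  g <- sample_graph(X, threshold = 0.2)
  y <- rep(c(1, 0), each = 8)
  cfg <- gcn_config(hidden_sizes = c(6L, 4L), epochs = 25L, seed = 13)
  mc <- train_gcn(g, y, 1:12, cfg, engine = "cpp")
  mr <- train_gcn(g, y, 1:12, cfg, engine = "r")
  for (k in seq_along(mc$weights)) {
    expect_equal(mc$weights[[k]], mr$weights[[k]], tolerance = 1e-10)
  }
  expect_equal(mc$loss_trace, mr$loss_trace, tolerance = 1e-10)
})

test_that("test-node labels never influence training (mask hygiene)", {
  X <- two_community_matrix(n_per = 8, p = 10, seed = 17)
  g <- sample_graph(X, threshold = 0.2)
  y <- rep(c(1, 0), each = 8)
  mask <- c(1:6, 9:14) # nodes 7, 8, 15, 16 unlabeled
  cfg <- gcn_config(hidden_sizes = c(6L, 3L), epochs = 20L, seed = 12)
  y_perm <- y
  y_perm[c(7, 8, 15, 16)] <- sample(y[c(7, 8, 15, 16)], 4)
  y_perm[c(7, 15)] <- 1 - y_perm[c(7, 15)]
  expect_identical(
    train_gcn(g, y, mask, cfg)$weights,
    train_gcn(g, y_perm, mask, cfg)$weights
  )
})

test_that("stronger l2 shrinks trained weight norms (3-point ladder)", {
  X <- two_community_matrix(n_per = 6, p = 8, seed = 23)
  g <- sample_graph(X, threshold = 0.2)
  y <- rep(c(1, 0), each = 6)
  norms <- sapply(c(1e-4, 1e-1, 10), function(l2) {
    cfg <- gcn_config(hidden_sizes = c(6L, 3L), epochs = 60L, l2_coeff = l2, seed = 2)
    m <- train_gcn(g, y, 1:12, cfg)
    sqrt(sum(sapply(m$weights, function(w) sum(w^2))))
  })
  expect_true(all(diff(norms) <= 0))
})

test_that("embeddings separate the two communities", {
  X <- two_community_matrix(n_per = 10, p = 15, strength = 2, seed = 29)
  g <- sample_graph(X, threshold = 0.2)
  y <- rep(c(1, 0), each = 10)
  cfg <- gcn_config(hidden_sizes = c(8L, 4L), epochs = 80L, seed = 4)
  model <- train_gcn(g, y, seq_len(20), cfg)
  E <- extract_embeddings(g, model)
  cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2) + 1e-12)
  within <- c()
  between <- c()
  for (i in 1:19) {
    for (j in (i + 1):20) {
      v <- cs(E[i, ], E[j, ])
      if (y[i] == y[j]) within <- c(within, v) else between <- c(between, v)
    }
  }
  expect_gt(mean(within), mean(between))
})

test_that("training errors are informative", {
  X <- two_community_matrix(n_per = 3, p = 5)
  g <- sample_graph(X, threshold = 0.2)
  expect_error(train_gcn(g, rep(0, 6), integer(0), gcn_config(hidden_sizes = 2L)),
               "empty training mask")
})
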