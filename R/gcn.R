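#' Graph convolutional network configuration
#'
#' Defaults follow the architecture used for survival-prognosis embedding:
#' three hidden layers of 200, 150 and 100 rectifier units, a 2-class
#' softmax head, 200 full-batch epochs of Adam at learning rate 0.001, and
#' an L2 weight penalty whose coefficient enters the loss as
#' `(l2_coeff / 2) * sum(W^2)`.
#'
#' @param hidden_sizes integer vector of hidden layer widths.
#' @param epochs number of training epochs.
#' @param learning_rate Adam step size.
#' @param l2_coeff L2 regularization coefficient (this is the loss-function
#'   lambda, unrelated to the fuzzy-measure lambda).
#' @param seed integer seed for weight initialization.
#' @param activation hidden nonlinearity, `"relu"` or `"tanh"`.
#' @return an object of class `gcn_config`.
#' @export
gcn_config <- function(hidden_sizes = c(200L, 150L, 100L), epochs = 200L,
                       learning_rate = 0.001, l2_coeff = 5e-4, seed = 1L,
                       activation = c("relu", "tanh")) {
  activation <- match.arg(activation)
  stopifnot(
    length(hidden_sizes) >= 1, all(hidden_sizes >= 1),
    epochs >= 0, learning_rate > 0, l2_coeff >= 0
  )
  structure(
    list(
      hidden_sizes = as.integer(hidden_sizes), epochs = as.integer(epochs),
      learning_rate = learning_rate, l2_coeff = l2_coeff,
      seed = as.integer(seed), activation = activation
    ),
    class = "gcn_config"
  )
}

activation_fun <- function(name) {
  switch(name,
    relu = list(f = function(z) z * (z > 0), df = function(z) (z > 0) * 1),
    tanh = list(f = tanh, df = function(z) 1 - tanh(z)^2)
  )
}

#' Initialize a GCN model
#'
#' Glorot-uniform weights, seeded. Layer widths chain from `n_features`
#' through `config$hidden_sizes` to the 2-class softmax output.
#'
#' @param n_features width of the node feature matrix.
#' @param config a [gcn_config()].
#' @return an object of class `gcn_model`.
#' @export
gcn_init <- function(n_features, config) {
  stopifnot(inherits(config, "gcn_config"))
  dims <- c(n_features, config$hidden_sizes, 2L)
  weights <- with_seed(config$seed, {
    lapply(seq_len(length(dims) - 1L), function(k) {
      fan_in <- dims[k]
      fan_out <- dims[k + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))
      matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
    })
  })
  structure(list(weights = weights, config = config), class = "gcn_model")
}

row_softmax <- function(Z) {
  E <- exp(Z - apply(Z, 1, max))
  E / rowSums(E)
}

#' GCN forward pass
#'
#' Propagates node features through `L[k+1] = sigma(A_norm L[k] W[k])` for
#' each hidden layer and applies a row-wise softmax after the final graph
#' convolution. Layer 0 is the node feature matrix of the graph.
#'
#' @param graph a [sample_graph()].
#' @param model a [gcn_model][gcn_init()].
#' @return list with `activations` (per hidden layer), `logits` and `probs`
#'   (rows sum to 1); `probs[, 2]` is the class-1 probability.
#' @export
gcn_forward <- function(graph, model) {
  fwd <- gcn_forward_cache(graph$A_norm, graph$X, model)
  list(activations = fwd$H, logits = fwd$Z[[length(fwd$Z)]], probs = fwd$probs)
}

# Forward pass keeping pre-activations for backprop. P may be a sparse
# Matrix or base dense matrix.
gcn_forward_cache <- function(P, X, model) {
  act <- activation_fun(model$config$activation)
  W <- model$weights
  K <- length(W)
  if (ncol(X) != nrow(W[[1]])) stop("feature width does not match the model")
  Z <- vector("list", K)
  H <- vector("list", K - 1L)
  Hprev <- X
  for (k in seq_len(K - 1L)) {
    Z[[k]] <- as.matrix(P %*% (Hprev %*% W[[k]]))
    H[[k]] <- act$f(Z[[k]])
    Hprev <- H[[k]]
  }
  Z[[K]] <- as.matrix(P %*% (Hprev %*% W[[K]]))
  list(Z = Z, H = H, probs = row_softmax(Z[[K]]))
}

#' Masked cross-entropy loss with L2 penalty
#'
#' Mean binary cross-entropy over the labeled (training-mask) nodes plus
#' `(l2_coeff / 2) * sum(W^2)` over every weight matrix. Probabilities are
#' clipped to `[1e-12, 1 - 1e-12]` before taking logs.
#'
#' @param y_true 0/1 labels for the masked nodes.
#' @param y_prob predicted class-1 probabilities for the masked nodes.
#' @param model a [gcn_model][gcn_init()] supplying the weights (or `NULL`
#'   for no penalty term).
#' @param l2_coeff L2 coefficient.
#' @return scalar loss.
#' @export
gcn_loss <- function(y_true, y_prob, model = NULL, l2_coeff = 0) {
  if (!length(y_true)) stop("empty training mask")
  stopifnot(length(y_true) == length(y_prob))
  p <- pmin(pmax(y_prob, 1e-12), 1 - 1e-12)
  y <- as.numeric(y_true)
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  pen <- if (!is.null(model) && l2_coeff > 0) {
    l2_coeff / 2 * sum(vapply(model$weights, function(w) sum(w^2), numeric(1)))
  } else 0
  bce + pen
}

# Analytic gradients of the masked loss w.r.t. every weight matrix.
# Returns list(grads, loss, probs).
gcn_gradients <- function(P, X, model, y, mask, l2_coeff) {
  act <- activation_fun(model$config$activation)
  W <- model$weights
  K <- length(W)
  fwd <- gcn_forward_cache(P, X, model)
  p1 <- fwd$probs[, 2]
  n_lab <- sum(mask)
  loss <- gcn_loss(y[mask], p1[mask], model, l2_coeff)
  # softmax + cross-entropy on class-1 probability: d loss / d logits
  dZ <- matrix(0, nrow(fwd$probs), 2)
  resid <- (p1[mask] - y[mask]) / n_lab
  dZ[mask, 1] <- -resid
  dZ[mask, 2] <- resid
  grads <- vector("list", K)
  for (k in K:1) {
    Hprev <- if (k == 1L) X else fwd$H[[k - 1L]]
    dM <- as.matrix(P %*% dZ) # P is symmetric
    grads[[k]] <- crossprod(Hprev, dM) + l2_coeff * W[[k]]
    if (k > 1L) {
      dH <- dM %*% t(W[[k]])
      dZ <- dH * act$df(fwd$Z[[k - 1L]])
    }
  }
  list(grads = grads, loss = loss, probs = fwd$probs)
}

#' Train a GCN with Adam on masked cross-entropy
#'
#' Full-batch, transductive training: every node participates in message
#' passing, but the loss (and therefore every gradient) only sees labels of
#' nodes in `train_mask`. Deterministic given the config seed: fixed Glorot
#' initialization and a fixed update order, no stochastic regularization.
#'
#' @param graph a [sample_graph()].
#' @param labels 0/1 vector over all nodes (entries outside the mask are
#'   never read).
#' @param train_mask logical vector or integer indices of labeled nodes.
#' @param config a [gcn_config()].
#' @param engine `"cpp"` (compiled Adam loop, the default) or `"r"` (the
#'   plain-R reference implementation the compiled path is tested against).
#'   Both engines only support the rectifier activation through the same
#'   formulas; results agree to floating-point reordering.
#' @return a trained `gcn_model` with a `loss_trace` field (loss evaluated
#'   at the start of each epoch).
#' @export
train_gcn <- function(graph, labels, train_mask, config = gcn_config(),
                      engine = c("cpp", "r")) {
  stopifnot(inherits(graph, "sample_graph"), inherits(config, "gcn_config"))
  engine <- match.arg(engine)
  n <- nrow(graph$X)
  mask <- logical(n)
  mask[train_mask] <- TRUE
  if (!any(mask)) stop("empty training mask")
  y <- as.numeric(labels)
  stopifnot(length(y) == n)
  model <- gcn_init(ncol(graph$X), config)
  if (engine == "cpp" && config$activation == "relu") {
    P <- methods::as(methods::as(graph$A_norm, "generalMatrix"), "CsparseMatrix")
    fit <- gcn_train_cpp(P, graph$X, model$weights, y,
                         which(mask) - 1L, config$epochs,
                         config$learning_rate, config$l2_coeff)
    model$weights <- lapply(fit$weights, unname)
    model$loss_trace <- as.numeric(fit$trace)
    return(model)
  }
  # --- reference R implementation ---
  # dense propagation is faster than sparse once the graph is dense enough
  P <- graph$A_norm
  if (Matrix::nnzero(P) / (n * n) > 0.25) P <- as.matrix(P)
  K <- length(model$weights)
  m_t <- lapply(model$weights, function(w) w * 0)
  v_t <- lapply(model$weights, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    g <- gcn_gradients(P, graph$X, model, y, mask, config$l2_coeff)
    if (!is.finite(g$loss)) {
      stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
    }
    trace[epoch] <- g$loss
    for (k in seq_len(K)) {
      m_t[[k]] <- b1 * m_t[[k]] + (1 - b1) * g$grads[[k]]
      v_t[[k]] <- b2 * v_t[[k]] + (1 - b2) * g$grads[[k]]^2
      mhat <- m_t[[k]] / (1 - b1^epoch)
      vhat <- v_t[[k]] / (1 - b2^epoch)
      model$weights[[k]] <- model$weights[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  model$loss_trace <- trace
  model
}

#' Extract last-hidden-layer node embeddings
#'
#' Returns the activations of the last hidden layer (default width 100) for
#' every node, labeled and unlabeled alike; the softmax head is only the
#' training signal, the embedding is the feature representation passed on to
#' the downstream classifiers.
#'
#' @param graph a [sample_graph()].
#' @param model a trained [gcn_model][gcn_init()].
#' @return numeric matrix `n_samples x last_hidden_size` with sample-id
#'   rownames.
#' @export
extract_embeddings <- function(graph, model) {
  fwd <- gcn_forward(graph, model)
  E <- fwd$activations[[length(fwd$activations)]]
  rownames(E) <- graph$node_ids
  E
}
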