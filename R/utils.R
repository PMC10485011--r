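#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor rbinom rnorm runif sd predict glm binomial plogis
#' @importFrom utils read.delim write.table
#' @useDynLib choqfuzgcn, .registration = TRUE
## usethis namespace: end
NULL

# Evaluate `code` under a fixed RNG seed and restore the caller's RNG state.
# All stochastic operations in the package route through this so that pipeline
# runs are reproducible from a single integer seed.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and an index; kept strictly below
# 2^31 so it is always a valid R integer.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647L)
}

as_numeric_matrix <- function(X, what = "X") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop(sprintf("`%s` must be a numeric matrix", what), call. = FALSE)
  }
  X
}

# Stratified assignment of n samples with binary labels into k folds.
# Shuffles within each class, then deals round-robin so class balance is
# preserved as far as integer arithmetic allows.
stratified_folds <- function(y, k, seed) {
  y <- as.integer(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Stratified holdout: returns indices of the holdout subset.
stratified_holdout <- function(y, fraction, seed) {
  y <- as.integer(y)
  hold <- integer(0)
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      n_hold <- max(1L, round(fraction * length(idx)))
      hold <- c(hold, idx[sample.int(length(idx), n_hold)])
    }
  })
  sort(hold)
}
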