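# Small in-code fixtures shared across test files.

# Two-community feature matrix: samples in the same block share a latent
# factor with feature-varying loadings (a constant per-row shift would be
# removed by the row centering inside Pearson correlation), so within-block
# sample-sample correlations are high and between-block ones negative.
two_community_matrix <- function(n_per = 10, p = 30, strength = 2, seed = 42) {
  set.seed(seed)
  z <- c(rep(strength, n_per), rep(-strength, n_per))
  w <- rnorm(p)
  X <- z %o% w + matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  rownames(X) <- sprintf("S%03d", seq_len(2 * n_per))
  X
}

# Tiny labeled 2-D blobs, linearly separable at the given gap.
blob_data <- function(n_per = 40, gap = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(2 * n_per), n_per, 2),
    matrix(rnorm(2 * n_per) + gap, n_per, 2)
  )
  list(X = X, y = rep(c(0L, 1L), each = n_per))
}

# Small cohort + fast pipeline config for orchestration tests.
small_cohort <- function(seed = 5, n = 120) {
  generate_cohort(cohort_spec(
    n_samples = n, n_ge = 40, n_cna = 30, n_cln = 8,
    effect_size = 3, seed = seed
  ))
}

fast_config <- function(seed = 5, n_folds = 3) {
  pipeline_config(
    n_folds = n_folds,
    gcn = gcn_config(hidden_sizes = c(16L, 8L), epochs = 40L),
    mrmr_n = c(GE = 20L, CNA = 15L),
    rf_ntree = 30L,
    seed = seed
  )
}

cohort_inputs <- function(co) list(GE = co$ge, CNA = co$cna, CLN = co$cln)

# Seeded evaluation that restores the caller's RNG state.
with_seed_local <- function(seed, code) choqfuzgcn:::with_seed(seed, code)
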