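#' Fuzzy densities from classifier validation scores
#'
#' The density of classifier j (the measure of the singleton set) is its
#' validation score divided by the sum of all scores, so densities sum to 1.
#' With `normalize = FALSE` the raw scores themselves are used as densities
#' (they must then lie in (0, 1]); this exposes the general
#' lambda-interaction regime, since normalized densities always force
#' lambda = 0 (see [solve_lambda()]).
#'
#' @param validation_scores positive scores, e.g. validation accuracies.
#' @param normalize divide by the sum (default TRUE).
#' @return numeric vector of densities in (0, 1].
#' @export
fuzzy_densities <- function(validation_scores, normalize = TRUE) {
  s <- as.numeric(validation_scores)
  if (any(!is.finite(s)) || any(s <= 0)) stop("validation scores must be positive")
  g <- if (normalize) s / sum(s) else s
  if (any(g > 1)) stop("densities must lie in (0, 1]; unnormalized scores > 1")
  names(g) <- names(validation_scores)
  g
}

# Defining polynomial of the lambda-measure interaction parameter:
# f(lam) = prod(1 + lam * g) - 1 - lam, whose nonzero root in (-1, Inf)
# makes the measure of the full set exactly 1.
lambda_residual <- function(lam, densities) {
  prod(1 + lam * densities) - 1 - lam
}

#' Solve for the lambda-measure interaction parameter
#'
#' Finds the root of `1 + lambda = prod(g_j * lambda + 1)` in
#' `(-1, Inf)`. `lambda = 0` is always a root; it is the relevant one
#' exactly when the densities sum to 1 (the measure is then additive).
#' Otherwise the unique nonzero root is bracketed (in `(0, Inf)` when
#' `sum(g) < 1`, in `(-1, 0)` when `sum(g) > 1`) and polished by bisection
#' until the residual is at most `1e-12`.
#'
#' @param densities fuzzy densities in (0, 1), at least two classifiers.
#' @param sum_tol tolerance on `|sum(g) - 1|` below which the additive case
#'   (lambda = 0) is returned.
#' @return the interaction parameter lambda.
#' @export
solve_lambda <- function(densities, sum_tol = 1e-12) {
  g <- as.numeric(densities)
  if (length(g) < 2L) stop("need at least two densities")
  if (any(g <= 0) || any(g >= 1)) stop("densities must lie strictly in (0, 1)")
  s <- sum(g)
  if (abs(s - 1) <= sum_tol) return(0)
  # lambda = 0 is always a root of the defining polynomial, so the brackets
  # below use the known sign pattern of f on each side of the nonzero root
  # rather than the (zero) endpoint values: for sum(g) < 1, f < 0 on
  # (0, root) and f > 0 beyond; for sum(g) > 1, f > 0 on (-1, root) and
  # f < 0 on (root, 0).
  if (s < 1) {
    lo <- 0; hi <- 1
    while (lambda_residual(hi, g) < 0) hi <- hi * 2
    if (!is.finite(hi)) stop("no admissible root found for lambda > 0")
  } else {
    lo <- -1 + 1e-15; hi <- 0
  }
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    f_mid <- lambda_residual(mid, g)
    below_root <- if (s < 1) f_mid < 0 else f_mid > 0
    if (below_root) lo <- mid else hi <- mid
    if (abs(hi - lo) < 1e-16 * max(1, abs(lo))) break
  }
  root <- (lo + hi) / 2
  if (abs(lambda_residual(root, g)) > 1e-12) {
    stop(sprintf(
      "lambda root residual %.3g exceeds 1e-12 (densities sum %.6f)",
      lambda_residual(root, g), s
    ))
  }
  root
}

#' Lambda-fuzzy measure of a classifier subset
#'
#' The empty set has measure 0 and singletons their density; larger subsets
#' fold the pairwise rule
#' `fuzz(X u Y) = fuzz(X) + fuzz(Y) + lambda * fuzz(X) * fuzz(Y)`,
#' which is associative and order-independent for lambda-measures. The full
#' set has measure 1 (up to root-finding precision) by construction of
#' lambda.
#'
#' @param subset integer indices (or names) of the classifiers in the
#'   subset.
#' @param densities fuzzy densities of all classifiers.
#' @param lam interaction parameter from [solve_lambda()].
#' @return the measure, a value in \[0, 1\].
#' @export
subset_measure <- function(subset, densities, lam) {
  if (is.character(subset)) {
    idx <- match(subset, names(densities))
    if (anyNA(idx)) stop("unknown classifier id(s): ",
                         paste(subset[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(subset)
    if (length(idx) && (min(idx) < 1L || max(idx) > length(densities))) {
      stop("classifier index out of range")
    }
  }
  if (anyDuplicated(idx)) stop("duplicated classifier in subset")
  mu <- 0
  for (g in densities[idx]) mu <- mu + g + lam * mu * g
  min(max(mu, 0), 1 + 1e-9)
}

#' Build a lambda-fuzzy measure from validation scores
#'
#' Bundles [fuzzy_densities()] and [solve_lambda()] and precomputes the
#' measure of every classifier subset (there are only `2^m`).
#'
#' @param validation_scores positive per-classifier scores.
#' @param classifier_ids identifiers (defaults to names or C1..Cm).
#' @param normalize normalize scores to densities summing to 1 (the
#'   convention that makes the measure additive); see [fuzzy_densities()].
#' @return object of class `fuzzy_measure` with fields `classifier_ids`,
#'   `densities`, `lam`, and `measure_table` indexed by subset bitmask + 1.
#' @export
fuzzy_measure <- function(validation_scores, classifier_ids = NULL,
                          normalize = TRUE) {
  m <- length(validation_scores)
  if (is.null(classifier_ids)) {
    classifier_ids <- names(validation_scores)
    if (is.null(classifier_ids)) classifier_ids <- paste0("C", seq_len(m))
  }
  g <- fuzzy_densities(validation_scores, normalize = normalize)
  names(g) <- classifier_ids
  lam <- solve_lambda(g)
  tab <- numeric(2^m)
  for (mask in seq_len(2^m) - 1L) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0L)
    tab[mask + 1L] <- subset_measure(idx, g, lam)
  }
  structure(
    list(classifier_ids = classifier_ids, densities = g, lam = lam,
         measure_table = tab),
    class = "fuzzy_measure"
  )
}

#' @export
print.fuzzy_measure <- function(x, ...) {
  cat(sprintf(
    "<fuzzy_measure> %d classifiers, lambda = %.6g\n densities: %s\n",
    length(x$densities), x$lam,
    paste(sprintf("%s=%.4f", x$classifier_ids, x$densities), collapse = ", ")
  ))
  invisible(x)
}

# Measure of a subset given as integer indices, via the precomputed table.
measure_of <- function(fm, idx) {
  fm$measure_table[sum(bitwShiftL(1L, idx - 1L)) + 1L]
}

#' Choquet integral of sorted scores
#'
#' For scores `s_1 <= ... <= s_m` (the caller sorts; an unsorted input is a
#' contract violation) the integral is
#' `sum_i (s_i - s_{i-1}) * fuzz(A_i)` with `s_0 = 0` and `A_i` the suffix
#' set of classifiers with the i-th smallest score onwards. The result
#' always lies between the smallest and largest score because
#' `fuzz(A_1) = 1` and the measure is monotone.
#'
#' @param sorted_scores ascending numeric scores.
#' @param fm a [fuzzy_measure()].
#' @param order integer permutation mapping sort position to classifier
#'   index (defaults to identity, i.e. scores already given per classifier
#'   in ascending order).
#' @return scalar fused score.
#' @export
choquet_integral <- function(sorted_scores, fm, order = seq_along(sorted_scores)) {
  s <- as.numeric(sorted_scores)
  m <- length(s)
  if (m != length(fm$densities)) stop("score/classifier count mismatch")
  if (is.unsorted(s)) stop("scores must be sorted ascending (caller sorts)")
  total <- 0
  prev <- 0
  for (i in seq_len(m)) {
    mu <- measure_of(fm, order[i:m])
    total <- total + (s[i] - prev) * mu
    prev <- s[i]
  }
  total
}

#' Choquet fusion of per-classifier class confidences
#'
#' For every sample and each of the two classes, the m classifiers'
#' confidences are sorted ascending (ties broken by classifier index) and
#' aggregated with [choquet_integral()] under the suffix-set measure. The
#' two fused class scores are renormalized to sum to 1 and the hard label
#' is 1 when the fused class-1 probability exceeds `threshold`.
#'
#' @param scores a `score_matrix` (see [score_matrix()]) or a named list of
#'   per-classifier `n x 2` probability matrices.
#' @param fm a [fuzzy_measure()] over the same classifiers.
#' @param threshold decision threshold on the fused class-1 probability
#'   (0.5, the standard binary cutoff).
#' @return data.frame with `sample_id`, `fused_p0`, `fused_p1` (normalized),
#'   `label`.
#' @export
ensemble_predict <- function(scores, fm, threshold = 0.5) {
  mats <- if (inherits(scores, "score_matrix")) scores$scores else scores
  ids <- fm$classifier_ids
  if (!all(ids %in% names(mats))) {
    stop("missing classifier score matrix: ",
         paste(setdiff(ids, names(mats)), collapse = ", "))
  }
  mats <- mats[ids]
  n <- nrow(mats[[1]])
  stopifnot(all(vapply(mats, nrow, 1L) == n), all(vapply(mats, ncol, 1L) == 2L))
  m <- length(mats)
  fused <- matrix(0, n, 2)
  for (cls in 1:2) {
    S <- vapply(mats, function(M) M[, cls], numeric(n))
    if (n == 1L) S <- matrix(S, nrow = 1L)
    for (i in seq_len(n)) {
      ord <- order(S[i, ], seq_len(m)) # stable: ties by classifier index
      fused[i, cls] <- choquet_integral(S[i, ord], fm, order = ord)
    }
  }
  tot <- rowSums(fused)
  p1 <- ifelse(tot > 0, fused[, 2] / tot, 0.5)
  sample_ids <- rownames(mats[[1]])
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  data.frame(
    sample_id = sample_ids,
    fused_p0 = 1 - p1,
    fused_p1 = p1,
    label = as.integer(p1 > threshold)
  )
}

#' Per-classifier confidence container
#'
#' Holds, for each classifier, an `n x 2` matrix of class confidences (rows
#' sum to 1), plus the validation accuracies used to derive fuzzy densities.
#'
#' @param scores named list of `n x 2` probability matrices.
#' @param validation_accuracies named numeric vector, same classifiers.
#' @return object of class `score_matrix`.
#' @export
score_matrix <- function(scores, validation_accuracies = NULL) {
  stopifnot(is.list(scores), length(scores) >= 1, !is.null(names(scores)))
  n <- nrow(scores[[1]])
  for (M in scores) {
    stopifnot(is.matrix(M), nrow(M) == n, ncol(M) == 2L)
    if (any(M < 0 | M > 1)) stop("confidences must lie in [0, 1]")
    if (any(abs(rowSums(M) - 1) > 1e-6)) stop("class confidences must sum to 1 per sample")
  }
  structure(
    list(scores = scores, validation_accuracies = validation_accuracies),
    class = "score_matrix"
  )
}

#' Read per-classifier scores from long-format TSV
#'
#' Columns `sample_id`, `classifier_id`, `p_class0`, `p_class1`.
#' @param path file path.
#' @return a [score_matrix()].
#' @export
read_scores_tsv <- function(path) {
  df <- utils::read.delim(path)
  need <- c("sample_id", "classifier_id", "p_class0", "p_class1")
  if (!all(need %in% names(df))) stop("scores TSV needs columns: ", paste(need, collapse = ", "))
  ids <- unique(df$sample_id)
  mats <- lapply(split(df, df$classifier_id), function(d) {
    d <- d[match(ids, d$sample_id), ]
    M <- cbind(d$p_class0, d$p_class1)
    rownames(M) <- ids
    M
  })
  score_matrix(mats)
}

#' Write per-classifier scores as long-format TSV
#' @param scores a [score_matrix()].
#' @param path output file path.
#' @export
write_scores_tsv <- function(scores, path) {
  rows <- lapply(names(scores$scores), function(cid) {
    M <- scores$scores[[cid]]
    ids <- rownames(M)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(M)))
    data.frame(sample_id = ids, classifier_id = cid,
               p_class0 = M[, 1], p_class1 = M[, 2])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
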