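#' Synthetic multi-omics cohort specification
#'
#' The generator emulates the statistical structure the classifier relies
#' on: a latent per-sample factor with class-separated means induces both
#' feature-label signal and within-class sample-sample correlation (so that
#' thresholded correlation graphs acquire community structure), while the
#' modality alphabets match preprocessed cohort data — ternary gene
#' expression, five-level copy-number calls, unit-interval clinical
#' covariates. Defaults mirror a 1980-patient cohort with 491 short-term
#' survivors and the 400/200/25 GE/CNA/CLN feature widths.
#'
#' @param n_samples cohort size (default 1980).
#' @param minority_fraction short-term survivor prevalence
#'   (default 491/1980).
#' @param n_ge,n_cna,n_cln per-modality feature counts (defaults 400, 200,
#'   25).
#' @param informative_fraction fraction of label-informative features in
#'   each modality (default 0.2).
#' @param effect_size separation of the class-conditional latent means in
#'   latent-sd units (default 2).
#' @param within_class_corr target latent-driven correlation among
#'   informative GE features (sets the loading scale; default 0.5).
#' @param missing_rate fraction of GE/CNA cells set missing, to exercise
#'   imputation (default 0 = complete data).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 1980L, minority_fraction = 491 / 1980,
                        n_ge = 400L, n_cna = 200L, n_cln = 25L,
                        informative_fraction = 0.2, effect_size = 2,
                        within_class_corr = 0.5, missing_rate = 0,
                        seed = 1L) {
  stopifnot(
    n_samples >= 2, n_ge >= 1, n_cna >= 1, n_cln >= 1,
    minority_fraction > 0, minority_fraction < 1,
    informative_fraction > 0, informative_fraction < 1,
    effect_size >= 0, within_class_corr > 0, within_class_corr < 1,
    missing_rate >= 0, missing_rate < 1
  )
  structure(
    list(
      n_samples = as.integer(n_samples),
      minority_fraction = minority_fraction,
      n_ge = as.integer(n_ge), n_cna = as.integer(n_cna),
      n_cln = as.integer(n_cln),
      informative_fraction = informative_fraction,
      effect_size = effect_size, within_class_corr = within_class_corr,
      missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate a synthetic multi-omics cohort
#'
#' Labels are Bernoulli draws at the minority fraction. Each sample carries
#' a latent factor `z = c_y + h`, `h ~ N(0, 1)`, with class means
#' `c_y = +/- effect_size / 2`. Informative GE columns load on the latent
#' with sign-randomized loadings of magnitude
#' `sqrt(rho / (1 - rho))` (`rho` = `within_class_corr`) plus unit noise,
#' then the \{-1, 0, 1\} discretization at |z| > 1 is applied;
#' non-informative columns are pure noise. Informative CNA columns are
#' categorical over \{-2..2\} with class-tilted level probabilities;
#' informative clinical columns are class-shifted Gaussians min-max scaled
#' to \[0, 1\]. Fully reproducible from the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return list with `ge`, `cna`, `cln` ([omics_matrix()]), `labels`
#'   ([label_vector()]) and `truth` (data.frame of informative feature ids
#'   with their latent loadings/directions).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  lam <- sqrt(spec$within_class_corr / (1 - spec$within_class_corr))
  out <- with_seed(spec$seed, {
    y <- rbinom(n, 1L, spec$minority_fraction)
    z <- ifelse(y == 1L, spec$effect_size / 2, -spec$effect_size / 2) + rnorm(n)

    # --- gene expression: latent loadings + noise, then ternarized
    n_inf_ge <- max(1L, round(spec$informative_fraction * spec$n_ge))
    load_sign <- sample(c(-1, 1), n_inf_ge, replace = TRUE)
    ge_raw <- matrix(rnorm(n * spec$n_ge), n, spec$n_ge)
    ge_raw[, seq_len(n_inf_ge)] <- ge_raw[, seq_len(n_inf_ge)] +
      z %o% (lam * load_sign)
    ge <- discretize_expression(ge_raw, z_cut = 1)

    # --- copy number: categorical with class-tilted level probabilities
    n_inf_cna <- max(1L, round(spec$informative_fraction * spec$n_cna))
    base_p <- c(0.05, 0.2, 0.5, 0.2, 0.05) # levels -2..2
    levels <- -2:2
    cna_dir <- sample(c(-1, 1), n_inf_cna, replace = TRUE)
    cna <- matrix(0L, n, spec$n_cna)
    for (j in seq_len(spec$n_cna)) {
      if (j <= n_inf_cna) {
        tilt <- function(sgn) {
          p <- base_p * exp(0.25 * spec$effect_size * cna_dir[j] * levels * sgn)
          p / sum(p)
        }
        p1 <- tilt(1); p0 <- tilt(-1)
        cna[, j] <- ifelse(
          y == 1L,
          sample(levels, n, replace = TRUE, prob = p1),
          sample(levels, n, replace = TRUE, prob = p0)
        )
      } else {
        cna[, j] <- sample(levels, n, replace = TRUE, prob = base_p)
      }
    }

    # --- clinical: class-shifted and null gaussians, min-max scaled
    n_inf_cln <- max(1L, round(spec$informative_fraction * spec$n_cln))
    cln_dir <- sample(c(-1, 1), n_inf_cln, replace = TRUE)
    cln_raw <- matrix(rnorm(n * spec$n_cln), n, spec$n_cln)
    cln_raw[, seq_len(n_inf_cln)] <- cln_raw[, seq_len(n_inf_cln)] +
      ((y - 0.5) * spec$effect_size) %o% cln_dir
    cln <- minmax_normalize(cln_raw)

    if (spec$missing_rate > 0) {
      punch <- function(M) {
        holes <- which(runif(length(M)) < spec$missing_rate)
        # keep at least one observed value per row and per column
        M2 <- M
        M2[holes] <- NA
        bad_r <- rowSums(!is.na(M2)) == 0
        bad_c <- colSums(!is.na(M2)) == 0
        M2[bad_r, 1] <- M[bad_r, 1]
        M2[1, bad_c] <- M[1, bad_c]
        M2
      }
      ge <- punch(ge)
      cna <- punch(cna)
    }
    list(y = y, ge = ge, cna = cna, cln = cln,
         load_sign = load_sign, cna_dir = cna_dir, cln_dir = cln_dir,
         n_inf = c(GE = n_inf_ge, CNA = n_inf_cna, CLN = n_inf_cln))
  })

  dimnames(out$ge) <- list(ids, sprintf("GE_f%04d", seq_len(spec$n_ge)))
  dimnames(out$cna) <- list(ids, sprintf("CNA_f%04d", seq_len(spec$n_cna)))
  dimnames(out$cln) <- list(ids, sprintf("CLN_f%04d", seq_len(spec$n_cln)))
  truth <- rbind(
    data.frame(modality = "GE", feature_id = colnames(out$ge)[seq_len(out$n_inf["GE"])],
               direction = out$load_sign, loading = lam * out$load_sign),
    data.frame(modality = "CNA", feature_id = colnames(out$cna)[seq_len(out$n_inf["CNA"])],
               direction = out$cna_dir, loading = NA_real_),
    data.frame(modality = "CLN", feature_id = colnames(out$cln)[seq_len(out$n_inf["CLN"])],
               direction = out$cln_dir, loading = NA_real_)
  )
  miss <- spec$missing_rate > 0
  list(
    ge = omics_matrix(out$ge, "GE", allow_missing = miss),
    cna = omics_matrix(out$cna, "CNA", allow_missing = miss),
    cln = omics_matrix(out$cln, "CLN"),
    labels = label_vector(ids, out$y),
    truth = truth,
    spec = spec
  )
}

#' Write a generated cohort to TSV files
#'
#' Emits `ge.tsv`, `cna.tsv`, `cln.tsv`, `labels.tsv` and `truth.tsv` in
#' the dialects consumed by [read_omics_tsv()] / [read_labels_tsv()].
#'
#' @param cohort a [generate_cohort()] result.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_omics_tsv(cohort$ge, file.path(out_dir, "ge.tsv"))
  write_omics_tsv(cohort$cna, file.path(out_dir, "cna.tsv"))
  write_omics_tsv(cohort$cln, file.path(out_dir, "cln.tsv"))
  write_labels_tsv(cohort$labels, file.path(out_dir, "labels.tsv"))
  utils::write.table(cohort$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Synthetic per-classifier score fixture
#'
#' Draws per-sample class confidences for `m_classifiers` whose errors
#' correlate at the requested `agreement_level`: each classifier's decision
#' noise is a mixture `sqrt(a) * shared + sqrt(1 - a) * independent`. At
#' `a = 1` all classifiers are identical; at `a = 0` their errors are
#' independent and fusing them should beat any individual classifier.
#' Used to unit-test the fusion layer in isolation.
#'
#' @param n_samples number of samples.
#' @param m_classifiers number of classifiers.
#' @param agreement_level error correlation in \[0, 1\].
#' @param seed integer seed.
#' @param signal decision-signal strength (default 1.2, i.e. individual
#'   accuracy around 0.88).
#' @return list with `scores` (a [score_matrix()]) and `labels` (0/1).
#' @export
generate_score_fixture <- function(n_samples, m_classifiers = 3L,
                                   agreement_level = 0.5, seed = 1L,
                                   signal = 1.2) {
  stopifnot(agreement_level >= 0, agreement_level <= 1, m_classifiers >= 1)
  with_seed(seed, {
    y <- rbinom(n_samples, 1L, 0.5)
    shared <- rnorm(n_samples)
    mats <- lapply(seq_len(m_classifiers), function(j) {
      noise <- sqrt(agreement_level) * shared +
        sqrt(1 - agreement_level) * rnorm(n_samples)
      p1 <- plogis(signal * (2 * y - 1) + noise)
      matrix(c(1 - p1, p1), ncol = 2,
             dimnames = list(sprintf("S%04d", seq_len(n_samples)), NULL))
    })
    names(mats) <- paste0("C", seq_len(m_classifiers))
    list(scores = score_matrix(mats), labels = y)
  })
}
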