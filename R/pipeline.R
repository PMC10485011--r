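#' End-to-end pipeline configuration
#'
#' Bundles every tunable of the cross-validated survival classifier:
#' modalities to use, per-modality correlation thresholds (GE 0.3, CNA 0.6),
#' the GCN settings, mRMR feature counts, fold structure and the base
#' classifier ensemble (logistic regression, RBF-SVM, random forest with 70
#' trees).
#'
#' @param modalities subset of `c("GE", "CNA", "CLN")`.
#' @param thresholds named correlation cutoffs for the graph modalities.
#' @param gcn a [gcn_config()] applied to each graph modality, or a named
#'   list of configs keyed by modality.
#' @param mrmr_n named per-modality mRMR feature counts (capped at the
#'   matrix width); the conventional final choice is 400 GE / 200 CNA genes.
#' @param mrmr_candidates optional vector of counts; when set, the
#'   AUC-driven count search ([search_feature_count()], classically 100 to
#'   500 in steps of 100) replaces `mrmr_n` in every fold.
#' @param n_folds cross-validation folds (default 10).
#' @param validation_fraction fraction of each training split carved out
#'   (stratified) as the validation set (default 0.20).
#' @param seed master seed; every stochastic step derives its own child
#'   seed from it.
#' @param rf_ntree random-forest tree count (default 70).
#' @param smote_k SMOTE neighbour count.
#' @param absolute_correlation threshold on `|r|` instead of signed `r`.
#' @param density_normalize normalize validation accuracies into densities
#'   summing to 1 (additive measure); `FALSE` exercises the general-lambda
#'   interaction regime.
#' @param mrmr_per_fold re-select features inside each fold (default) or
#'   once globally on all labels.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(modalities = c("GE", "CNA", "CLN"),
                            thresholds = c(GE = 0.3, CNA = 0.6),
                            gcn = gcn_config(),
                            mrmr_n = c(GE = 400L, CNA = 200L),
                            mrmr_candidates = NULL,
                            n_folds = 10L,
                            validation_fraction = 0.20,
                            seed = 1L,
                            rf_ntree = 70L,
                            smote_k = 5L,
                            absolute_correlation = FALSE,
                            density_normalize = TRUE,
                            mrmr_per_fold = TRUE) {
  modalities <- match.arg(modalities, c("GE", "CNA", "CLN"), several.ok = TRUE)
  stopifnot(
    length(modalities) >= 1,
    all(thresholds >= -1 & thresholds <= 1),
    n_folds >= 2,
    validation_fraction > 0, validation_fraction < 1
  )
  if (inherits(gcn, "gcn_config")) {
    gcn <- stats::setNames(
      rep(list(gcn), length(setdiff(modalities, "CLN"))),
      setdiff(modalities, "CLN")
    )
  }
  structure(
    list(
      modalities = modalities, thresholds = thresholds, gcn = gcn,
      mrmr_n = mrmr_n, mrmr_candidates = mrmr_candidates,
      n_folds = as.integer(n_folds),
      validation_fraction = validation_fraction, seed = as.integer(seed),
      rf_ntree = as.integer(rf_ntree), smote_k = as.integer(smote_k),
      absolute_correlation = absolute_correlation,
      density_normalize = density_normalize,
      mrmr_per_fold = mrmr_per_fold
    ),
    class = "pipeline_config"
  )
}

#' Stack per-modality feature blocks by sample identifier
#'
#' Column-wise concatenation of GCN embeddings and clinical covariates in
#' the order GE, CNA, CLN (missing modalities are skipped). Rows are aligned
#' by sample id against the first block; an id mismatch is an error, so a
#' permuted block stacks identically after alignment.
#'
#' @param blocks named list of numeric matrices with sample-id rownames,
#'   keyed by modality.
#' @return stacked numeric matrix of width `sum(widths)`.
#' @export
stack_features <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1, !is.null(names(blocks)))
  order_pref <- c("GE", "CNA", "CLN")
  keys <- c(intersect(order_pref, names(blocks)),
            setdiff(names(blocks), order_pref))
  blocks <- blocks[keys]
  ids <- rownames(blocks[[1]])
  if (is.null(ids)) stop("feature blocks need sample-id rownames")
  out <- lapply(seq_along(blocks), function(i) {
    B <- blocks[[i]]
    if (is.null(rownames(B)) || !setequal(rownames(B), ids)) {
      stop("sample ids of block '", keys[i], "' do not match")
    }
    B <- B[ids, , drop = FALSE]
    colnames(B) <- paste(keys[i], seq_len(ncol(B)), sep = "_")
    B
  })
  do.call(cbind, out)
}

#' Fit the three base classifiers and score them on validation data
#'
#' Fits logistic regression, the RBF-SVM and the random forest on the
#' (typically SMOTE-balanced) training matrix, records each classifier's
#' validation accuracy — the quantity the fuzzy densities are built from —
#' and returns probability-producing fits.
#'
#' @param X_train,y_train training features and 0/1 labels.
#' @param X_val,y_val validation features and labels.
#' @param seed seed for the random forest.
#' @param rf_ntree forest size (default 70).
#' @return list with `classifiers` (named list: LR, SVM, RF),
#'   `val_accuracy` (named numeric) and `val_scores` (per-classifier `n x 2`
#'   validation probabilities).
#' @export
train_base_classifiers <- function(X_train, y_train, X_val, y_val, seed = 1L,
                                   rf_ntree = 70L) {
  y_train <- as.integer(y_train)
  if (length(unique(y_train)) < 2L) stop("single-class training data")
  fits <- list(
    LR = fit_logistic(X_train, y_train),
    SVM = fit_svm_rbf(X_train, y_train),
    RF = fit_random_forest(X_train, y_train, ntree = rf_ntree, seed = seed)
  )
  val_scores <- lapply(fits, function(f) predict_proba(f, X_val))
  val_accuracy <- vapply(val_scores, function(M) {
    mean(as.integer(M[, 2] > 0.5) == as.integer(y_val))
  }, numeric(1))
  list(classifiers = fits, val_accuracy = val_accuracy, val_scores = val_scores)
}

# Extract the plain numeric matrix from an omics_matrix or matrix.
modality_values <- function(x) {
  if (inherits(x, "omics_matrix")) x$values else as_numeric_matrix(x)
}

#' Cross-validated end-to-end evaluation
#'
#' Runs the full method under stratified k-fold cross-validation. Per fold:
#' a stratified validation set (20% by default) is carved from the training
#' split; for each graph modality (GE/CNA), mRMR features are selected on
#' training+validation labels only, a patient-similarity graph is built over
#' *all* samples on the selected features (transductive message passing;
#' test labels stay masked), and a GCN is trained on the training nodes; the
#' last-hidden-layer embeddings are stacked with the clinical block; the
#' training portion is SMOTE-balanced; the three base classifiers are
#' fitted and their validation accuracies turned into a lambda-fuzzy
#' measure; finally the test samples' class confidences are fused with the
#' Choquet integral and the seven evaluation metrics computed.
#'
#' @param omics named list with any of `GE`, `CNA` ([omics_matrix()] or
#'   plain matrices) and `CLN`.
#' @param labels a [label_vector()] (or named 0/1 vector) aligned with the
#'   omics rows.
#' @param config a [pipeline_config()].
#' @param folds optional precomputed fold assignment (integer vector in
#'   `1..n_folds`); by default stratified folds are drawn from the seed.
#' @return object of class `cv_result`: per-fold results (metrics, fused
#'   scores, validation accuracies, selected features, GCN weight
#'   checksums), the per-fold metrics table, mean and sd rows, and pooled
#'   ROC points.
#' @export
run_cross_validation <- function(omics, labels, config = pipeline_config(),
                                 folds = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  mods <- config$modalities
  omics <- omics[mods]
  if (any(vapply(omics, is.null, TRUE))) {
    stop("missing modality input: ",
         paste(mods[vapply(omics, is.null, TRUE)], collapse = ", "))
  }
  y <- as.integer(labels)
  ids <- names(labels)
  vals <- lapply(omics, modality_values)
  for (m in mods) check_alignment(vals[[m]], labels)
  n <- length(y)
  if (is.null(folds)) {
    folds <- stratified_folds(y, config$n_folds, derive_seed(config$seed, 0L))
  }
  stopifnot(length(folds) == n)

  graph_mods <- intersect(c("GE", "CNA"), mods)
  # clinical block: pass through, min-max rescaled if not already in [0, 1]
  cln_block <- NULL
  if ("CLN" %in% mods) {
    cln_block <- vals$CLN
    if (min(cln_block) < 0 || max(cln_block) > 1) {
      cln_block <- minmax_normalize(cln_block)
    }
  }

  global_sel <- NULL
  if (!config$mrmr_per_fold) {
    global_sel <- lapply(graph_mods, function(m) {
      mrmr_features(vals[[m]], y, m, config, seed = derive_seed(config$seed, 900L))
    })
    names(global_sel) <- graph_mods
  }

  fold_results <- vector("list", config$n_folds)
  for (fold in seq_len(config$n_folds)) {
    fold_seed <- derive_seed(config$seed, fold)
    test_idx <- which(folds == fold)
    trainval_idx <- which(folds != fold)
    val_idx <- trainval_idx[
      match(stratified_holdout(y[trainval_idx], config$validation_fraction,
                               derive_seed(fold_seed, 1L)),
            seq_along(trainval_idx))
    ]
    train_idx <- setdiff(trainval_idx, val_idx)
    if (length(unique(y[train_idx])) < 2L) {
      warning(sprintf("fold %d has single-class training data; skipped", fold))
      fold_results[[fold]] <- list(fold = fold, failed = TRUE)
      next
    }

    blocks <- list()
    selected <- list()
    weight_checksums <- list()
    for (m in graph_mods) {
      Xm <- vals[[m]]
      sel <- if (config$mrmr_per_fold) {
        mrmr_features(Xm[trainval_idx, , drop = FALSE], y[trainval_idx], m,
                      config, seed = derive_seed(fold_seed, 2L))
      } else global_sel[[m]]
      selected[[m]] <- colnames(Xm)[sel]
      graph <- sample_graph(Xm[, sel, drop = FALSE],
                            threshold = config$thresholds[[m]],
                            absolute = config$absolute_correlation)
      gcfg <- config$gcn[[m]]
      gcfg$seed <- derive_seed(fold_seed, 3L + match(m, graph_mods))
      model <- train_gcn(graph, y, train_idx, gcfg)
      weight_checksums[[m]] <- sum(vapply(model$weights,
                                          function(w) sum(abs(w)), numeric(1)))
      blocks[[m]] <- extract_embeddings(graph, model)
    }
    if (!is.null(cln_block)) blocks$CLN <- cln_block
    F_all <- stack_features(blocks)

    bal <- smote_oversample(F_all[train_idx, , drop = FALSE], y[train_idx],
                            k = config$smote_k,
                            seed = derive_seed(fold_seed, 7L))
    base <- train_base_classifiers(bal$X, bal$y,
                                   F_all[val_idx, , drop = FALSE], y[val_idx],
                                   seed = derive_seed(fold_seed, 8L),
                                   rf_ntree = config$rf_ntree)
    # clamp away from {0, 1}: a perfect validation score would make the
    # unnormalized density hit the open-interval boundary of the lambda root
    fm <- fuzzy_measure(pmin(pmax(base$val_accuracy, 1e-6), 1 - 1e-6),
                        normalize = config$density_normalize)
    test_scores <- lapply(base$classifiers, function(f) {
      predict_proba(f, F_all[test_idx, , drop = FALSE])
    })
    fused <- ensemble_predict(test_scores, fm)
    fused$sample_id <- ids[test_idx]
    metrics <- suppressWarnings(
      compute_metrics(y[test_idx], fused$label, fused$fused_p1)
    )
    fold_results[[fold]] <- list(
      fold = fold, failed = FALSE, test_ids = ids[test_idx],
      val_accuracy = base$val_accuracy, lam = fm$lam,
      selected_features = selected, gcn_weight_checksums = weight_checksums,
      fused = fused, y_test = y[test_idx], metrics = metrics
    )
  }

  ok <- !vapply(fold_results, function(r) isTRUE(r$failed), TRUE)
  metrics_tab <- do.call(rbind, lapply(fold_results[ok], function(r) {
    cbind(data.frame(fold = r$fold), r$metrics)
  }))
  mcols <- setdiff(names(metrics_tab), "fold")
  mean_row <- colMeans(metrics_tab[mcols], na.rm = TRUE)
  sd_row <- vapply(metrics_tab[mcols], stats::sd, numeric(1), na.rm = TRUE)
  fused_all <- do.call(rbind, lapply(fold_results[ok], function(r) {
    cbind(data.frame(fold = r$fold), r$fused, y_true = r$y_test)
  }))
  structure(
    list(
      folds = fold_results, metrics_per_fold = metrics_tab,
      metrics_mean = mean_row, metrics_sd = sd_row,
      fused = fused_all, roc_points = roc_points(fused_all$y_true,
                                                 fused_all$fused_p1),
      config = config, fold_assignment = folds
    ),
    class = "cv_result"
  )
}

# Per-modality mRMR feature choice honouring the config (fixed count or
# AUC-driven candidate search).
mrmr_features <- function(X, y, modality, config, seed) {
  p <- ncol(X)
  nf <- if (!is.null(config$mrmr_candidates)) {
    search_feature_count(X, y, config$mrmr_candidates, seed = seed)
  } else {
    min(p, config$mrmr_n[[modality]])
  }
  mrmr_select(X, y, nf)
}

# Empirical ROC curve points from pooled scores.
roc_points <- function(y_true, y_score) {
  ord <- order(y_score, decreasing = TRUE)
  y <- as.integer(y_true)[ord]
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  data.frame(
    threshold = c(Inf, y_score[ord]),
    tpr = c(0, cumsum(y == 1L) / max(n1, 1L)),
    fpr = c(0, cumsum(y == 0L) / max(n0, 1L))
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, %d samples\n",
              nrow(x$metrics_per_fold), nrow(x$fused)))
  cat("mean metrics:\n")
  print(round(x$metrics_mean, 4))
  invisible(x)
}

#' Write cross-validation outputs to a directory
#'
#' Emits `metrics_per_fold.tsv`, `metrics_mean.tsv` (mean and sd rows),
#' `roc_points.tsv` and `fused_scores.tsv`.
#'
#' @param result a [run_cross_validation()] result.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_cv_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  w(result$metrics_per_fold, "metrics_per_fold.tsv")
  w(cbind(data.frame(stat = c("mean", "sd")),
          rbind(result$metrics_mean, result$metrics_sd)),
    "metrics_mean.tsv")
  w(result$roc_points, "roc_points.tsv")
  w(result$fused, "fused_scores.tsv")
  invisible(out_dir)
}
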