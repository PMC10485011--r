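#' Multi-omics sample-by-feature container
#'
#' An `omics_matrix` couples a numeric samples x features matrix with the
#' modality it came from and the value alphabet the modality is allowed to
#' take after preprocessing: gene expression (`GE`) is ternary
#' \{-1, 0, 1\}, copy-number alteration (`CNA`) takes the five discrete
#' levels \{-2, ..., 2\}, and clinical covariates (`CLN`) live in \[0, 1\]
#' after min-max scaling.
#'
#' @param values numeric matrix (samples in rows) with unique row and column
#'   names; missing cells may be `NA` only when `allow_missing = TRUE`.
#' @param modality one of `"GE"`, `"CNA"`, `"CLN"`.
#' @param alphabet one of `"ternary"` (\{-1,0,1\}), `"cna5"` (\{-2..2\}),
#'   `"unit"` (\[0,1\]) or `"real"` (unrestricted). Defaults to the
#'   conventional alphabet of the modality.
#' @param allow_missing allow `NA` cells (pre-imputation data).
#'
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, modality = c("GE", "CNA", "CLN"),
                         alphabet = NULL, allow_missing = FALSE) {
  modality <- match.arg(modality)
  values <- as_numeric_matrix(values, "values")
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("%s_f%04d", modality, seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate feature identifiers")
  if (is.null(alphabet)) {
    alphabet <- switch(modality, GE = "ternary", CNA = "cna5", CLN = "unit")
  }
  alphabet <- match.arg(alphabet, c("ternary", "cna5", "unit", "real"))
  if (!allow_missing && anyNA(values)) {
    stop("`values` contains missing cells; impute first or set allow_missing")
  }
  check_alphabet(values, alphabet)
  structure(
    list(values = values, modality = modality, alphabet = alphabet),
    class = "omics_matrix"
  )
}

check_alphabet <- function(values, alphabet) {
  v <- values[!is.na(values)]
  ok <- switch(alphabet,
    ternary = all(v %in% c(-1, 0, 1)),
    cna5 = all(v %in% -2:2),
    unit = all(v >= 0 & v <= 1),
    real = TRUE
  )
  if (!ok) stop(sprintf("values violate the declared '%s' alphabet", alphabet))
  invisible(TRUE)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "<omics_matrix> %s: %d samples x %d features, alphabet '%s'%s\n",
    x$modality, nrow(x$values), ncol(x$values), x$alphabet,
    if (anyNA(x$values)) sprintf(" (%d missing cells)", sum(is.na(x$values))) else ""
  ))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Binary survival label vector
#'
#' Labels follow the five-year convention: 1 marks a short-term survivor
#' (death before five years), 0 a long-term survivor. Class 1 is the
#' positive (minority) class throughout the package.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param label vector of 0/1 labels aligned with `sample_ids`.
#' @return an object of class `label_vector` (a named integer vector).
#' @export
label_vector <- function(sample_ids, label) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  label <- as.integer(label)
  if (length(label) != length(sample_ids)) stop("length mismatch")
  if (!all(label %in% c(0L, 1L))) stop("labels must be 0 (long-term) or 1 (short-term)")
  structure(stats::setNames(label, sample_ids), class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  cat(sprintf(
    "<label_vector> %d samples: %d short-term (1) / %d long-term (0)\n",
    length(x), sum(x == 1L), sum(x == 0L)
  ))
  invisible(x)
}

# Check that an omics_matrix (or plain matrix) and labels refer to the same
# samples in the same order.
check_alignment <- function(values, labels) {
  ids <- rownames(values)
  if (is.null(ids) || !identical(ids, names(labels))) {
    stop("sample identifiers of the matrix and labels do not align")
  }
  invisible(TRUE)
}

#' Read a modality table from TSV
#'
#' Expects a header row of feature names, a first column `sample_id`, and
#' numeric cells; empty cells or `NA` encode missing values.
#'
#' @param path file path.
#' @param modality one of `"GE"`, `"CNA"`, `"CLN"`.
#' @param alphabet value alphabet, see [omics_matrix()]; use `"real"` for raw
#'   (not yet preprocessed) input.
#' @return an [omics_matrix()].
#' @export
read_omics_tsv <- function(path, modality, alphabet = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"))
  if (names(df)[1] != "sample_id") stop("first column must be `sample_id`")
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric entries in omics table")
  rownames(values) <- as.character(df$sample_id)
  omics_matrix(values, modality, alphabet, allow_missing = anyNA(values))
}

#' Write a modality table to TSV
#' @param x an [omics_matrix()] or numeric matrix with rownames.
#' @param path output file path.
#' @export
write_omics_tsv <- function(x, path) {
  values <- if (inherits(x, "omics_matrix")) x$values else x
  df <- data.frame(sample_id = rownames(values), values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read survival labels from TSV (`sample_id`, `label` columns)
#' @param path file path.
#' @return a [label_vector()].
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("labels TSV needs `sample_id` and `label` columns")
  }
  label_vector(df$sample_id, df$label)
}

#' Write survival labels to TSV
#' @param labels a [label_vector()].
#' @param path output file path.
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), label = as.integer(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
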