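#' Binary classification metrics from predictions
#'
#' Computes the seven confusion-table metrics plus ROC-AUC, with class 1
#' (short-term survivor) as the positive class: accuracy, Matthews
#' correlation coefficient, precision, sensitivity, specificity, balanced
#' accuracy (the arithmetic mean of sensitivity and specificity), F1, and
#' AUC by the rank (Mann-Whitney) method, which equals the trapezoid rule on
#' the empirical ROC. Ratios with a zero denominator are reported as 0 with
#' a warning (documented convention); when `y_true` has a single class, Mcc
#' and AUC are undefined and reported as `NA` with a warning.
#'
#' @param y_true 0/1 truth.
#' @param y_pred 0/1 predictions.
#' @param y_score optional continuous scores for AUC (higher = class 1).
#' @return one-row data.frame: `Acc`, `Mcc`, `Pre`, `Sn`, `Sp`, `Bal_Acc`,
#'   `F1`, `AUC`.
#' @export
compute_metrics <- function(y_true, y_pred, y_score = NULL) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!is.null(y_score) && length(y_score) != length(y_true)) stop("length mismatch")
  tp <- sum(y_true == 1L & y_pred == 1L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s has zero denominator; reported as 0", what))
      return(0)
    }
    num / den
  }
  acc <- (tp + tn) / length(y_true)
  pre <- safe_div(tp, tp + fp, "Pre")
  sn <- safe_div(tp, tp + fn, "Sn")
  sp <- safe_div(tn, tn + fp, "Sp")
  bal <- (sn + sp) / 2
  f1 <- if (pre + sn == 0) {
    warning("F1 has zero denominator; reported as 0")
    0
  } else 2 * pre * sn / (pre + sn)
  one_class <- (tp + fn == 0L) || (tn + fp == 0L)
  if (one_class) {
    warning("single-class y_true: Mcc and AUC undefined, reported as NA")
    mcc <- NA_real_
    auc <- NA_real_
  } else {
    mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (mcc_den == 0) {
      warning("Mcc has zero denominator; reported as 0")
      0
    } else (tp * tn - fp * fn) / mcc_den
    auc <- if (is.null(y_score)) NA_real_ else auc_rank(y_true, y_score)
  }
  data.frame(Acc = acc, Mcc = mcc, Pre = pre, Sn = sn, Sp = sp,
             Bal_Acc = bal, F1 = f1, AUC = auc)
}
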