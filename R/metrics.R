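#' Confusion matrix counts
#'
#' The positive class is 1 (hypertensive).
#'
#' @param y_true,y_pred equal-length 0/1 label vectors.
#' @return A list of class `bcg_confusion` with integer `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- label_to_int(y_true)
  y_pred <- label_to_int(y_pred)
  if (length(y_true) != length(y_pred)) stop_bcg("length mismatch")
  structure(list(
    tp = sum(y_true == 1L & y_pred == 1L),
    tn = sum(y_true == 0L & y_pred == 0L),
    fp = sum(y_true == 0L & y_pred == 1L),
    fn = sum(y_true == 1L & y_pred == 0L)
  ), class = "bcg_confusion")
}

# 0/0 rate cases return 0 and set the `degenerate` flag rather than
# erroring, so cross-validation loops survive degenerate folds
safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Confusion-matrix metrics
#'
#' Accuracy, precision, sensitivity (recall), specificity, F1 (harmonic
#' mean of precision and recall) and Jaccard score. Any 0/0 case returns 0
#' and is flagged in the `degenerate` attribute.
#'
#' @param cm a `bcg_confusion` from [confusion()].
#' @return A named numeric vector of the six metrics.
#' @export
basic_metrics <- function(cm) {
  n <- cm$tp + cm$tn + cm$fp + cm$fn
  if (n == 0) stop_bcg("empty confusion matrix")
  precision <- safe_ratio(cm$tp, cm$tp + cm$fp)
  sensitivity <- safe_ratio(cm$tp, cm$tp + cm$fn)
  out <- c(
    accuracy = (cm$tp + cm$tn) / n,
    precision = precision,
    sensitivity = sensitivity,
    specificity = safe_ratio(cm$tn, cm$tn + cm$fp),
    f1 = safe_ratio(2 * precision * sensitivity, precision + sensitivity),
    jaccard = safe_ratio(cm$tp, cm$tp + cm$fp + cm$fn)
  )
  degenerate <- (cm$tp + cm$fp == 0) || (cm$tp + cm$fn == 0) ||
    (cm$tn + cm$fp == 0) || (precision + sensitivity == 0)
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(Po - Pe) / (1 - Pe)`, with
#' `Pe = sum_k (row_k/n) * (col_k/n)` over the class marginals. When
#' `Pe = 1` (both vectors constant on one class) the convention is kappa =
#' 1 for perfect agreement, else 0 with a warning.
#'
#' @inheritParams confusion
#' @return Scalar kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(y_true, y_pred) {
  y_true <- label_to_int(y_true)
  y_pred <- label_to_int(y_pred)
  if (length(y_true) != length(y_pred)) stop_bcg("length mismatch")
  n <- length(y_true)
  po <- mean(y_true == y_pred)
  classes <- 0:1
  pe <- sum(vapply(classes, function(k)
    (sum(y_true == k) / n) * (sum(y_pred == k) / n), numeric(1)))
  if (abs(1 - pe) < 1e-12) {
    if (po == 1) return(1)
    warning("chance agreement is 1; kappa undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' McNemar's paired test of two classifiers
#'
#' `b` counts samples model A classifies correctly and model B wrongly;
#' `c` the reverse. The statistic is `(b - c)^2 / (b + c)` (with continuity
#' correction `(|b - c| - 1)^2 / (b + c)` when enabled), referred to a
#' chi-squared distribution with 1 df. `b + c = 0` gives chi2 = 0, p = 1.
#'
#' @param y_true 0/1 truth.
#' @param pred_a,pred_b 0/1 predictions of the two models.
#' @param correction apply the continuity correction (default `FALSE`).
#' @return A list with `chi2`, `p`, `b`, `c` and the full paired table.
#' @export
mcnemar_test <- function(y_true, pred_a, pred_b, correction = FALSE) {
  y_true <- label_to_int(y_true)
  pred_a <- label_to_int(pred_a)
  pred_b <- label_to_int(pred_b)
  if (length(y_true) != length(pred_a) || length(y_true) != length(pred_b))
    stop_bcg("length mismatch")
  a_ok <- pred_a == y_true
  b_ok <- pred_b == y_true
  b <- sum(a_ok & !b_ok)
  cc <- sum(!a_ok & b_ok)
  both <- sum(a_ok & b_ok)
  neither <- sum(!a_ok & !b_ok)
  if (b + cc == 0) {
    chi2 <- 0; p <- 1
  } else {
    num <- if (correction) (abs(b - cc) - 1)^2 else (b - cc)^2
    chi2 <- num / (b + cc)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  list(chi2 = chi2, p = p, b = b, c = cc,
       table = matrix(c(both, cc, b, neither), 2, 2,
                      dimnames = list(A = c("correct", "wrong"),
                                      B = c("correct", "wrong"))))
}

#' ROC curve and AUC
#'
#' The ROC traces (FPR, TPR) — the abscissa being 1 - specificity — over
#' all score thresholds; the AUC is the trapezoidal integral, which equals
#' the Mann-Whitney rank statistic with ties counted one half.
#'
#' @param y_true 0/1 labels (both classes must be present).
#' @param scores numeric scores, larger = more positive.
#' @return A list with `auc` and `roc_points` (data frame `fpr`, `tpr`,
#'   monotone from (0,0) to (1,1)).
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- label_to_int(y_true)
  if (length(y_true) != length(scores)) stop_bcg("length mismatch")
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_bcg("both classes must be present for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  # cumulative counts at each distinct threshold (ties move together)
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, tp[keep] / n_pos)
  fpr <- c(0, fp[keep] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, roc_points = data.frame(fpr = fpr, tpr = tpr))
}
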