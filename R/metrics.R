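# Confusion-matrix machinery and the six evaluation metrics used across
# cross-validation, hold-out evaluation and prediction-vs-experiment
# bookkeeping: MCC, precision, recall, accuracy, specificity and NPV.

#' Build a confusion matrix from binary labels and predictions
#'
#' The positive class is "active" (coded 1). `fp` counts inactive
#' compounds predicted active, `fn` active compounds predicted inactive.
#'
#' @param labels,predictions Vectors of equal length; either 0/1, logical,
#'   or character `"active"`/`"inactive"`.
#' @return An `iso_confusion` object with counts `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(labels, predictions) {
  assert_that(length(labels) == length(predictions) && length(labels) >= 1,
              "labels and predictions must have equal positive length")
  to01 <- function(x) {
    if (is.character(x) || is.factor(x)) as.integer(as.character(x) == "active")
    else as.integer(x)
  }
  y <- to01(labels); p <- to01(predictions)
  assert_that(all(y %in% 0:1) && all(p %in% 0:1),
              "labels/predictions must be binary")
  structure(list(tp = sum(y == 1 & p == 1), tn = sum(y == 0 & p == 0),
                 fp = sum(y == 0 & p == 1), fn = sum(y == 1 & p == 0)),
            class = "iso_confusion")
}

#' @export
print.iso_confusion <- function(x, ...) {
  cat(sprintf("<iso_confusion> tp=%d tn=%d fp=%d fn=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Evaluation metrics from a confusion matrix
#'
#' Computes MCC, precision, recall, accuracy, specificity and NPV from the
#' four counts. A metric whose denominator is zero (e.g. precision with no
#' positive predictions, or MCC with an empty margin) is reported as `NA`
#' rather than silently forced to 0.
#'
#' @param cm An `iso_confusion`, or a list/vector with elements `tp`, `tn`,
#'   `fp`, `fn`.
#' @return One-row tibble with columns `mcc`, `precision`, `recall`,
#'   `accuracy`, `specificity`, `npv`.
#' @examples
#' metric_set(confusion(c(1, 1, 0, 0), c(1, 0, 1, 0)))
#' @export
metric_set <- function(cm) {
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  assert_that(all(c(tp, tn, fp, fn) >= 0) && tp + tn + fp + fn >= 1,
              "invalid confusion matrix")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (mcc_den == 0) NA_real_ else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  tibble::tibble(
    mcc = mcc,
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    accuracy = safe_div(tp + tn, tp + tn + fp + fn),
    specificity = safe_div(tn, tn + fp),
    npv = safe_div(tn, tn + fn))
}

#' Metrics directly from labels and predictions
#'
#' Convenience wrapper: `metric_set(confusion(labels, predictions))`.
#'
#' @inheritParams confusion
#' @return One-row metrics tibble (see [metric_set()]).
#' @export
classification_metrics <- function(labels, predictions) {
  metric_set(confusion(labels, predictions))
}
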