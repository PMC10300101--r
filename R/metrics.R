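#' Classification metrics from confusion counts
#'
#' Computes precision (one minus the false discovery rate), recall
#' (sensitivity), F1 score, Matthews correlation coefficient (MCC) and
#' Youden's J from the four confusion counts:
#' \deqn{pr = TP/(TP+FP), \quad rc = TP/(TP+FN),}
#' \deqn{F1 = 2 \cdot pr \cdot rc / (pr + rc),}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)},}
#' \deqn{J = TP/(TP+FN) + TN/(TN+FP) - 1.}
#'
#' Zero-denominator conventions: precision is 0 when `TP+FP = 0`, recall
#' 0 when `TP+FN = 0`, specificity 0 when `TN+FP = 0`, F1 0 when
#' `pr + rc = 0`, and MCC 0 when any factor under the root is 0. Under
#' these conventions an accept-everything strategy on data with at least
#' one positive and one negative has recall 1, MCC 0 and J 0 — the
#' performance of no filtering at all.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts, not all zero.
#' @return Object of class `metrics_report`: a list with the counts and
#'   `precision`, `recall`, `f1`, `mcc`, `youden_j`.
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || anyNA(counts))
    stop("compute_metrics: counts must be non-negative")
  if (sum(counts) == 0)
    stop("compute_metrics: all counts are zero")
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  rc <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- f1_from_pr_rc(pr, rc)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 precision = pr, recall = rc, f1 = f1,
                 mcc = mcc, youden_j = rc + sp - 1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("TP=%g FP=%g TN=%g FN=%g | pr=%.3f rc=%.3f F1=%.3f MCC=%.3f J=%.3f\n",
              x$tp, x$fp, x$tn, x$fn, x$precision, x$recall, x$f1,
              x$mcc, x$youden_j))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
             precision = x$precision, recall = x$recall, f1 = x$f1,
             mcc = x$mcc, youden_j = x$youden_j)
}

#' F1 score from precision and recall
#'
#' Harmonic mean of precision and recall; 0 by convention when both are 0.
#'
#' @param pr Precision in `[0, 1]`.
#' @param rc Recall in `[0, 1]`.
#' @return The F1 score.
#' @examples
#' f1_from_pr_rc(0.36, 0.35) # 0.355, rounds to 0.35
#' @export
f1_from_pr_rc <- function(pr, rc) {
  ifelse(pr + rc > 0, 2 * pr * rc / (pr + rc), 0)
}

#' Confusion counts of a keep/remove decision against labels
#'
#' @param labels Logical truth labels for the observed calls.
#' @param keep Logical decision per call (`TRUE` = kept as somatic).
#' @param extra_fn Additional false negatives: ground-truth variants the
#'   large panel never called, which no filtering strategy can recover.
#' @return A `metrics_report`.
#' @export
metrics_from_decisions <- function(labels, keep, extra_fn = 0L) {
  stopifnot(length(labels) == length(keep))
  compute_metrics(tp = sum(keep & labels), fp = sum(keep & !labels),
                  tn = sum(!keep & !labels),
                  fn = sum(!keep & labels) + extra_fn)
}
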