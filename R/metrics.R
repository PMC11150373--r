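# One-vs-rest evaluation metrics from a multiclass confusion matrix
# (rows = true class, columns = predicted class).

#' Per-class precision, recall, F1 and overall accuracy
#'
#' Derives one-vs-rest TP/FP/TN/FN counts for every class and computes
#' precision \eqn{P = TP/(TP+FP)}, recall \eqn{R = TP/(TP+FN)},
#' \eqn{F_1 = 2PR/(P+R)} and overall accuracy
#' \eqn{Acc = \mathrm{trace}(C)/\sum C}. A zero denominator (e.g. a class
#' never predicted) yields 0 for the affected metric with the `degenerate`
#' flag set, rather than NaN.
#'
#' @param confusion square matrix of nonnegative integer counts,
#'   rows = true class, columns = predicted class.
#' @return object of class `class_metrics`: list with `per_class`
#'   (data.frame of counts and metrics per class) and `accuracy`.
#' @examples
#' cm <- matrix(c(50, 2, 3, 45), 2, 2)
#' class_metrics(cm)
#' @export
class_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) {
    stop("`confusion` must be square", call. = FALSE)
  }
  if (any(confusion < 0) || any(confusion != round(confusion))) {
    stop("`confusion` must hold nonnegative integer counts", call. = FALSE)
  }
  total <- sum(confusion)
  k <- nrow(confusion)
  classes <- rownames(confusion)
  if (is.null(classes)) classes <- as.character(seq_len(k) - 1L)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  degenerate <- (tp + fp) == 0 | (tp + fn) == 0 | (precision + recall) == 0
  per_class <- data.frame(class = classes, TP = tp, FP = fp, TN = tn, FN = fn,
                          precision = precision, recall = recall, f1 = f1,
                          degenerate = degenerate, row.names = NULL)
  structure(list(per_class = per_class,
                 accuracy = if (total > 0) sum(tp) / total else 0),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, digits = 3L, ...) {
  m <- x$per_class
  cat(sprintf("%-8s %10s %10s %10s\n", "Class", "Precision", "Recall", "F1"))
  for (i in seq_len(nrow(m))) {
    cat(sprintf("%-8s %10.*f %10.*f %10.*f%s\n", m$class[i],
                digits, m$precision[i], digits, m$recall[i], digits, m$f1[i],
                if (m$degenerate[i]) "  (degenerate)" else ""))
  }
  cat(sprintf("Overall accuracy: %.*f\n", digits, x$accuracy))
  invisible(x)
}

#' F1 score from precision and recall
#'
#' Harmonic mean \eqn{F_1 = 2PR/(P+R)}; returns 0 when `p + r == 0`.
#' @param p,r precision and recall in `[0, 1]`.
#' @return F1 score in `[0, 1]`.
#' @examples
#' f1_score(0.902, 0.485)  # 0.631 to 3 d.p.
#' @export
f1_score <- function(p, r) {
  stopifnot(all(p >= 0 & p <= 1), all(r >= 0 & r <= 1))
  ifelse(p + r > 0, 2 * p * r / (p + r), 0)
}
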