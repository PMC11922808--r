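#' Confusion matrix for a binary classifier
#'
#' Counts are stored with the case group (e.g. patients) as the positive
#' class. All four counts must be non-negative integers.
#'
#' @param tp,fp,tn,fn true/false positive/negative counts.
#' @return an object of class `confusion_matrix`.
#' @export
#' @examples
#' confusion_matrix(tp = 25, fp = 8, tn = 24, fn = 7)
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stop_if_not(all(is.finite(counts)) && all(counts >= 0) &&
                all(counts == round(counts)),
              "confusion_matrix: counts must be non-negative integers")
  structure(setNames(as.list(as.integer(counts)), names(counts)),
            class = "confusion_matrix")
}

#' Tally a confusion matrix from predicted probabilities
#'
#' Predicted label is `probability >= threshold`; a probability exactly at
#' the threshold therefore predicts the positive class (documented tie
#' rule).
#'
#' @param true_labels binary vector (0 = control, 1 = case).
#' @param probabilities predicted case probabilities in `[0, 1]`.
#' @param threshold decision threshold, default 0.5.
#' @return a [confusion_matrix()].
#' @export
confusion_from_predictions <- function(true_labels, probabilities,
                                       threshold = 0.5) {
  stop_if_not(length(true_labels) == length(probabilities),
              "length mismatch: %d labels vs %d probabilities",
              length(true_labels), length(probabilities))
  stop_if_not(all(true_labels %in% c(0, 1)),
              "confusion_from_predictions: labels must be binary 0/1")
  stop_if_not(all(is.finite(probabilities)) && all(probabilities >= 0) &&
                all(probabilities <= 1),
              "confusion_from_predictions: probabilities must lie in [0, 1]")
  pred <- as.integer(probabilities >= threshold)
  confusion_matrix(tp = sum(pred == 1 & true_labels == 1),
                   fp = sum(pred == 1 & true_labels == 0),
                   tn = sum(pred == 0 & true_labels == 0),
                   fn = sum(pred == 0 & true_labels == 1))
}

#' Derived classification metrics
#'
#' Computes the six reported metrics from a 2x2 confusion matrix:
#' accuracy, sensitivity (recall on cases), specificity, precision, F1 and
#' the Matthews correlation coefficient
#' \deqn{MCC = \frac{tp\,tn - fp\,fn}{\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}}.}
#' Any metric whose denominator is zero is reported as 0 and its name is
#' added to `degenerate_flags`, so pooled reports stay total and auditable.
#'
#' @param cm a [confusion_matrix()].
#' @return an object of class `metrics_report` with fields `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `f1`, `mcc`, `n` and
#'   `degenerate_flags`.
#' @export
#' @examples
#' compute_metrics(confusion_matrix(25, 8, 24, 7))
compute_metrics <- function(cm) {
  stop_if_not(inherits(cm, "confusion_matrix"),
              "compute_metrics: expected a confusion_matrix")
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  n <- tp + fp + tn + fn
  stop_if_not(n > 0, "compute_metrics: empty confusion matrix")
  flags <- character()
  safe <- function(num, den, name) {
    if (den == 0) {
      flags <<- c(flags, name)
      0
    } else num / den
  }
  mcc_den2 <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  out <- list(
    accuracy    = (tp + tn) / n,
    sensitivity = safe(tp, tp + fn, "sensitivity"),
    specificity = safe(tn, tn + fp, "specificity"),
    precision   = safe(tp, tp + fp, "precision"),
    f1          = safe(2 * tp, 2 * tp + fp + fn, "f1"),
    mcc         = if (mcc_den2 == 0) 0
                  else (tp * tn - fp * fn) / sqrt(mcc_den2),
    n = n
  )
  if (mcc_den2 == 0) flags <- c(flags, "mcc")
  out$degenerate_flags <- flags
  out$confusion <- cm
  structure(out, class = "metrics_report")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(`true` = c("case", "control"),
                              `predicted` = c("case", "control")))
  cat("Confusion matrix (positive class = case)\n")
  print(m)
  invisible(x)
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  cat(sprintf("Classification metrics (n = %d)\n", x$n))
  vals <- c(accuracy = x$accuracy, sensitivity = x$sensitivity,
            specificity = x$specificity, precision = x$precision,
            f1 = x$f1, mcc = x$mcc)
  for (nm in names(vals))
    cat(sprintf("  %-11s %s%s\n", nm, formatC(vals[[nm]], format = "f",
                                              digits = digits),
                if (nm %in% x$degenerate_flags) "  [degenerate: 0/0 -> 0]"
                else ""))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(accuracy = x$accuracy, sensitivity = x$sensitivity,
             specificity = x$specificity, precision = x$precision,
             f1 = x$f1, mcc = x$mcc, n = x$n)
}
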