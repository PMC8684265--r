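#' @title Evaluation: confusion counts, derived metrics, and rank-based AUC
#'
#' @description The positive class is benign throughout (TP = benign called
#' benign), mirroring the clinical-tables convention this method reports
#' under. Note this inverts the common "positive = disease" convention.
#'
#' @name evaluation
NULL

#' Confusion counts with benign as the positive class
#'
#' @param truth vector of true labels (\code{benign}/\code{malignant}).
#' @param predicted vector of predicted labels, same length.
#' @return a \code{confusion_counts} list with integers \code{TP},
#'   \code{TN}, \code{FP}, \code{FN}.
#' @export
#' @examples
#' confusion(c("benign", "malignant"), c("benign", "benign"))
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop_lrsc("truth (%d) and predicted (%d) lengths differ", length(truth),
              length(predicted))
  }
  t <- normalize_label(truth, "truth label")
  p <- normalize_label(predicted, "predicted label")
  if (length(truth) > 0 && (any(is.na(t)) || any(is.na(p)))) {
    stop_lrsc("labels must all be benign or malignant")
  }
  structure(list(
    TP = sum(t == "benign" & p == "benign"),
    TN = sum(t == "malignant" & p == "malignant"),
    FP = sum(t == "malignant" & p == "benign"),
    FN = sum(t == "benign" & p == "malignant")
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> (positive = benign)\n")
  cat(sprintf("  TP = %d  FN = %d\n  FP = %d  TN = %d\n", x$TP, x$FN, x$FP,
              x$TN))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity, PPV and NPV from the benign-positive
#' counts. A metric with an empty denominator is reported as \code{NA} and
#' named in the \code{"undefined"} attribute — never silently coerced to 0.
#'
#' @param c a \code{confusion_counts} object (or list with TP/TN/FP/FN).
#' @return named numeric vector \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, \code{ppv}, \code{npv}; attribute
#'   \code{"undefined"} lists the metrics with zero denominators.
#' @export
classification_metrics <- function(c) {
  TP <- c$TP; TN <- c$TN; FP <- c$FP; FN <- c$FN
  stopifnot(all(c(TP, TN, FP, FN) >= 0))
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  out <- c(
    accuracy = safe(TP + TN, TP + TN + FP + FN),
    sensitivity = safe(TP, TP + FN),
    specificity = safe(TN, TN + FP),
    ppv = safe(TP, TP + FP),
    npv = safe(TN, TN + FN)
  )
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Rank-based ROC area
#'
#' Mann-Whitney AUC of benign-likelihood scores with benign as the positive
#' class; tied scores contribute 1/2. Equals the probability that a random
#' benign image outscores a random malignant one.
#'
#' @param scores numeric benign-likelihood scores.
#' @param truth true labels, same length; both classes must be present.
#' @return AUC in \code{[0, 1]}.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.2, 0.1), c("benign", "benign", "malignant", "malignant"))
roc_auc <- function(scores, truth) {
  if (length(scores) != length(truth)) {
    stop_lrsc("scores (%d) and truth (%d) lengths differ", length(scores),
              length(truth))
  }
  t <- normalize_label(truth, "truth label")
  pos <- t == "benign"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop_lrsc("AUC needs both classes present (benign: %d, malignant: %d)",
              n1, n0)
  }
  r <- rank(scores)  # average ranks give half-credit on ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate predictions against truth
#'
#' Convenience wrapper bundling confusion counts, the five derived metrics
#' and the rank-based AUC into one report.
#'
#' @param truth true labels.
#' @param predicted predicted labels.
#' @param scores benign-likelihood scores for the AUC (optional; without
#'   them AUC is \code{NA}).
#' @return list with \code{counts}, \code{metrics}, \code{auc},
#'   \code{n_images}.
#' @export
evaluate_predictions <- function(truth, predicted, scores = NULL) {
  cts <- confusion(truth, predicted)
  auc <- if (is.null(scores)) NA_real_ else roc_auc(scores, truth)
  list(counts = cts, metrics = classification_metrics(cts), auc = auc,
       n_images = length(truth))
}
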