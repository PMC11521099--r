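check_binary_labels <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) < 1L) stop("empty input", call. = FALSE)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  labels
}

#' ROC curve by threshold sweep
#'
#' Sweeps a decision threshold over the unique scores (ties grouped), from
#' "call everything negative" to "call everything positive". The score is
#' the predicted probability (or any monotone score) of the positive class,
#' label 1 (diseased). The curve runs from (FPR, TPR) = (0, 0) to (1, 1)
#' with both rates nondecreasing.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric vector, higher = more likely label 1.
#' @return A `roc_curve` tibble: `threshold`, `fpr`, `tpr`. The first row
#'   has threshold `Inf` (nothing called positive).
#' @export
roc_curve <- function(labels, scores) {
  labels <- check_binary_labels(labels)
  scores <- as.numeric(scores)
  if (length(labels) != length(scores)) {
    stop("`labels` and `scores` must have equal length", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # group tied scores: one curve point after each distinct score value
  keep <- c(sc[-length(sc)] != sc[-1L], TRUE)
  tp <- cumsum(lab)[keep]
  fp <- cumsum(1L - lab)[keep]
  P <- sum(lab)
  N <- length(lab) - P
  out <- tibble::tibble(threshold = c(Inf, sc[keep]),
                        fpr = c(0, fp / N),
                        tpr = c(0, tp / P))
  class(out) <- c("roc_curve", class(out))
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area under a [roc_curve()]. Equivalent to the normalized
#' Mann-Whitney U statistic: the fraction of (positive, negative) pairs
#' ranked correctly, with half credit for ties. `roc_auc(labels, scores)`
#' computes the curve first.
#'
#' @param x a `roc_curve`, or a 0/1 label vector.
#' @param scores scores when `x` is a label vector.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(x, scores = NULL) {
  roc <- if (inherits(x, "roc_curve")) x else roc_curve(x, scores)
  sum(diff(roc$fpr) * (roc$tpr[-1L] + roc$tpr[-nrow(roc)]) / 2)
}

#' Classification accuracy at a probability threshold
#'
#' Predicts label 1 when the diseased-class probability exceeds
#' `threshold`, and reports the overall fraction correct together with the
#' two class-conditional accuracies (the healthy figure is the accuracy on
#' true label-0 samples, i.e. specificity).
#'
#' @param labels 0/1 vector with both classes present.
#' @param p_diseased probability (score) of label 1 per sample.
#' @param threshold decision cut on `p_diseased` (default 0.5).
#' @return A one-row tibble: `overall`, `acc_healthy`, `acc_diseased`,
#'   `threshold`.
#' @export
classification_accuracy <- function(labels, p_diseased, threshold = 0.5) {
  labels <- check_binary_labels(labels)
  p_diseased <- as.numeric(p_diseased)
  if (length(labels) != length(p_diseased)) {
    stop("`labels` and `p_diseased` must have equal length", call. = FALSE)
  }
  pred <- as.integer(p_diseased > threshold)
  tibble::tibble(
    overall = mean(pred == labels),
    acc_healthy = mean(pred[labels == 0L] == 0L),
    acc_diseased = mean(pred[labels == 1L] == 1L),
    threshold = threshold)
}

#' Full classifier evaluation report
#'
#' ROC curve, AUC and accuracies for a scored cohort.
#'
#' @inheritParams classification_accuracy
#' @return A `roc_report`: list with `roc` (tibble), `auc`, `accuracy`
#'   (tibble row).
#' @export
evaluate_classifier <- function(labels, p_diseased, threshold = 0.5) {
  roc <- roc_curve(labels, p_diseased)
  structure(list(roc = roc,
                 auc = roc_auc(roc),
                 accuracy = classification_accuracy(labels, p_diseased,
                                                    threshold)),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("<roc_report> AUC %.4f | accuracy %.2f%% (healthy %.2f%%, diseased %.2f%%)\n",
              x$auc, 100 * x$accuracy$overall,
              100 * x$accuracy$acc_healthy, 100 * x$accuracy$acc_diseased))
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param object a `roc_curve` or `roc_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = fpr, y = tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#2171b5", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", roc_auc(object))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.roc_report <- function(object, ...) autoplot.roc_curve(object$roc, ...)
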