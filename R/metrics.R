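# Confusion-matrix indices, ROC/AUC, and optimal-cutoff estimation.
# Conventions for degenerate denominators: MCC -> 0; sensitivity /
# specificity / precision -> 0 with an undefined flag; DOR and DP flagged
# undefined whenever sensitivity or specificity sits on {0, 1} (optionally
# a Haldane +0.5 correction instead).

#' Confusion counts from binary labels
#'
#' @param truth,estimate 0/1 vectors of equal length (1 = positive class).
#' @return Object of class `confusion_counts` with fields TP, FP, TN, FN.
#' @export
#' @examples
#' confusion(c(1, 1, 1, 0), c(1, 0, 1, 0))
confusion <- function(truth, estimate) {
  truth <- check_labels(truth, both_classes = FALSE)
  estimate <- check_labels(estimate, both_classes = FALSE)
  if (length(truth) != length(estimate)) abort("truth/estimate length mismatch")
  structure(list(TP = sum(truth == 1 & estimate == 1),
                 FP = sum(truth == 0 & estimate == 1),
                 TN = sum(truth == 0 & estimate == 0),
                 FN = sum(truth == 1 & estimate == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP=", x$TP, " FP=", x$FP,
      " TN=", x$TN, " FN=", x$FN, "\n", sep = "")
  invisible(x)
}

#' Matthews correlation coefficient from counts
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' when the denominator vanishes. Robust to class imbalance; used as the
#' PSO fitness throughout the GMDH engine.
#'
#' @param counts A [confusion()] object or list with TP/FP/TN/FN.
#' @return Scalar in \[-1, 1\].
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' All performance indices from confusion counts
#'
#' Computes sensitivity, specificity, precision, accuracy, MCC, the
#' diagnostic odds ratio `DOR = (TP*TN)/(FP*FN)` and discriminant power
#' `DP = (sqrt(3)/pi) * (logit(sens) + logit(spec))`. Rates with a zero
#' denominator are reported as 0 and flagged; DOR/DP are flagged undefined
#' when sensitivity or specificity is exactly 0 or 1 (unless
#' `haldane = TRUE`, which adds 0.5 to every cell first).
#'
#' @param counts A [confusion()] object.
#' @param scores,truth Optional: per-sample scores and true labels, to add
#'   AUC to the metric set.
#' @param haldane Apply the +0.5 Haldane correction for DOR/DP.
#' @return One-row tibble of class `metric_set`.
#' @export
#' @examples
#' compute_metrics(confusion(c(1, 1, 0, 0), c(1, 0, 1, 0)))
compute_metrics <- function(counts, scores = NULL, truth = NULL,
                            haldane = FALSE) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  total <- tp + fp + tn + fn
  if (total < 1) abort("empty confusion table")
  rate <- function(num, den) if (den == 0) 0 else num / den
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, tn + fp)
  prec <- rate(tp, tp + fp)
  acc <- (tp + tn) / total
  undefined <- character(0)
  if (tp + fn == 0) undefined <- c(undefined, "sensitivity")
  if (tn + fp == 0) undefined <- c(undefined, "specificity")
  if (tp + fp == 0) undefined <- c(undefined, "precision")
  if (haldane) {
    s2 <- (tp + 0.5) / (tp + fn + 1)
    c2 <- (tn + 0.5) / (tn + fp + 1)
    dor <- ((tp + 0.5) * (tn + 0.5)) / ((fp + 0.5) * (fn + 0.5))
    dp <- (sqrt(3) / pi) * (qlogis(s2) + qlogis(c2))
  } else if (sens %in% c(0, 1) || spec %in% c(0, 1)) {
    dor <- NA_real_
    dp <- NA_real_
    undefined <- c(undefined, "DOR", "DP")
  } else {
    dor <- (tp * tn) / (fp * fn)
    dp <- (sqrt(3) / pi) * (qlogis(sens) + qlogis(spec))
  }
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.null(truth)) abort("`truth` is required when `scores` is given")
    auc <- roc_auc(scores, truth)$auc
  }
  out <- tibble(sensitivity = sens, specificity = spec, precision = prec,
                accuracy = acc, mcc = mcc(counts), dor = dor, dp = dp,
                auc = auc, tp = tp, fp = fp, tn = tn, fn = fn)
  structure(out, undefined = undefined,
            class = c("metric_set", class(out)))
}

#' Metric set straight from labels
#'
#' Convenience wrapper: confusion counts plus [compute_metrics()], with AUC
#' when scores are supplied.
#'
#' @inheritParams compute_metrics
#' @param estimate Predicted 0/1 labels.
#' @export
metric_set <- function(truth, estimate, scores = NULL, haldane = FALSE) {
  compute_metrics(confusion(truth, estimate), scores = scores, truth = truth,
                  haldane = haldane)
}

#' ROC curve and AUC
#'
#' Sweeps every unique score as a threshold (predicted positive when
#' `score >= threshold`), grouping tied scores, and anchors the curve at
#' (0,0) and (1,1). AUC is the trapezoid-rule area, which equals the
#' normalised Mann-Whitney U statistic with the standard tie correction.
#'
#' @param scores Numeric per-sample scores (higher = more positive).
#' @param labels 0/1 true labels; both classes must be present.
#' @return List with `curve` (tibble of class `roc_curve`: threshold, fpr,
#'   tpr) and `auc`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))$auc
roc_auc <- function(scores, labels) {
  labels <- check_labels(labels, n = length(scores))
  if (anyNA(scores)) abort("scores contain missing values")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores at one threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last <- which(!duplicated(grp, fromLast = TRUE))
  thr <- s[last]
  tpr <- tp[last] / n_pos
  fpr <- fp[last] / n_neg
  curve <- tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] != 1 || curve$tpr[nrow(curve)] != 1) {
    curve <- bind_rows(curve, tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  curve <- structure(curve, class = c("roc_curve", class(curve)))
  list(curve = curve, auc = auc)
}

#' Optimal decision cutoff from a ROC sweep
#'
#' Default criterion is Youden's J = TPR - FPR, maximised over the observed
#' score thresholds; ties resolve to the smallest threshold. The
#' alternative picks the threshold closest to the (0,1) corner. The
#' returned cutoff is clipped strictly inside (0,1) so it remains usable as
#' a probability threshold.
#'
#' @inheritParams roc_auc
#' @param method `"youden"` (default) or `"closest_topleft"`.
#' @return Scalar cutoff in (0, 1).
#' @export
optimal_cutoff <- function(scores, labels,
                           method = c("youden", "closest_topleft")) {
  method <- arg_match(method)
  curve <- roc_auc(scores, labels)$curve
  finite <- is.finite(curve$threshold)
  curve <- curve[finite, , drop = FALSE]
  if (nrow(curve) == 0L) return(0.5)
  crit <- switch(method,
                 youden = curve$tpr - curve$fpr,
                 closest_topleft = -(curve$fpr^2 + (1 - curve$tpr)^2))
  best <- which(crit == max(crit))
  cut <- min(curve$threshold[best])
  eps <- 1e-6
  min(max(cut, eps), 1 - eps)
}

#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}
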