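# ROC analysis and confusion metrics.

#' ROC curve, AUC and Youden-optimal cutoff
#'
#' Builds the empirical ROC of a score against a binary label (higher
#' score = more positive). Tied scores are grouped, so the curve walks
#' diagonal segments through ties and the trapezoidal area equals the
#' tie-corrected Mann-Whitney probability
#' `P(score+ > score-) + 0.5 P(score+ = score-)`. The recorded cutoff
#' maximizes Youden's J = sensitivity + specificity - 1 among the
#' observed score thresholds (prediction rule: score strictly greater
#' than the cutoff is positive).
#'
#' @param scores numeric vector.
#' @param labels binary vector (logical, 0/1, or two-level factor);
#'   both classes must be present.
#' @return list of class `ROCCurve`: `fpr`, `tpr`, `thresholds`
#'   (per curve point), `auc`, `cutoff`, `youden`.
#' @examples
#' rocAuc(c(0.8, 0.3, 0.5, 0.1), c(1, 1, 0, 0))$auc  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  lab <- .asBinary(labels)
  if (length(scores) != length(lab)) stop("length mismatch")
  if (length(unique(lab)) < 2)
    stop("both classes must be present for ROC analysis")
  nPos <- sum(lab == 1); nNeg <- sum(lab == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- lab[ord]
  # group tied scores
  grp <- cumsum(!duplicated(s))
  tpG <- tapply(l == 1, grp, sum)
  fpG <- tapply(l == 0, grp, sum)
  tpr <- c(0, cumsum(tpG) / nPos)
  fpr <- c(0, cumsum(fpG) / nNeg)
  thr <- c(Inf, s[!duplicated(s)])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- tpr - fpr
  best <- which.max(j)
  structure(list(fpr = unname(fpr), tpr = unname(tpr), thresholds = thr,
                 auc = unname(auc), cutoff = unname(thr[best]),
                 youden = unname(j[best])),
            class = "ROCCurve")
}

#' @export
print.ROCCurve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  cat(sprintf("  Youden-optimal cutoff: score > %.4g (J = %.3f)\n",
              x$cutoff, x$youden))
  invisible(x)
}

#' Confusion matrix and derived classification metrics
#'
#' @param predicted binary vector of predicted positives (e.g. high-risk
#'   calls).
#' @param truth binary vector of true positives (e.g. early recurrence),
#'   same length.
#' @return list of class `ConfusionMetrics`: counts `tp`, `fp`, `fn`,
#'   `tn` and proportions `sensitivity`, `specificity`, `fpr`, `fnr`
#'   (multiply by 100 for percentages; printing reports percents to one
#'   decimal).
#' @examples
#' m <- confusionMetrics(rep(c(TRUE, FALSE), c(22, 42)),
#'                       rep(c(TRUE, FALSE, TRUE, FALSE), c(18, 4, 4, 38)))
#' round(100 * m$sensitivity, 1)  # 81.8
#' @export
confusionMetrics <- function(predicted, truth) {
  p <- .asBinary(predicted); t <- .asBinary(truth)
  if (length(p) != length(t)) stop("length mismatch")
  tp <- sum(p == 1 & t == 1); fp <- sum(p == 1 & t == 0)
  fn <- sum(p == 0 & t == 1); tn <- sum(p == 0 & t == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = sens, specificity = spec,
                 fpr = 1 - spec, fnr = 1 - sens),
            class = "ConfusionMetrics")
}

#' @export
print.ConfusionMetrics <- function(x, ...) {
  cat(sprintf("Confusion: TP %d  FP %d  FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  FPR %.1f%%  FNR %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity,
              100 * x$fpr, 100 * x$fnr))
  invisible(x)
}

.asBinary <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.factor(x)) {
    if (nlevels(x) > 2) stop("more than two classes")
    return(as.integer(x == levels(x)[nlevels(x)]))
  }
  u <- unique(x[!is.na(x)])
  if (!all(u %in% c(0, 1))) stop("labels must be binary (0/1)")
  as.integer(x)
}
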