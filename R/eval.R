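## Video-level performance evaluation: confusion counts and derived metrics,
## row-normalized confusion matrices, ROC/AUC over the score range, threshold
## sweeps, and the exact McNemar comparison of two paired classifiers.

.predFrame <- function(predictions) {
  if (is.data.frame(predictions)) {
    stopifnot(all(c("video_score", "true_label") %in% names(predictions)))
    predictions
  } else {
    predictionsTable(predictions)
  }
}

#' Compute confusion counts and performance metrics at a threshold
#'
#' Counts are recomputed at the stated threshold by re-thresholding the video
#' scores (score >= threshold is a positive call). Accuracy, precision,
#' sensitivity and F1 follow the usual definitions; a ratio whose denominator
#' is empty is reported as \code{NaN} and flagged in \code{undefined}, never
#' silently set to 0.
#'
#' @param predictions data frame with \code{video_score} and \code{true_label}
#'   columns (as from [predictVideos()]), or a list of
#'   [PredictionRecord-class]; every record must carry a true label.
#' @param threshold confidence threshold.
#' @return a [MetricsReport-class].
#' @examples
#' p <- data.frame(video_score = c(0.9, 0.8, 0.3, 0.1),
#'                 true_label = c("positive", "positive",
#'                                "negative", "negative"))
#' computeMetrics(p, 0.5)
#' @export
computeMetrics <- function(predictions, threshold) {
  p <- .predFrame(predictions)
  if (anyNA(p$true_label)) stop("every record must carry a true label")
  .assertFraction(threshold, "threshold")
  pos <- p$video_score >= threshold
  truth <- p$true_label == "positive"
  tp <- sum(pos & truth); fp <- sum(pos & !truth)
  fn <- sum(!pos & truth); tn <- sum(!pos & !truth)
  undef <- character(0)
  prec <- if (tp + fp == 0) { undef <- c(undef, "precision"); NaN }
          else tp / (tp + fp)
  sens <- if (tp + fn == 0) { undef <- c(undef, "sensitivity"); NaN }
          else tp / (tp + fn)
  f1 <- if (is.nan(prec) || is.nan(sens) || (prec + sens) == 0) {
    undef <- c(undef, "f1"); NaN
  } else 2 * prec * sens / (prec + sens)
  new("MetricsReport", tp = tp, fp = fp, fn = fn, tn = tn,
      accuracy = (tp + tn) / (tp + fp + fn + tn),
      precision = prec, sensitivity = sens, f1 = f1,
      threshold = threshold, undefined = undef)
}

#' Metrics report as a one-row data frame
#'
#' @param report a [MetricsReport-class].
#' @return one-row data frame of counts and metrics.
#' @export
metricsRow <- function(report) {
  data.frame(threshold = report@threshold, tp = report@tp, fp = report@fp,
             fn = report@fn, tn = report@tn, accuracy = report@accuracy,
             precision = report@precision, sensitivity = report@sensitivity,
             f1 = report@f1)
}

#' Confusion matrix normalized to ground-truth counts
#'
#' Rows are the true classes (positive first), columns the predicted classes;
#' each row is normalized by the number of videos of that true class, so a
#' present class row sums to 1. A class with no videos gives an all-\code{NaN}
#' row, flagged in the \code{"emptyRows"} attribute.
#'
#' @inheritParams computeMetrics
#' @return 2x2 numeric matrix with dimnames \code{true x predicted}.
#' @export
confusionMatrixNormalized <- function(predictions, threshold) {
  m <- computeMetrics(predictions, threshold)
  counts <- matrix(c(m@tp, m@fn, m@fp, m@tn), 2L, 2L, byrow = TRUE,
                   dimnames = list(true = c("positive", "negative"),
                                   predicted = c("positive", "negative")))
  rs <- rowSums(counts)
  out <- counts / rs
  attr(out, "emptyRows") <- rownames(counts)[rs == 0]
  out
}

#' ROC curve and trapezoidal AUC over video scores
#'
#' Thresholds are the sorted unique video scores plus sentinels, each applied
#' as "positive iff score >= threshold"; the resulting points are sorted by
#' false-positive rate, include (0,0) and (1,1), and the AUC is their
#' trapezoidal integral (equal to the Mann-Whitney probability with
#' half-credit for ties).
#'
#' @inheritParams computeMetrics
#' @return a [RocCurve-class].
#' @examples
#' p <- data.frame(video_score = c(0.9, 0.6, 0.7, 0.2),
#'                 true_label = c("positive", "positive",
#'                                "negative", "negative"))
#' auc(rocAuc(p))  # 0.75
#' @export
rocAuc <- function(predictions) {
  p <- .predFrame(predictions)
  truth <- p$true_label == "positive"
  if (!any(truth) || all(truth))
    stop("ROC needs both classes present")
  thr <- c(Inf, sort(unique(p$video_score), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(p$video_score[truth] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(p$video_score[!truth] >= t), numeric(1))
  pts <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1)
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  rownames(pts) <- NULL
  aucVal <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                 utils::tail(pts$tpr, -1)) / 2)
  new("RocCurve", points = pts, auc = aucVal)
}

#' Sweep confidence thresholds and select the best
#'
#' Evaluates every grid threshold and selects the one maximizing the chosen
#' criterion (F1 by default; "youden" = sensitivity + specificity - 1;
#' "accuracy"), with ties going to the lower threshold. The study selected
#' 0.75 for the pelvic site and 0.05 for the right upper quadrant by this kind
#' of sweep; such values can be imposed downstream instead of the argmax.
#'
#' @inheritParams computeMetrics
#' @param grid thresholds to evaluate, all in [0, 1]; by default the sorted
#'   unique video scores plus the 0/1 sentinels, i.e. every achievable
#'   operating point of the score set (the ROC thresholds).
#' @param criterion selection criterion.
#' @return list with \code{table} (one row per grid value: counts, metrics,
#'   youden), \code{selected} (the chosen threshold) and \code{criterion}.
#' @export
thresholdSweep <- function(predictions, grid = NULL,
                           criterion = c("f1", "youden", "accuracy")) {
  criterion <- match.arg(criterion)
  if (is.null(grid))
    grid <- unique(c(0, sort(unique(.predFrame(predictions)$video_score)), 1))
  if (any(grid < 0 | grid > 1)) stop("grid must lie within [0, 1]")
  grid <- sort(grid)
  rows <- lapply(grid, function(t) {
    m <- computeMetrics(predictions, t)
    r <- metricsRow(m)
    spec <- if (m@fp + m@tn == 0) NaN else m@tn / (m@fp + m@tn)
    r$youden <- m@sensitivity + spec - 1
    r
  })
  tab <- do.call(rbind, rows)
  crit <- tab[[criterion]]
  crit[is.nan(crit)] <- -Inf
  list(table = tab, selected = grid[which.max(crit)], criterion = criterion)
}

#' Exact McNemar test between two paired classifiers
#'
#' Compares per-video correctness of two models evaluated on the same videos.
#' With \code{b} and \code{c} the discordant counts (videos only one model got
#' right), the exact two-sided p-value is
#' \code{min(1, 2 * P(X <= min(b, c)))} for \code{X ~ Binomial(b + c, 1/2)};
#' the exact form is used because the study's video counts are small (54 and
#' 43). \code{method = "chisq"} gives the continuity-corrected chi-square
#' variant for cross-checking. No discordant videos gives p = 1 with the
#' degeneracy flag set.
#'
#' @param predictionsA,predictionsB data frames (or record lists) for the two
#'   models over the same videos, with \code{video_id},
#'   \code{predicted_label} and \code{true_label}.
#' @param method "exact" (binomial) or "chisq".
#' @return a [McNemarResult-class]; symmetric in its arguments.
#' @examples
#' a <- data.frame(video_id = as.character(1:10),
#'                 predicted_label = rep(c("positive", "negative"), 5),
#'                 true_label = "positive")
#' b <- data.frame(video_id = as.character(1:10),
#'                 predicted_label = "positive", true_label = "positive")
#' pValue(mcnemarTest(a, b))
#' @export
mcnemarTest <- function(predictionsA, predictionsB,
                        method = c("exact", "chisq")) {
  method <- match.arg(method)
  a <- .predFrame2(predictionsA); b <- .predFrame2(predictionsB)
  m <- merge(a, b, by = "video_id", suffixes = c("_a", "_b"))
  if (nrow(m) != nrow(a) || nrow(m) != nrow(b))
    stop("the two prediction sets must cover the same videos")
  if (!all(m$true_label_a == m$true_label_b))
    stop("true labels disagree between the two prediction sets")
  okA <- m$predicted_label_a == m$true_label_a
  okB <- m$predicted_label_b == m$true_label_b
  bb <- sum(okA & !okB); cc <- sum(okB & !okA)
  nd <- bb + cc
  degenerate <- nd == 0L
  p <- if (degenerate) 1 else if (method == "exact") {
    min(1, 2 * stats::pbinom(min(bb, cc), nd, 0.5))
  } else {
    tab <- matrix(c(sum(okA & okB), bb, cc, sum(!okA & !okB)), 2L, 2L)
    unname(stats::mcnemar.test(tab, correct = TRUE)$p.value)
  }
  new("McNemarResult", b = bb, c = cc, nConcordant = nrow(m) - nd,
      pValue = p, method = method, degenerate = degenerate)
}

.predFrame2 <- function(predictions) {
  p <- if (is.data.frame(predictions)) predictions
       else predictionsTable(predictions)
  stopifnot(all(c("video_id", "predicted_label", "true_label") %in% names(p)))
  if (anyNA(p$true_label)) stop("every record must carry a true label")
  if (anyDuplicated(p$video_id)) stop("video_id values must be unique")
  p
}
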