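#' Score pooled windows with a trained model
#'
#' Runs the model in evaluation mode (no augmentation, no stochastic layers)
#' on each window and returns one softmax confidence pair per window, order
#' preserved.
#'
#' @param model a [SonoModel-class].
#' @param windows list of [FrameWindow-class] whose window size matches the
#'   model's input channel count.
#' @param chunkSize windows scored per forward pass.
#' @return numeric matrix with one row per window and columns
#'   \code{p_negative}, \code{p_positive}; rows sum to 1.
#' @export
scoreWindows <- function(model, windows, chunkSize = 64L) {
  stopifnot(is(model, "SonoModel"))
  if (!length(windows)) stop("no windows to score")
  ns <- vapply(windows, windowSize, numeric(1))
  if (any(ns != model@inChannels))
    stop(sprintf("channel mismatch: windows carry %s frames but the model expects %d",
                 paste(unique(ns), collapse = "/"),
                 as.integer(model@inChannels)))
  S <- as.integer(model@inputSize)
  out <- matrix(NA_real_, length(windows), 2L,
                dimnames = list(NULL, c("p_negative", "p_positive")))
  for (bStart in seq.int(1L, length(windows), by = chunkSize)) {
    take <- bStart:min(bStart + chunkSize - 1L, length(windows))
    xb <- .stacksToBatch(lapply(windows[take], function(w)
      .resizeStack(windowStack(w), S)))
    out[take, ] <- t(.softmaxProbs(.forwardTiny(model@params, xb)$logits))
  }
  out
}

#' Aggregate window confidences into a per-video prediction
#'
#' The video score is the arithmetic mean of the per-window positive-class
#' softmax confidences; the video is called positive when the score is greater
#' than or equal to the threshold. The tie goes to positive, consistent with
#' reading any suspicion of injury as a positive call. Padded windows
#' contribute with equal weight.
#'
#' @param windowScores matrix of \code{(p_negative, p_positive)} rows as
#'   returned by [scoreWindows()] (a single pair may be given as a length-2
#'   vector); at least one row.
#' @param threshold confidence threshold in [0, 1].
#' @param videoId,trueLabel metadata carried into the record.
#' @return a [PredictionRecord-class].
#' @examples
#' aggregateVideo(cbind(1 - c(0.9, 0.8, 0.7), c(0.9, 0.8, 0.7)), 0.75)
#' @export
aggregateVideo <- function(windowScores, threshold, videoId = "video",
                           trueLabel = NA_character_) {
  if (is.null(dim(windowScores))) windowScores <- matrix(windowScores, 1L)
  if (!nrow(windowScores)) stop("windowScores must contain at least one window")
  .assertFraction(threshold, "threshold")
  score <- mean(windowScores[, 2L])
  new("PredictionRecord", videoId = videoId, windowScores = windowScores,
      videoScore = score, threshold = threshold,
      predictedLabel = if (score >= threshold) "positive" else "negative",
      trueLabel = if (is.na(trueLabel)) NA_character_
                  else .matchLabel(trueLabel))
}

#' Predict labels for whole videos
#'
#' Windows each video with \code{windowing} (the real-time recipe pools
#' 150-channel windows at 30-s strides, one window per 30-s video; when the
#' cue is intermittent, denser overlapping windows at the training stride are
#' preferable), scores every window, and averages the positive-class
#' confidences into a thresholded per-video prediction.
#'
#' @param model a [SonoModel-class].
#' @param videos list of [FrameVideo-class].
#' @param windowing a [WindowingConfig-class]; its window size must equal the
#'   model's channel count.
#' @param threshold confidence threshold.
#' @return data frame with one row per video: \code{video_id},
#'   \code{n_windows}, \code{video_score}, \code{threshold},
#'   \code{predicted_label}, \code{true_label}. The underlying
#'   [PredictionRecord-class] objects are attached as attribute
#'   \code{"records"}.
#' @export
predictVideos <- function(model, videos, windowing, threshold = 0.5) {
  records <- lapply(videos, function(v) {
    w <- makeWindows(v, windowing)
    aggregateVideo(scoreWindows(model, w), threshold,
                   videoId = videoId(v), trueLabel = videoLabel(v))
  })
  structure(predictionsTable(records), records = records)
}

#' Tabulate prediction records
#'
#' @param records list of [PredictionRecord-class].
#' @return data frame in the predictions-CSV shape (\code{video_id},
#'   \code{n_windows}, \code{video_score}, \code{threshold},
#'   \code{predicted_label}, \code{true_label}).
#' @export
predictionsTable <- function(records) {
  do.call(rbind, lapply(records, function(r) data.frame(
    video_id = r@videoId, n_windows = nrow(r@windowScores),
    video_score = r@videoScore, threshold = r@threshold,
    predicted_label = r@predictedLabel, true_label = r@trueLabel,
    stringsAsFactors = FALSE)))
}
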