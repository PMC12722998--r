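#' Accessors for sonopool objects
#'
#' Small accessor generics so slots are never reached into directly:
#' \code{frames()} returns the frame array, \code{fps()} the frame rate,
#' \code{nFrames()} the temporal length, \code{videoLabel()} the binary label,
#' and so on.
#'
#' @param object a [FrameVideo-class], [FrameWindow-class] or related object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases frames fps videoId subjectId scanSite videoLabel groupTag
#'   nFrames cueFrames cueMask windowSize stride startIndex nPadded
#'   videoScore predictedLabel trueLabel windowScores auc rocPoints pValue
#' @examples
#' cfg <- syntheticConfig(durationS = 1, fps = 10, nSubjects = 2)
#' v <- simulateVideo(cfg, "S01", "positive")
#' nFrames(v)
#' videoLabel(v)
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("fps", function(object) standardGeneric("fps"))
#' @rdname accessors
#' @export
setGeneric("videoId", function(object) standardGeneric("videoId"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("scanSite", function(object) standardGeneric("scanSite"))
#' @rdname accessors
#' @export
setGeneric("videoLabel", function(object) standardGeneric("videoLabel"))
#' @rdname accessors
#' @export
setGeneric("groupTag", function(object) standardGeneric("groupTag"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("cueFrames", function(object) standardGeneric("cueFrames"))
#' @rdname accessors
#' @export
setGeneric("cueMask", function(object) standardGeneric("cueMask"))
#' @rdname accessors
#' @export
setGeneric("windowSize", function(object) standardGeneric("windowSize"))
#' @rdname accessors
#' @export
setGeneric("stride", function(object) standardGeneric("stride"))
#' @rdname accessors
#' @export
setGeneric("startIndex", function(object) standardGeneric("startIndex"))
#' @rdname accessors
#' @export
setGeneric("nPadded", function(object) standardGeneric("nPadded"))
#' @rdname accessors
#' @export
setGeneric("videoScore", function(object) standardGeneric("videoScore"))
#' @rdname accessors
#' @export
setGeneric("predictedLabel", function(object) standardGeneric("predictedLabel"))
#' @rdname accessors
#' @export
setGeneric("trueLabel", function(object) standardGeneric("trueLabel"))
#' @rdname accessors
#' @export
setGeneric("windowScores", function(object) standardGeneric("windowScores"))
#' @rdname accessors
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))
#' @rdname accessors
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

setMethod("frames", "FrameVideo", function(object) object@frames)
setMethod("fps", "FrameVideo", function(object) object@fps)
setMethod("videoId", "FrameVideo", function(object) object@videoId)
setMethod("subjectId", "FrameVideo", function(object) object@subjectId)
setMethod("scanSite", "FrameVideo", function(object) object@scanSite)
setMethod("videoLabel", "FrameVideo", function(object) object@label)
setMethod("groupTag", "FrameVideo", function(object) object@groupTag)
setMethod("nFrames", "FrameVideo", function(object) dim(object@frames)[3L])
setMethod("cueFrames", "FrameVideo", function(object) object@cueFrames)
setMethod("cueMask", "FrameVideo", function(object) object@cueMask)

setMethod("frames", "FrameWindow", function(object) object@frames)
setMethod("videoId", "FrameWindow", function(object) object@videoId)
setMethod("videoLabel", "FrameWindow", function(object) object@label)
setMethod("startIndex", "FrameWindow", function(object) object@startIndex)
setMethod("nPadded", "FrameWindow", function(object) object@nPadded)
setMethod("windowSize", "FrameWindow", function(object) dim(object@frames)[3L])

setMethod("windowSize", "WindowingConfig", function(object) object@windowSize)
setMethod("stride", "WindowingConfig", function(object) object@stride)

setMethod("videoId", "PredictionRecord", function(object) object@videoId)
setMethod("videoScore", "PredictionRecord", function(object) object@videoScore)
setMethod("predictedLabel", "PredictionRecord",
          function(object) object@predictedLabel)
setMethod("trueLabel", "PredictionRecord", function(object) object@trueLabel)
setMethod("windowScores", "PredictionRecord",
          function(object) object@windowScores)

setMethod("auc", "RocCurve", function(object) object@auc)
setMethod("rocPoints", "RocCurve", function(object) object@points)
setMethod("pValue", "McNemarResult", function(object) object@pValue)

setMethod("show", "FrameVideo", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "FrameVideo '%s': %d frames of %dx%d @ %g FPS | subject %s | site %s | %s\n",
    object@videoId, d[3], d[1], d[2], object@fps,
    object@subjectId, object@scanSite, object@label))
  if (length(object@cueFrames))
    cat(sprintf("  cue rendered in %d/%d frames\n",
                length(object@cueFrames), d[3]))
})

setMethod("show", "FrameWindow", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "FrameWindow: video '%s' start %d, %d frames (%d padded), label %s\n",
    object@videoId, object@startIndex, d[3], object@nPadded, object@label))
})

setMethod("show", "SonoModel", function(object) {
  cat(sprintf("SonoModel (%s): %d input channels, %dx%d input\n",
              object@architecture, object@inChannels,
              object@inputSize, object@inputSize))
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("  %d trainable parameters\n", np))
  if (nrow(object@history)) {
    b <- object@meta$bestEpoch
    if (b >= 1)
      cat(sprintf("  trained %d epochs; best epoch %s (val loss %.4f, val acc %.3f)\n",
                  nrow(object@history), b,
                  object@history$val_loss[b], object@history$val_acc[b]))
    else
      cat(sprintf("  trained %d epochs; warm-start weights retained (epoch 0)\n",
                  nrow(object@history)))
  } else cat("  untrained\n")
})

setMethod("show", "PredictionRecord", function(object) {
  cat(sprintf(
    "PredictionRecord '%s': %d windows, video score %.4f, threshold %.3f -> %s",
    object@videoId, nrow(object@windowScores), object@videoScore,
    object@threshold, object@predictedLabel))
  if (!is.na(object@trueLabel)) cat(sprintf(" (truth: %s)", object@trueLabel))
  cat("\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport @ threshold %.3f\n", object@threshold))
  cat(sprintf("  tp %d  fp %d  fn %d  tn %d\n",
              object@tp, object@fp, object@fn, object@tn))
  cat(sprintf("  accuracy %.4f  precision %.4f  sensitivity %.4f  F1 %.4f\n",
              object@accuracy, object@precision, object@sensitivity,
              object@f1))
  if (length(object@undefined))
    cat("  undefined:", paste(object@undefined, collapse = ", "), "\n")
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d points, AUC %.4f\n",
              nrow(object@points), object@auc))
})

setMethod("show", "McNemarResult", function(object) {
  cat(sprintf("McNemar (%s): b = %d, c = %d, concordant = %d, p = %.6g\n",
              object@method, object@b, object@c, object@nConcordant,
              object@pValue))
  if (object@degenerate) cat("  no discordant pairs; p fixed at 1\n")
})
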