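#' @import methods
NULL

#' Configuration of the synthetic ultrasound-sweep generator
#'
#' Parameters of the simulated B-mode sweep: image geometry, speckle, the dark
#' elliptical organ and its drift (probe motion), the anechoic fluid cue shown
#' in a fraction of frames of positive videos, and the dataset layout
#' (subjects, videos per subject, class balance).
#'
#' @slot imageHeight,imageWidth frame size in pixels (>= 32).
#' @slot fps frames per second of the sweep (capture default 30).
#' @slot durationS sweep duration in seconds (capture default 30);
#'   \code{fps * durationS} must be an integer frame count.
#' @slot speckleScale Rayleigh scale of the multiplicative speckle field;
#'   the default \code{sqrt(2/pi)} gives the speckle multiplier unit mean.
#' @slot organCenter,organRadii fractional (row, col) center and radii of the
#'   dark organ ellipse.
#' @slot organDriftAmplitude sinusoidal drift of the organ center, in pixels,
#'   emulating probe motion over the sweep.
#' @slot fluidVisibilityFraction fraction of frames (contiguous block) in which
#'   the anechoic crescent is rendered for positive videos.
#' @slot fluidContrast nominal relative intensity depression of the crescent
#'   in [0, 1].
#' @slot severityRange per-video injury-severity multipliers on
#'   \code{fluidContrast}, emulating the spread from slight small pockets to
#'   obvious large accumulations; drawn once per positive video.
#' @slot nSubjects,videosPerSubject,positiveFraction dataset layout.
#' @slot nGroups number of capture-experiment groups subjects are cycled over.
#' @slot scanSite scan-site tag stamped on generated videos ("BLD" or "RUQ").
#' @slot seed base seed; identical configuration and seed give bit-identical
#'   frame buffers.
#' @seealso [syntheticConfig()], [simulateVideo()], [simulateDataset()]
#' @export
setClass("SyntheticConfig", representation(
  imageHeight = "numeric", imageWidth = "numeric",
  fps = "numeric", durationS = "numeric",
  speckleScale = "numeric",
  organCenter = "numeric", organRadii = "numeric",
  organDriftAmplitude = "numeric",
  fluidVisibilityFraction = "numeric", fluidContrast = "numeric",
  severityRange = "numeric",
  nSubjects = "numeric", videosPerSubject = "numeric",
  positiveFraction = "numeric", nGroups = "numeric",
  scanSite = "character", seed = "numeric"
))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@imageHeight < 32 || object@imageWidth < 32)
    msg <- c(msg, "pixel dimensions must be >= 32")
  tf <- object@fps * object@durationS
  if (abs(tf - round(tf)) > 1e-9 || round(tf) < 1)
    msg <- c(msg, "fps * durationS must be a positive integer frame count")
  for (f in c("fluidVisibilityFraction", "fluidContrast", "positiveFraction")) {
    v <- slot(object, f)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("'%s' must lie in [0, 1]", f))
  }
  if (length(object@organCenter) != 2L || length(object@organRadii) != 2L)
    msg <- c(msg, "organCenter and organRadii must each have length 2")
  if (object@speckleScale <= 0) msg <- c(msg, "speckleScale must be positive")
  if (length(object@severityRange) != 2L || diff(object@severityRange) < 0 ||
      any(object@severityRange < 0))
    msg <- c(msg, "severityRange must be an increasing non-negative pair")
  if (object@nSubjects < 1 || object@videosPerSubject < 1)
    msg <- c(msg, "nSubjects and videosPerSubject must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A labeled grayscale ultrasound video
#'
#' An ordered stack of 8-bit grayscale frames from one sweep, with capture
#' metadata and a single binary injury label. Frames are stored as an
#' \code{H x W x T} integer array with intensities in 0..255; the third
#' dimension is the temporal order of the sweep.
#'
#' The generator additionally fills the ground-truth side channel
#' (\code{cueFrames}, \code{cueMask}: which frames render the fluid crescent,
#' and the nominal crescent region). These slots exist for oracle checks only
#' and are never consumed by the classifier path; videos loaded from disk leave
#' them empty.
#'
#' @slot frames integer array, \code{H x W x T}, values in 0..255.
#' @slot fps frames per second.
#' @slot videoId,subjectId,groupTag identifiers.
#' @slot scanSite scan site ("BLD" or "RUQ").
#' @slot label "negative" or "positive"; constant for the whole video.
#' @slot cueFrames integer vector of 1-based frame indices that render the cue.
#' @slot cueMask logical \code{H x W} matrix of the nominal cue region.
#' @export
setClass("FrameVideo", representation(
  frames = "array", fps = "numeric",
  videoId = "character", subjectId = "character",
  scanSite = "character", label = "character", groupTag = "character",
  cueFrames = "integer", cueMask = "matrix"
))

setValidity("FrameVideo", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L || d[3] < 1L)
    msg <- c(msg, "frames must be an H x W x T array with T >= 1")
  if (!is.numeric(object@frames) ||
      anyNA(object@frames) ||
      min(object@frames) < 0 || max(object@frames) > 255)
    msg <- c(msg, "frame intensities must lie in [0, 255]")
  if (!(object@label %in% .LABELS))
    msg <- c(msg, "label must be 'negative' or 'positive'")
  if (length(object@cueFrames) &&
      (min(object@cueFrames) < 1L || max(object@cueFrames) > d[3]))
    msg <- c(msg, "cueFrames out of range")
  if (length(msg)) msg else TRUE
})

#' Sliding-window configuration for frame pooling
#'
#' @slot windowSize number of consecutive frames pooled into one model input
#'   (channel count); study values 1, 30, 90, 150.
#' @slot stride frame offset between window starts (training default 15;
#'   real-time inference default 900, i.e. one window per 30 s at 30 FPS).
#' @slot paddingPolicy how windows extending past the last frame are completed;
#'   only \code{"repeat_last"} is defined (repeating the final frame preserves
#'   intensity statistics, whereas zero padding would inject an artificial
#'   anechoic signal that mimics fluid).
#' @export
setClass("WindowingConfig", representation(
  windowSize = "numeric", stride = "numeric", paddingPolicy = "character"
))

setValidity("WindowingConfig", function(object) {
  msg <- character()
  if (object@windowSize < 1) msg <- c(msg, "windowSize must be >= 1")
  if (object@stride < 1) msg <- c(msg, "stride must be >= 1")
  if (!identical(object@paddingPolicy, "repeat_last"))
    msg <- c(msg, "paddingPolicy must be 'repeat_last'")
  if (length(msg)) msg else TRUE
})

#' A pooled frame window
#'
#' \code{windowSize} consecutive (possibly end-padded) frames from one video;
#' the model's input unit. Frame indices are 0-based and windows are half-open
#' \code{[start, start + n)}.
#'
#' @slot frames integer array \code{H x W x n}, 0..255.
#' @slot videoId source video.
#' @slot startIndex 0-based index of the first frame.
#' @slot nPadded number of trailing frames that are copies of the final video
#'   frame; always \code{0 <= nPadded < n}.
#' @slot label label inherited from the source video.
#' @export
setClass("FrameWindow", representation(
  frames = "array", videoId = "character",
  startIndex = "numeric", nPadded = "numeric", label = "character"
))

setValidity("FrameWindow", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L) msg <- c(msg, "frames must be H x W x n")
  if (object@nPadded < 0 || object@nPadded >= d[3])
    msg <- c(msg, "nPadded must satisfy 0 <= nPadded < n")
  if (object@startIndex < 0) msg <- c(msg, "startIndex must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Training hyperparameters
#'
#' Defaults follow the study recipe: batch size 32, Adam with learning rate
#' 0.001, early stopping after 10 epochs without validation-loss improvement,
#' a maximum of 100 epochs (200 when training from scratch with Kaiming
#' initialization), and an 80/20 train/validation split by subject.
#'
#' @slot architecture backbone name; \code{"tiny_cnn"} is the supported
#'   backbone (three 3x3 conv blocks with average pooling, global average
#'   pooling, and a 2-logit head).
#' @slot inChannels number of pooled frames per input (the window size).
#' @slot inputSize square spatial resolution inputs are resampled to.
#' @slot init \code{"kaiming_scratch"} or \code{"pretrained_inflate"}.
#' @slot batchSize,learningRate,maxEpochs,earlyStopPatience optimizer recipe.
#' @slot splitFraction fraction of subjects assigned to training.
#' @slot seed seed governing initialization, shuffling and augmentation.
#' @export
setClass("TrainConfig", representation(
  architecture = "character", inChannels = "numeric", inputSize = "numeric",
  init = "character", batchSize = "numeric", learningRate = "numeric",
  maxEpochs = "numeric", earlyStopPatience = "numeric",
  splitFraction = "numeric", seed = "numeric"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@batchSize < 1) msg <- c(msg, "batchSize must be >= 1")
  if (object@splitFraction <= 0 || object@splitFraction >= 1)
    msg <- c(msg, "splitFraction must lie in (0, 1)")
  if (object@earlyStopPatience >= object@maxEpochs)
    msg <- c(msg, "earlyStopPatience must be smaller than maxEpochs")
  if (object@inChannels < 1) msg <- c(msg, "inChannels must be >= 1")
  if (object@inputSize %% 8 != 0)
    msg <- c(msg, "inputSize must be a multiple of 8 (three 2x2 poolings)")
  if (length(msg)) msg else TRUE
})

#' Augmentation parameters
#'
#' One crop rectangle, one jitter triple and one flip decision are drawn per
#' window and applied identically to every channel, so the temporal structure
#' pooling relies on is preserved. Saturation jitter is drawn for parity with
#' the usual colour-jitter pipeline but is a no-op on single-intensity
#' channels.
#'
#' @slot cropScaleRange random crop area as a fraction of the frame (0.8-1.0).
#' @slot cropAspectRange aspect-ratio range of the crop (3/4-4/3).
#' @slot brightnessJitter,contrastJitter,saturationJitter half-widths of the
#'   multiplicative jitter factors (0.20, 0.10, 0.10).
#' @slot hflipProbability probability of a horizontal flip (0.5).
#' @export
setClass("AugmentConfig", representation(
  cropScaleRange = "numeric", cropAspectRange = "numeric",
  brightnessJitter = "numeric", contrastJitter = "numeric",
  saturationJitter = "numeric", hflipProbability = "numeric"
))

setValidity("AugmentConfig", function(object) {
  msg <- character()
  if (length(object@cropScaleRange) != 2L ||
      diff(object@cropScaleRange) < 0 ||
      any(object@cropScaleRange <= 0) || any(object@cropScaleRange > 1))
    msg <- c(msg, "cropScaleRange must be an increasing pair in (0, 1]")
  if (length(object@cropAspectRange) != 2L || diff(object@cropAspectRange) < 0)
    msg <- c(msg, "cropAspectRange must be an increasing pair")
  .ok <- function(x) length(x) == 1L && x >= 0
  if (!.ok(object@brightnessJitter) || !.ok(object@contrastJitter) ||
      !.ok(object@saturationJitter))
    msg <- c(msg, "jitter half-widths must be single non-negative values")
  if (object@hflipProbability < 0 || object@hflipProbability > 1)
    msg <- c(msg, "hflipProbability must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' A trained (or freshly initialized) pooled-frame classifier
#'
#' @slot architecture backbone name.
#' @slot inChannels input channel count (frames per window).
#' @slot inputSize square input resolution.
#' @slot params named list of weight arrays.
#' @slot history per-epoch training record (epoch, train/validation loss and
#'   accuracy); empty until [trainModel()] is run.
#' @slot seed seed the weights were drawn (or training was run) under.
#' @slot meta free-form provenance (configs, best epoch, ...).
#' @export
setClass("SonoModel", representation(
  architecture = "character", inChannels = "numeric", inputSize = "numeric",
  params = "list", history = "data.frame", seed = "numeric", meta = "list"
))

#' Per-video prediction record
#'
#' Window-level softmax confidence pairs, their per-video average, and the
#' thresholded label. The video score is the arithmetic mean of the
#' positive-class confidences; a video is called positive when the score is
#' greater than or equal to the threshold (ties go to positive).
#'
#' @slot videoId video identifier.
#' @slot windowScores numeric matrix, one row per window, columns
#'   \code{(p_negative, p_positive)}; each row sums to 1.
#' @slot videoScore mean of the positive-class column.
#' @slot threshold confidence threshold used for the label.
#' @slot predictedLabel "negative" or "positive".
#' @slot trueLabel ground truth, or \code{NA} when unknown.
#' @export
setClass("PredictionRecord", representation(
  videoId = "character", windowScores = "matrix", videoScore = "numeric",
  threshold = "numeric", predictedLabel = "character", trueLabel = "character"
))

setValidity("PredictionRecord", function(object) {
  msg <- character()
  ws <- object@windowScores
  if (nrow(ws) < 1L || ncol(ws) != 2L)
    msg <- c(msg, "windowScores must be a k x 2 matrix with k >= 1")
  else {
    if (any(abs(rowSums(ws) - 1) > 1e-6))
      msg <- c(msg, "each softmax pair must sum to 1 (tolerance 1e-6)")
    if (abs(object@videoScore - mean(ws[, 2L])) > 1e-9)
      msg <- c(msg, "videoScore must equal the mean positive-class confidence")
  }
  want <- if (object@videoScore >= object@threshold) "positive" else "negative"
  if (!identical(object@predictedLabel, want))
    msg <- c(msg, "predictedLabel inconsistent with videoScore and threshold")
  if (length(msg)) msg else TRUE
})

#' Confusion counts and derived performance metrics at one threshold
#'
#' Accuracy, precision, sensitivity and F1 computed from video-level confusion
#' counts. Ratios with an empty denominator are reported as \code{NaN} and
#' listed in \code{undefined}, never silently set to 0.
#'
#' @slot tp,fp,fn,tn video counts.
#' @slot accuracy,precision,sensitivity,f1 fractions in [0, 1] (or \code{NaN}).
#' @slot threshold threshold the counts were computed at.
#' @slot undefined names of metrics whose denominator was empty.
#' @export
setClass("MetricsReport", representation(
  tp = "numeric", fp = "numeric", fn = "numeric", tn = "numeric",
  accuracy = "numeric", precision = "numeric", sensitivity = "numeric",
  f1 = "numeric", threshold = "numeric", undefined = "character"
))

#' Receiver operating characteristic curve
#'
#' @slot points data frame with columns \code{threshold}, \code{fpr},
#'   \code{tpr}, sorted by increasing false-positive rate and including the
#'   (0,0) and (1,1) endpoints.
#' @slot auc trapezoidal area under the curve.
#' @export
setClass("RocCurve", representation(points = "data.frame", auc = "numeric"))

#' Paired McNemar comparison of two classifiers
#'
#' @slot b videos the first model got right and the second wrong.
#' @slot c videos the second model got right and the first wrong.
#' @slot nConcordant videos where both were right or both wrong.
#' @slot pValue two-sided p-value.
#' @slot method "exact" (binomial) or "chisq" (continuity-corrected).
#' @slot degenerate \code{TRUE} when there were no discordant videos
#'   (\code{b + c == 0}), in which case \code{pValue} is 1.
#' @export
setClass("McNemarResult", representation(
  b = "numeric", c = "numeric", nConcordant = "numeric",
  pValue = "numeric", method = "character", degenerate = "logical"
))
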