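#' Create a synthetic-sweep configuration
#'
#' Defaults emulate the capture recipe of the study data (30-s sweeps at 30
#' FPS) at a desk-scale 64x64 resolution, with a dark drifting organ ellipse,
#' fully developed multiplicative Rayleigh speckle, and — for positive videos —
#' an anechoic crescent lateral to the organ rendered only in a contiguous
#' block of frames (the cue entering and leaving the imaging plane during the
#' sweep). With the default \code{fluidVisibilityFraction = 0.2},
#' single-frame classification is label-noisy while multi-frame pooling can
#' recover the video label.
#'
#' @param imageHeight,imageWidth frame size in pixels (>= 32).
#' @param fps frames per second.
#' @param durationS duration in seconds; \code{fps * durationS} must be an
#'   integer.
#' @param speckleScale Rayleigh scale of the speckle multiplier; the default
#'   \code{sqrt(2/pi)} normalizes the multiplier to unit mean.
#' @param organCenter,organRadii fractional (row, col) organ geometry.
#' @param organDriftAmplitude probe-motion drift in pixels.
#' @param fluidVisibilityFraction fraction of frames rendering the cue in
#'   positive videos.
#' @param fluidContrast nominal relative intensity depression of the cue.
#' @param severityRange range of the per-video severity multiplier applied to
#'   \code{fluidContrast} for positive videos, emulating the clinical spread
#'   from slight small pockets to obvious accumulations.
#' @param nSubjects,videosPerSubject,positiveFraction dataset layout.
#' @param nGroups number of capture-experiment groups.
#' @param scanSite scan-site tag ("BLD" or "RUQ").
#' @param seed base seed.
#' @return a validated [SyntheticConfig-class].
#' @examples
#' cfg <- syntheticConfig(durationS = 3)
#' framesPerVideo(cfg)
#' @export
syntheticConfig <- function(imageHeight = 64, imageWidth = 64,
                            fps = 30, durationS = 30,
                            speckleScale = sqrt(2 / pi),
                            organCenter = c(0.45, 0.5),
                            organRadii = c(0.24, 0.2),
                            organDriftAmplitude = 2,
                            fluidVisibilityFraction = 0.2,
                            fluidContrast = 0.25,
                            severityRange = c(0.5, 1.5),
                            nSubjects = 8, videosPerSubject = 4,
                            positiveFraction = 0.5, nGroups = 1,
                            scanSite = c("BLD", "RUQ"), seed = 1) {
  scanSite <- match.arg(scanSite)
  new("SyntheticConfig",
      imageHeight = imageHeight, imageWidth = imageWidth,
      fps = fps, durationS = durationS, speckleScale = speckleScale,
      organCenter = organCenter, organRadii = organRadii,
      organDriftAmplitude = organDriftAmplitude,
      fluidVisibilityFraction = fluidVisibilityFraction,
      fluidContrast = fluidContrast, severityRange = severityRange,
      nSubjects = nSubjects, videosPerSubject = videosPerSubject,
      positiveFraction = positiveFraction, nGroups = nGroups,
      scanSite = scanSite, seed = seed)
}

#' Number of frames per simulated video
#'
#' @param config a [SyntheticConfig-class].
#' @return integer frame count \code{fps * durationS}.
#' @export
framesPerVideo <- function(config) {
  tf <- config@fps * config@durationS
  if (abs(tf - round(tf)) > 1e-9)
    stop("configuration error: fps * durationS is not an integer frame count")
  as.integer(round(tf))
}

## Nominal (undrifted) organ and crescent masks for a config. The crescent is
## the lateral (right-of-center) band of an elliptical shell hugging the organ.
.sweepMasks <- function(config) {
  H <- config@imageHeight; W <- config@imageWidth
  rr <- config@organRadii[1] * H; rc <- config@organRadii[2] * W
  cr <- config@organCenter[1] * H; cc <- config@organCenter[2] * W
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  d2 <- ((rows - cr) / rr)^2 + ((cols - cc) / rc)^2
  organ <- d2 <= 1
  crescent <- d2 > 1.10^2 & d2 <= 1.30^2 & (cols - cc) >= 0.55 * rc
  list(rows = rows, cols = cols, organ = organ, crescent = crescent,
       cr = cr, cc = cc, rr = rr, rc = rc)
}

#' Simulate one labeled ultrasound-like sweep video
#'
#' Renders \code{fps * durationS} frames: a depth-attenuated tissue background
#' with a dark elliptical organ whose center drifts sinusoidally
#' (\code{organDriftAmplitude} pixels, emulating probe motion), multiplied by
#' per-pixel Rayleigh speckle and quantized to 8 bits. For positive videos an
#' anechoic crescent adjacent to the organ (intensity depressed by
#' \code{fluidContrast}) is rendered in exactly
#' \code{round(fluidVisibilityFraction * T)} frames, chosen as a contiguous
#' block positioned by the seeded generator. The rendered cue frames and the
#' nominal crescent region are recorded in the video's ground-truth side
#' channel for oracle checks; the classifier path never reads them.
#'
#' Output is bit-identical for identical configuration and seed.
#'
#' @param config a [SyntheticConfig-class].
#' @param subjectId subject identifier stamped on the video.
#' @param label "negative" or "positive".
#' @param videoId video identifier (defaults to subject + label).
#' @param groupTag capture-experiment group tag.
#' @return a [FrameVideo-class].
#' @examples
#' cfg <- syntheticConfig(fps = 10, durationS = 3,
#'                        fluidVisibilityFraction = 0.3)
#' v <- simulateVideo(cfg, "S01", "positive")
#' length(cueFrames(v))  # 9 of 30 frames carry the cue
#' @export
simulateVideo <- function(config, subjectId, label,
                          videoId = sprintf("%s_%s", subjectId, label),
                          groupTag = "G1") {
  validObject(config)
  label <- .matchLabel(label)
  nT <- framesPerVideo(config)
  H <- config@imageHeight; W <- config@imageWidth
  m <- .sweepMasks(config)

  .withSeed(.deriveSeed(config@seed, subjectId, videoId, label), {
    phase <- stats::runif(1, 0, 2 * pi)
    severity <- stats::runif(1, config@severityRange[1],
                             config@severityRange[2])
    fcEff <- min(1, config@fluidContrast * severity)
    nCue <- as.integer(round(config@fluidVisibilityFraction * nT))
    cue <- integer(0)
    if (label == "positive" && nCue > 0) {
      blockStart <- if (nCue >= nT) 0L else sample.int(nT - nCue + 1L, 1L) - 1L
      cue <- blockStart + seq_len(nCue)
    }

    depth <- 0.78 - 0.18 * (m$rows - 1) / (H - 1)  # mild depth attenuation
    A <- config@organDriftAmplitude
    meanSpeck <- config@speckleScale * sqrt(pi / 2)
    fr <- array(0L, dim = c(H, W, nT))
    for (t in seq_len(nT)) {
      dr <- A * sin(2 * pi * (t - 1) / nT + phase)
      dc <- 0.5 * A * cos(2 * pi * (t - 1) / nT + phase)
      d2 <- ((m$rows - m$cr - dr) / m$rr)^2 + ((m$cols - m$cc - dc) / m$rc)^2
      img <- depth
      img[d2 <= 1] <- 0.12
      if (t %in% cue) {
        cres <- d2 > 1.10^2 & d2 <= 1.30^2 & (m$cols - m$cc - dc) >= 0.55 * m$rc
        img[cres] <- img[cres] * (1 - fcEff)
      }
      ## fully developed speckle: Rayleigh multiplier, unit mean at the
      ## default scale (Rayleigh mean is scale * sqrt(pi/2))
      speck <- config@speckleScale *
        sqrt(-2 * log(stats::runif(H * W))) / meanSpeck
      img <- img * speck
      img[img < 0] <- 0; img[img > 1] <- 1
      fr[, , t] <- as.integer(round(255 * img))
    }
    new("FrameVideo", frames = fr, fps = config@fps,
        videoId = videoId, subjectId = subjectId,
        scanSite = config@scanSite, label = label, groupTag = groupTag,
        cueFrames = as.integer(cue), cueMask = m$crescent)
  })
}

## Per-subject positive counts: floor everywhere, then distribute the remaining
## positives (to match the rounded global target) over the first subjects.
.positiveCounts <- function(nSubjects, videosPerSubject, positiveFraction) {
  perSub <- positiveFraction * videosPerSubject
  base <- floor(perSub)
  total <- round(positiveFraction * nSubjects * videosPerSubject)
  extra <- total - base * nSubjects
  counts <- rep(base, nSubjects)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1
  if (abs(perSub - round(perSub)) > 1e-9)
    warning(sprintf(
      "positiveFraction * videosPerSubject = %.2f is not an integer; %s",
      perSub, "per-subject positive counts adjusted by +-1"), call. = FALSE)
  as.integer(counts)
}

#' Simulate a labeled dataset of sweep videos
#'
#' Generates \code{nSubjects * videosPerSubject} videos with the class balance
#' \code{positiveFraction} respected per subject up to rounding, subjects
#' cycled over \code{nGroups} capture-experiment groups, and a manifest row per
#' video. Mirrors a capture protocol in which the same number of clips is
#' recorded pre- and post-injury, giving an even class distribution.
#'
#' @param config a [SyntheticConfig-class]; requires \code{nSubjects >= 2}.
#' @return a list with elements \code{videos} (list of [FrameVideo-class]) and
#'   \code{manifest} (data frame with columns \code{video_id},
#'   \code{subject_id}, \code{scan_site}, \code{label}, \code{group_tag},
#'   \code{n_frames}, \code{fps}, \code{path}; \code{path} is \code{NA} until
#'   the dataset is written with [writeDataset()]).
#' @examples
#' ds <- simulateDataset(syntheticConfig(durationS = 1, fps = 5,
#'                                       nSubjects = 2, videosPerSubject = 2))
#' ds$manifest[, c("video_id", "label")]
#' @export
simulateDataset <- function(config) {
  validObject(config)
  if (config@nSubjects < 2) stop("simulateDataset needs nSubjects >= 2")
  S <- as.integer(config@nSubjects)
  V <- as.integer(config@videosPerSubject)
  nPos <- .positiveCounts(S, V, config@positiveFraction)
  subjects <- sprintf("S%02d", seq_len(S))
  groups <- sprintf("G%d", ((seq_len(S) - 1L) %% as.integer(config@nGroups)) + 1L)

  videos <- vector("list", S * V)
  rows <- vector("list", S * V)
  k <- 0L
  for (i in seq_len(S)) {
    labels <- c(rep("positive", nPos[i]), rep("negative", V - nPos[i]))
    for (j in seq_len(V)) {
      k <- k + 1L
      vid <- sprintf("%s_v%02d", subjects[i], j)
      v <- simulateVideo(config, subjects[i], labels[j],
                         videoId = vid, groupTag = groups[i])
      videos[[k]] <- v
      rows[[k]] <- data.frame(
        video_id = vid, subject_id = subjects[i],
        scan_site = config@scanSite, label = labels[j],
        group_tag = groups[i], n_frames = nFrames(v), fps = config@fps,
        path = NA_character_, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  names(videos) <- manifest$video_id
  list(videos = videos, manifest = manifest)
}
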