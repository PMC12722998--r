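## Independent brute-force oracles used by the unit and acceptance tests.
## These deliberately avoid the package's own formulas wherever possible.

## Enumerate window starts one by one and derive padding by simulating the
## actual frame indices taken.
bruteWindows <- function(nFrames, windowSize, strideLen) {
  starts <- integer(0)
  k <- 0L
  while (k * strideLen < nFrames) {
    starts <- c(starts, as.integer(k * strideLen))
    k <- k + 1L
  }
  nPadded <- vapply(starts, function(s) {
    idx <- s + seq_len(windowSize) - 1L   # 0-based frame indices
    sum(idx > nFrames - 1L)
  }, integer(1))
  data.frame(start = starts, n_padded = nPadded)
}

## Confusion counts by explicit per-video loop.
bruteCounts <- function(scores, labels, threshold) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(scores)) {
    called <- scores[i] >= threshold
    pos <- labels[i] == "positive"
    if (called && pos) tp <- tp + 1L
    else if (called && !pos) fp <- fp + 1L
    else if (!called && pos) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

## Mann-Whitney AUC by exhaustive pairwise comparison with half-credit ties.
bruteAuc <- function(scores, labels) {
  ps <- scores[labels == "positive"]
  ns <- scores[labels == "negative"]
  tot <- 0
  for (p in ps) for (n in ns)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(ps) * length(ns))
}

## Exact two-sided McNemar p by direct binomial summation.
bruteMcnemarP <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  tail <- sum(vapply(0:k, function(i) choose(n, i) * 0.5^n, numeric(1)))
  min(1, 2 * tail)
}

## Predictions data frame from raw scores/labels.
predFrame <- function(scores, labels, threshold = 0.5) {
  data.frame(video_id = sprintf("v%03d", seq_along(scores)),
             n_windows = 1L, video_score = scores, threshold = threshold,
             predicted_label = ifelse(scores >= threshold,
                                      "positive", "negative"),
             true_label = labels, stringsAsFactors = FALSE)
}

## Augmentation configuration that is the identity (up to resampling).
noAugment <- function() {
  augmentConfig(cropScaleRange = c(1, 1), cropAspectRange = c(1, 1),
                brightnessJitter = 0, contrastJitter = 0,
                saturationJitter = 0, hflipProbability = 0)
}

## All permutations of seq_len(n) (n small).
allPerms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in allPerms(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

## A small, quickly simulated dataset for training-path tests.
tinyTrainingSetup <- function(seed = 3, fluidContrast = 0.7,
                              fluidVisibilityFraction = 1.0) {
  cfg <- syntheticConfig(fps = 10, durationS = 2, imageHeight = 48,
                         imageWidth = 48,
                         fluidVisibilityFraction = fluidVisibilityFraction,
                         fluidContrast = fluidContrast,
                         severityRange = c(1, 1),
                         nSubjects = 6, videosPerSubject = 2, seed = seed)
  ds <- simulateDataset(cfg)
  split <- splitBySubject(ds$manifest, 0.8, seed = 1)
  wcfg <- windowingConfig(1, 5)
  getW <- function(subs)
    unlist(lapply(ds$videos[ds$manifest$subject_id %in% subs],
                  makeWindows, config = wcfg), recursive = FALSE)
  list(train = getW(split$train), val = getW(split$validation),
       dataset = ds, windowing = wcfg)
}

## A miniature end-to-end experiment configuration (fast pipeline runs).
microExperimentConfig <- function(seed = 5) {
  list(
    seed = seed,
    dataset = list(imageHeight = 48, imageWidth = 48, fps = 10, durationS = 2,
                   fluidVisibilityFraction = 0.5, fluidContrast = 0.5,
                   severityRange = c(1, 1),
                   nSubjects = 4, videosPerSubject = 2,
                   positiveFraction = 0.5),
    models = list(
      single = list(windowSize = 1, stride = 4,
                    train = list(maxEpochs = 3, earlyStopPatience = 2)),
      pooled = list(windowSize = 5, stride = 4, initFrom = "single",
                    train = list(maxEpochs = 3, earlyStopPatience = 2,
                                 init = "pretrained_inflate"))),
    train = list(inputSize = 32, batchSize = 16, learningRate = 0.001,
                 splitFraction = 0.8),
    augment = list(),
    testSubjects = 1,
    thresholdCriterion = "f1",
    compare = c("pooled", "single")
  )
}
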