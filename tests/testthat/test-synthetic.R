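test_that("simulated videos have the configured frame count and cue placement", {
  cfg <- syntheticConfig(fps = 30, durationS = 30, nSubjects = 2)
  expect_identical(framesPerVideo(cfg), 900L)

  neg <- simulateVideo(syntheticConfig(fps = 5, durationS = 2), "S01",
                       "negative")
  expect_identical(nFrames(neg), 10L)
  expect_length(cueFrames(neg), 0L)

  allcfg <- syntheticConfig(fps = 5, durationS = 2,
                            fluidVisibilityFraction = 1.0)
  pos <- simulateVideo(allcfg, "S01", "positive")
  expect_identical(cueFrames(pos), 1:10)

  expect_error(syntheticConfig(fps = 7, durationS = 2.21, nSubjects = 2),
               "integer frame count")
})

test_that("cue frames form one contiguous block recoverable from pixel data", {
  ## probe motion off so the static ground-truth mask is exact
  cfg <- syntheticConfig(fps = 10, durationS = 3,
                         fluidVisibilityFraction = 0.3, fluidContrast = 0.4,
                         severityRange = c(1, 1), organDriftAmplitude = 0,
                         seed = 21)
  v <- simulateVideo(cfg, "S01", "positive")
  cue <- cueFrames(v)
  expect_length(cue, 9L)                       # round(0.3 * 30)
  expect_identical(cue, min(cue):max(cue))     # contiguous block

  ## oracle: frames whose crescent-region mean drops well below the
  ## per-video background level are exactly the rendered cue frames
  m <- cueMask(v)
  region <- vapply(seq_len(nFrames(v)),
                   function(t) mean(frames(v)[, , t][m]), numeric(1))
  bg <- stats::median(region)
  expect_identical(which(region < bg * (1 - cfg@fluidContrast / 2)), cue)
})

test_that("negative videos carry no signal in the crescent region", {
  cfg <- syntheticConfig(fps = 10, durationS = 3, seed = 8)
  vn <- simulateVideo(cfg, "S05", "negative")
  vp <- simulateVideo(cfg, "S05", "positive")
  m <- cueMask(vn)
  regionMean <- function(v, frames_) mean(vapply(frames_, function(t)
    mean(frames(v)[, , t][m]), numeric(1)))
  nonCue <- setdiff(seq_len(nFrames(vp)), cueFrames(vp))
  ## matched control: the same region in cue-free frames of a positive sweep
  neg <- regionMean(vn, seq_len(nFrames(vn)))
  ctl <- regionMean(vp, nonCue)
  cue <- regionMean(vp, cueFrames(vp))
  expect_lt(abs(neg - ctl) / ctl, 0.02)   # indistinguishable without the cue
  expect_lt(cue, 0.95 * neg)              # the rendered cue is a real signal
})

test_that("dataset generation is deterministic and respects class balance", {
  cfg <- syntheticConfig(fps = 5, durationS = 1, nSubjects = 4,
                         videosPerSubject = 2, positiveFraction = 0.5,
                         seed = 7)
  ds1 <- simulateDataset(cfg)
  ds2 <- simulateDataset(cfg)
  expect_identical(lapply(ds1$videos, frames), lapply(ds2$videos, frames))
  expect_identical(nrow(ds1$manifest), 8L)
  expect_identical(sum(ds1$manifest$label == "positive"), 4L)

  ## non-realizable per-subject count: warned, adjusted by +-1
  cfg3 <- syntheticConfig(fps = 5, durationS = 1, nSubjects = 3,
                          videosPerSubject = 3, positiveFraction = 0.5)
  expect_warning(ds3 <- simulateDataset(cfg3), "adjusted")
  perSub <- tapply(ds3$manifest$label == "positive",
                   ds3$manifest$subject_id, sum)
  expect_true(all(perSub %in% 1:2))
  expect_true(sum(perSub) %in% 4:5)
})

test_that("single-frame oracle difficulty rises as cue visibility falls", {
  oracleAcc <- function(fvf) {
    cfg <- syntheticConfig(fps = 10, durationS = 3,
                           fluidVisibilityFraction = fvf,
                           fluidContrast = 0.4, severityRange = c(1, 1),
                           seed = 400 + round(100 * fvf))
    region <- c(); lab <- c()
    for (s in 1:3) {
      vp <- simulateVideo(cfg, sprintf("P%d", s), "positive")
      vn <- simulateVideo(cfg, sprintf("N%d", s), "negative")
      m <- cueMask(vp)
      region <- c(region,
                  vapply(seq_len(nFrames(vp)),
                         function(t) mean(frames(vp)[, , t][m]), numeric(1)),
                  vapply(seq_len(nFrames(vn)),
                         function(t) mean(frames(vn)[, , t][m]), numeric(1)))
      lab <- c(lab, rep(c(1, 0), each = nFrames(vp)))
    }
    ## Bayes-style oracle: best accuracy over all thresholds of the
    ## frame-level region mean against the frame's video label
    thr <- sort(unique(region))
    max(vapply(thr, function(t) mean((region <= t) == (lab == 1)),
               numeric(1)))
  }
  accs <- vapply(c(1.0, 0.5, 0.2), oracleAcc, numeric(1))
  expect_true(all(diff(accs) < 0))
})

test_that("severity scales the rendered cue depression per video", {
  base <- list(fps = 10, durationS = 2, fluidVisibilityFraction = 1.0,
               fluidContrast = 0.4, seed = 31)
  faint <- do.call(syntheticConfig, c(base, list(severityRange = c(0.5, 0.5))))
  strong <- do.call(syntheticConfig, c(base, list(severityRange = c(1.5, 1.5))))
  depth <- function(cfg) {
    v <- simulateVideo(cfg, "S01", "positive")
    m <- cueMask(v)
    mean(apply(frames(v), 3, function(fr) mean(fr[m])))
  }
  expect_gt(depth(faint), depth(strong))
})
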