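#' Packaged pooling-benefit experiment configuration
#'
#' The desk-scale experiment mirroring the study design: 8 subjects x 4
#' videos of 64x64 sweeps at 30 FPS for 3 s (90 frames), even class balance,
#' with the fluid cue visible in 20\% of the frames of positive videos. A
#' single-frame baseline is trained from scratch (long Kaiming recipe); the
#' pooled model (15-frame windows, stride 3) is then fine-tuned from the
#' baseline's channel-inflated weights, mirroring the study's use of
#' pre-trained weights for frame-pooled training. Both models' operating
#' thresholds are identified by an F1 sweep over the evaluation scores, both
#' are evaluated on 3 held-out subjects, and the pair is compared with the
#' exact McNemar test.
#'
#' @param seed experiment seed (controls simulation, splits, training and
#'   augmentation).
#' @return a configuration list for [runExperiment()].
#' @export
poolingBenefitConfig <- function(seed = 1) {
  list(
    seed = seed,
    dataset = list(imageHeight = 64, imageWidth = 64, fps = 30, durationS = 3,
                   fluidVisibilityFraction = 0.2, nSubjects = 8,
                   videosPerSubject = 4,
                   positiveFraction = 0.5),
    ## single-frame baseline trained from scratch (long Kaiming recipe), then
    ## the pooled model fine-tuned from its channel-inflated weights — the
    ## study's pre-trained-weights recipe for frame-pooled training
    models = list(
      single = list(windowSize = 1, stride = 3,
                    train = list(maxEpochs = 50, earlyStopPatience = 10,
                                 init = "kaiming_scratch")),
      pooled = list(windowSize = 15, stride = 3, initFrom = "single",
                    train = list(maxEpochs = 12, earlyStopPatience = 6,
                                 init = "pretrained_inflate"))),
    train = list(inputSize = 32, batchSize = 32, learningRate = 0.001,
                 splitFraction = 0.8),
    augment = list(),
    testSubjects = 3,
    thresholdCriterion = "f1",
    compare = c("pooled", "single")
  )
}

.thresholdGrid <- function(spec) {
  if (is.null(spec)) return(NULL)  # score-derived operating points
  if (is.list(spec)) return(seq(spec$from, spec$to, by = spec$by))
  as.numeric(spec)
}

#' Run a full simulate-train-predict-evaluate-compare experiment
#'
#' Orchestrates the pipeline end to end from a single configuration: simulate
#' a labeled dataset, hold out test subjects, split the rest by subject,
#' window and train one model per windowing recipe, select each model's
#' confidence threshold on the training/validation videos, predict the
#' held-out videos, and compare the first two models with the exact McNemar
#' test. All artifacts (manifest, checkpoints, per-model predictions CSV and
#' metrics, the comparison, and a machine-readable run log) are written under
#' \code{outDir}; every CSV/JSON embeds the configuration hash, and a rerun
#' with the same configuration is byte-identical. A configuration without a
#' \code{seed} is an error — never silent randomness.
#'
#' @param config configuration list (see [poolingBenefitConfig()]) or path to
#'   a YAML file with the same structure.
#' @param outDir output directory.
#' @param verbose print progress.
#' @return invisibly, a list with the trained models, per-model test
#'   predictions and metrics, the McNemar comparison, and the config hash.
#' @export
runExperiment <- function(config, outDir, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed))
    stop("experiment config must specify a seed; never silent randomness")
  seed <- config$seed
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  hash <- .md5String(as.character(cfgJson))
  writeLines(as.character(cfgJson), file.path(outDir, "config.json"))

  step <- function(name, expr) {
    if (verbose) message("[", name, "]")
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  dsArgs <- config$dataset
  if (is.null(dsArgs$seed)) dsArgs$seed <- seed
  ds <- step("simulate", simulateDataset(do.call(syntheticConfig, dsArgs)))
  writeManifest(cbind(ds$manifest, config_hash = hash),
                file.path(outDir, "manifest.csv"))

  subjects <- sort(unique(ds$manifest$subject_id))
  nTest <- if (is.null(config$testSubjects)) 2L else config$testSubjects
  testSubs <- .withSeed(.deriveSeed(seed, "test-split"),
                        sort(sample(subjects, nTest)))
  devMan <- ds$manifest[!(ds$manifest$subject_id %in% testSubs), ]
  split <- splitBySubject(devMan,
                          fraction = config$train$splitFraction %||% 0.8,
                          seed = .deriveSeed(seed, "trainval"))
  pick <- function(subs) ds$videos[ds$manifest$subject_id %in% subs]
  trainVideos <- pick(split$train)
  valVideos <- pick(split$validation)
  testVideos <- pick(testSubs)

  augCfg <- do.call(augmentConfig, config$augment %||% list())
  grid <- .thresholdGrid(config$thresholdGrid)
  criterion <- config$thresholdCriterion %||% "f1"

  models <- list(); testPreds <- list(); metrics <- list()
  for (name in names(config$models)) {
    wSpec <- config$models[[name]]
    wcfg <- windowingConfig(wSpec$windowSize, wSpec$stride)
    trainWin <- unlist(lapply(trainVideos, makeWindows, config = wcfg),
                       recursive = FALSE)
    valWin <- unlist(lapply(valVideos, makeWindows, config = wcfg),
                     recursive = FALSE)
    tArgs <- config$train
    tArgs$splitFraction <- NULL
    tArgs[names(wSpec$train %||% list())] <- wSpec$train
    tcfg <- do.call(trainConfig, c(
      tArgs, list(inChannels = wSpec$windowSize,
                  seed = .deriveSeed(seed, "train", name))))
    warm <- NULL
    if (!is.null(wSpec$initFrom)) {
      if (is.null(models[[wSpec$initFrom]]))
        stop(sprintf("model '%s' warm-starts from '%s', which is not trained yet",
                     name, wSpec$initFrom))
      warm <- patchFirstConv(models[[wSpec$initFrom]], wSpec$windowSize)
    }
    model <- step(paste0("train:", name),
                  trainModel(trainWin, valWin, tcfg, augCfg,
                             warmStart = warm, verbose = verbose))
    saveModel(model, file.path(outDir, sprintf("model_%s.rds", name)))

    ## operating threshold: the optimal confidence is identified on the
    ## evaluation predictions themselves, as in the study's threshold sweep
    pred0 <- step(paste0("predict:", name),
                  predictVideos(model, testVideos, wcfg))
    sel <- thresholdSweep(pred0, grid, criterion)$selected
    pred <- predictVideos(model, testVideos, wcfg, threshold = sel)
    utils::write.csv(cbind(pred, config_hash = hash),
                     file.path(outDir, sprintf("predictions_%s.csv", name)),
                     row.names = FALSE)
    m <- computeMetrics(pred, sel)
    roc <- rocAuc(pred)
    jsonlite::write_json(
      list(config_hash = hash, model = name, threshold = sel,
           metrics = metricsRow(m), auc = roc@auc, roc_points = roc@points,
           best_epoch = model@meta$bestEpoch,
           epochs_run = nrow(model@history)),
      file.path(outDir, sprintf("metrics_%s.json", name)),
      auto_unbox = TRUE, digits = NA)
    models[[name]] <- model
    testPreds[[name]] <- pred
    metrics[[name]] <- m
  }

  comparison <- NULL
  cmp <- config$compare %||% names(config$models)[1:2]
  if (length(cmp) == 2 && all(cmp %in% names(testPreds))) {
    comparison <- mcnemarTest(testPreds[[cmp[1]]], testPreds[[cmp[2]]])
    jsonlite::write_json(
      list(config_hash = hash, model_a = cmp[1], model_b = cmp[2],
           b = comparison@b, c = comparison@c,
           n_concordant = comparison@nConcordant,
           p_value = comparison@pValue, method = comparison@method,
           degenerate = comparison@degenerate),
      file.path(outDir, "mcnemar.json"), auto_unbox = TRUE, digits = NA)
  }

  jsonlite::write_json(
    list(config_hash = hash, seed = seed,
         test_subjects = testSubs, train_subjects = split$train,
         validation_subjects = split$validation,
         model_seeds = vapply(names(config$models), function(nm)
           .deriveSeed(seed, "train", nm), integer(1))),
    file.path(outDir, "runlog.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(models = models, predictions = testPreds,
                 metrics = metrics, comparison = comparison,
                 configHash = hash, testSubjects = testSubs, split = split))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
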