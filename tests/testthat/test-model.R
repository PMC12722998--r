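test_that("backbone construction enforces the architecture contract", {
  m <- sonoModel(inChannels = 150, inputSize = 32, seed = 7)
  expect_identical(dim(m@params$w1), c(3L, 3L, 150L, 8L))
  x <- array(runif(32 * 32 * 150 * 2), c(32, 32, 150, 2))
  p <- t(sonopool:::.softmaxProbs(sonopool:::.forwardTiny(m@params, x)$logits))
  expect_identical(dim(p), c(2L, 2L))
  expect_equal(rowSums(p), c(1, 1))

  expect_error(sonoModel("efficientnet_b9", 3), "unknown architecture")
  expect_error(sonoModel(inChannels = 3, init = "pretrained_inflate"),
               "source")

  ## identical seed, identical weights
  m2 <- sonoModel(inChannels = 150, inputSize = 32, seed = 7)
  expect_identical(m@params, m2@params)
})

test_that("inflated first convolutions preserve responses to gray inputs", {
  src <- sonoModel(inChannels = 3, inputSize = 16, seed = 2)
  gray <- array(runif(16 * 16), c(16, 16))
  grayRGB <- array(rep(gray, 3), c(16, 16, 3, 1))
  refLogits <- sonopool:::.forwardTiny(src@params, grayRGB)$logits

  for (n in c(1L, 5L, 150L)) {
    inflated <- patchFirstConv(src, n)
    expect_identical(inflated@inChannels, as.numeric(n))
    expect_identical(inflated@params$w2, src@params$w2)  # deeper layers copied
    stackN <- array(rep(gray, n), c(16, 16, n, 1))
    got <- sonopool:::.forwardTiny(inflated@params, stackN)$logits
    expect_lt(max(abs(got - refLogits)), 1e-5)
  }

  ## n = 1 closed form: kernels collapse to the sum of the source channels
  w1 <- inflateConvKernels(src@params$w1, 1L)
  expect_equal(w1[, , 1, ], apply(src@params$w1, c(1, 2, 4), sum))
})

test_that("subject splits are stratified, rounded and leakage-free", {
  man <- data.frame(subject_id = sprintf("S%02d", 1:10), group_tag = "G1")
  sp <- splitBySubject(man, 0.8, seed = 3)
  expect_length(sp$train, 8L)
  expect_length(sp$validation, 2L)

  man2 <- data.frame(subject_id = sprintf("S%02d", 1:10),
                     group_tag = rep(c("A", "B"), each = 5))
  sp2 <- splitBySubject(man2, 0.8, seed = 3)
  perGroup <- table(man2$group_tag[match(sp2$train, man2$subject_id)])
  expect_identical(as.integer(perGroup), c(4L, 4L))
  expect_length(sp2$validation, 2L)

  for (seed in 1:1000) {
    sp <- splitBySubject(man2, 0.8, seed = seed)
    expect_length(intersect(sp$train, sp$validation), 0L)
  }

  man3 <- data.frame(subject_id = c("S01", "S02", "S03"),
                     group_tag = c("A", "A", "B"))
  expect_warning(sp3 <- splitBySubject(man3, 0.8, seed = 1),
                 "single subject")
  expect_true("S03" %in% sp3$train)

  folds <- kFoldSubjects(man2, k = 5, seed = 2)
  expect_length(unlist(folds), 10L)
  expect_identical(anyDuplicated(unlist(folds)), 0L)
})

test_that("augmentation is shared across channels and has an identity limit", {
  st <- array(runif(24 * 24 * 4), c(24, 24, 4))
  withr::with_seed(1, out <- augmentWindow(st, noAugment()))
  expect_equal(out, st)

  ## flipping twice recovers the stack (crop disabled)
  flipCfg <- augmentConfig(cropScaleRange = c(1, 1), cropAspectRange = c(1, 1),
                           brightnessJitter = 0, contrastJitter = 0,
                           saturationJitter = 0, hflipProbability = 1)
  withr::with_seed(1, twice <- augmentWindow(augmentWindow(st, flipCfg),
                                             flipCfg))
  expect_equal(twice, st)

  ## a channel-monotone pattern stays channel-monotone: one draw per window,
  ## applied identically to every channel
  mono <- array(rep(matrix(runif(24 * 24), 24), 4), c(24, 24, 4))
  for (ch in 1:4) mono[, , ch] <- mono[, , ch] + ch  # strictly increasing
  mono <- mono / max(mono)
  withr::with_seed(7, aug <- augmentWindow(mono, augmentConfig(), size = 16))
  ord <- apply(aug, c(1, 2), function(v) paste(order(v), collapse = ""))
  expect_true(all(ord == "1234"))
})

test_that("training separable data reaches high validation accuracy quickly", {
  setup <- tinyTrainingSetup(seed = 3, fluidContrast = 0.7,
                             fluidVisibilityFraction = 1.0)
  tc <- trainConfig(inChannels = 1, inputSize = 32, maxEpochs = 20,
                    earlyStopPatience = 10, seed = 5)
  m <- trainModel(setup$train, setup$val, tc)
  expect_gt(max(m@history$val_acc), 0.95)
  expect_lte(nrow(m@history), 20L)
})

test_that("training is deterministic and guards its preconditions", {
  setup <- tinyTrainingSetup(seed = 11)
  tc <- trainConfig(inChannels = 1, inputSize = 32, maxEpochs = 2,
                    earlyStopPatience = 1, seed = 9)
  m1 <- trainModel(setup$train, setup$val, tc)
  m2 <- trainModel(setup$train, setup$val, tc)
  expect_identical(m1@history, m2@history)
  expect_identical(m1@params, m2@params)

  expect_error(trainModel(list(), setup$val, tc), "non-empty")
  badTc <- trainConfig(inChannels = 5, inputSize = 32, maxEpochs = 2,
                       earlyStopPatience = 1)
  expect_error(trainModel(setup$train, setup$val, badTc),
               "does not match")

  ## single-class validation set warns but still trains
  posVal <- Filter(function(w) videoLabel(w) == "positive", setup$val)
  expect_warning(trainModel(setup$train, posVal, tc), "single class")

  ## warm start must match the window channel count
  src <- sonoModel(inChannels = 1, inputSize = 32, seed = 1)
  wrong <- patchFirstConv(src, 5)
  expect_error(trainModel(setup$train, setup$val, tc, warmStart = wrong),
               "channels")
})

test_that("early stopping triggers on stalled validation loss only", {
  improving <- seq(1, 0.1, length.out = 30)
  expect_false(any(vapply(seq_along(improving), function(k)
    sonopool:::.stopAfterPatience(improving[1:k], 10), logical(1))))
  stalled <- c(0.5, 0.4, rep(0.45, 12))
  firstStop <- which(vapply(seq_along(stalled), function(k)
    sonopool:::.stopAfterPatience(stalled[1:k], 10), logical(1)))[1]
  expect_identical(firstStop, 12L)  # 10 epochs after the best (epoch 2)
})
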