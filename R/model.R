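#' Create a training configuration
#'
#' Defaults follow the study recipe: batch size 32, Adam, learning rate 0.001,
#' early stopping after 10 epochs without validation improvement, and a
#' maximum of 100 epochs — raised to 200 when training from scratch with
#' Kaiming initialization, which needs longer to converge.
#'
#' @param architecture backbone; \code{"tiny_cnn"} (three 3x3 conv blocks) is
#'   the supported backbone.
#' @param inChannels pooled frames per input (window size).
#' @param inputSize square resolution inputs are resampled to (multiple of 8).
#' @param init weight initialization mode.
#' @param batchSize,learningRate,maxEpochs,earlyStopPatience optimizer recipe;
#'   \code{maxEpochs} defaults to 200 for \code{"kaiming_scratch"} and 100
#'   otherwise.
#' @param splitFraction train share of the by-subject split.
#' @param seed training seed.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(architecture = "tiny_cnn", inChannels = 150,
                        inputSize = 32,
                        init = c("kaiming_scratch", "pretrained_inflate"),
                        batchSize = 32, learningRate = 0.001,
                        maxEpochs = NULL, earlyStopPatience = 10,
                        splitFraction = 0.8, seed = 1) {
  init <- match.arg(init)
  if (is.null(maxEpochs))
    maxEpochs <- if (init == "kaiming_scratch") 200 else 100
  new("TrainConfig", architecture = architecture, inChannels = inChannels,
      inputSize = inputSize, init = init, batchSize = batchSize,
      learningRate = learningRate, maxEpochs = maxEpochs,
      earlyStopPatience = earlyStopPatience, splitFraction = splitFraction,
      seed = seed)
}

#' Create an augmentation configuration
#'
#' Defaults: random resized crop keeping 80-100\% of the area with aspect
#' ratio in 3:4-4:3, brightness/contrast/saturation jitter of
#' +-20\%/+-10\%/+-10\%, and a 50\% horizontal flip. One draw per window,
#' applied identically to every channel.
#'
#' @param cropScaleRange,cropAspectRange crop sampling ranges.
#' @param brightnessJitter,contrastJitter,saturationJitter jitter half-widths.
#' @param hflipProbability horizontal flip probability.
#' @return an [AugmentConfig-class].
#' @export
augmentConfig <- function(cropScaleRange = c(0.8, 1.0),
                          cropAspectRange = c(3 / 4, 4 / 3),
                          brightnessJitter = 0.20, contrastJitter = 0.10,
                          saturationJitter = 0.10, hflipProbability = 0.5) {
  new("AugmentConfig", cropScaleRange = cropScaleRange,
      cropAspectRange = cropAspectRange, brightnessJitter = brightnessJitter,
      contrastJitter = contrastJitter, saturationJitter = saturationJitter,
      hflipProbability = hflipProbability)
}

#' Build a (channel-patched) classifier backbone
#'
#' Constructs the compact three-block CNN with a first convolution accepting
#' \code{inChannels} input channels — the frame-pooling adaptation in which n
#' consecutive grayscale frames enter as the channel dimension — and a
#' two-logit softmax head. With \code{init = "kaiming_scratch"} all weights
#' are drawn by Kaiming initialization under \code{seed}. With
#' \code{init = "pretrained_inflate"} a \code{source} model must be supplied
#' (there are no stock weights for the compact backbone); use
#' [patchFirstConv()] to inflate it.
#'
#' @param architecture \code{"tiny_cnn"}; anything else is an error.
#' @param inChannels number of input channels (>= 1).
#' @param inputSize square input resolution (multiple of 8).
#' @param init initialization mode.
#' @param source optional source [SonoModel-class] for inflation.
#' @param seed RNG seed for weight draws.
#' @return a [SonoModel-class].
#' @examples
#' m <- sonoModel(inChannels = 150, seed = 7)
#' m
#' @export
sonoModel <- function(architecture = "tiny_cnn", inChannels = 150,
                      inputSize = 32,
                      init = c("kaiming_scratch", "pretrained_inflate"),
                      source = NULL, seed = 1) {
  init <- match.arg(init)
  if (!identical(architecture, "tiny_cnn"))
    stop(sprintf("unknown architecture '%s': 'tiny_cnn' is the supported backbone",
                 architecture))
  if (init == "pretrained_inflate") {
    if (is.null(source))
      stop("init = 'pretrained_inflate' requires a 'source' model: ",
         "no stock weights exist for 'tiny_cnn'")
    return(patchFirstConv(source, inChannels, init = "pretrained_inflate"))
  }
  if (inChannels < 1) stop("inChannels must be >= 1")
  params <- .withSeed(seed, .initTinyCnn(as.integer(inChannels)))
  new("SonoModel", architecture = architecture, inChannels = inChannels,
      inputSize = inputSize, params = params,
      history = data.frame(), seed = seed, meta = list(init = init))
}

#' Inflate first-convolution kernels to a new channel count
#'
#' Adapts a first-layer kernel bank trained on \code{c}-channel (typically
#' RGB) input to \code{n}-channel pooled-frame input: for each output filter
#' the mean of its source-channel kernels is replicated across all \code{n}
#' channels and multiplied by \code{c/n}. The scaling preserves the expected
#' first-layer activation magnitude, and makes the response to a
#' channel-constant stack equal the source response to the corresponding gray
#' input exactly (linearity of convolution).
#'
#' @param w source kernel array \code{k x k x c x f}.
#' @param n target input channel count.
#' @return kernel array \code{k x k x n x f}.
#' @export
inflateConvKernels <- function(w, n) {
  d <- dim(w)
  if (length(d) != 4L) stop("w must be a k x k x c x f kernel array")
  meanK <- apply(w, c(1, 2, 4), mean)           # k x k x f
  scaled <- meanK * (d[3] / n)
  aperm(array(rep(as.vector(scaled), n),
              c(d[1], d[2], d[4], n)), c(1, 2, 4, 3))
}

#' Patch the first convolutional layer for n-channel input
#'
#' Returns a copy of \code{source} whose first convolution accepts
#' \code{inChannels} channels; all deeper layers are unchanged. With
#' \code{init = "pretrained_inflate"} the first-layer kernels are inflated
#' with [inflateConvKernels()]; with \code{init = "kaiming_scratch"} every
#' weight is redrawn by Kaiming initialization under \code{seed}.
#'
#' @param source a [SonoModel-class].
#' @param inChannels target channel count (>= 1).
#' @param init how to populate the weights.
#' @param seed RNG seed (scratch mode only).
#' @return a [SonoModel-class].
#' @examples
#' src <- sonoModel(inChannels = 3, seed = 2)
#' m150 <- patchFirstConv(src, 150)
#' m150@inChannels
#' @export
patchFirstConv <- function(source, inChannels,
                           init = c("pretrained_inflate", "kaiming_scratch"),
                           seed = source@seed) {
  stopifnot(is(source, "SonoModel"))
  init <- match.arg(init)
  if (inChannels < 1) stop("inChannels must be >= 1")
  if (init == "kaiming_scratch")
    return(sonoModel(source@architecture, inChannels, source@inputSize,
                     init = "kaiming_scratch", seed = seed))
  params <- source@params
  params$w1 <- inflateConvKernels(params$w1, as.integer(inChannels))
  new("SonoModel", architecture = source@architecture,
      inChannels = as.numeric(inChannels), inputSize = source@inputSize,
      params = params, history = data.frame(), seed = source@seed,
      meta = c(source@meta, list(inflatedFrom = source@inChannels)))
}

#' Split subjects into training and validation partitions
#'
#' An 80/20 (by default) split by subject, stratified by capture-experiment
#' group: within each \code{group_tag} the subject counts split as close to
#' the requested fraction as rounding allows, and no subject ever appears in
#' both partitions (asserted). A group with a single subject is assigned to
#' training with a warning. Deterministic under \code{seed}.
#'
#' @param manifest data frame with columns \code{subject_id} and
#'   \code{group_tag}.
#' @param fraction training share.
#' @param seed shuffle seed.
#' @return list with character vectors \code{train} and \code{validation}.
#' @examples
#' man <- data.frame(subject_id = sprintf("S%02d", 1:10), group_tag = "G1")
#' splitBySubject(man, 0.8, seed = 1)
#' @export
splitBySubject <- function(manifest, fraction = 0.8, seed = 1) {
  stopifnot(all(c("subject_id", "group_tag") %in% names(manifest)))
  .assertFraction(fraction, "fraction")
  subs <- unique(manifest[, c("subject_id", "group_tag")])
  if (nrow(subs) < 2) stop("need at least 2 subjects to split")
  train <- character(0); val <- character(0)
  .withSeed(seed, {
    for (g in sort(unique(subs$group_tag))) {
      s <- sort(subs$subject_id[subs$group_tag == g])
      if (length(s) == 1L) {
        warning(sprintf("group '%s' has a single subject; assigned to training", g),
                call. = FALSE)
        train <- c(train, s)
        next
      }
      s <- sample(s)
      nTrain <- max(1L, min(length(s), round(fraction * length(s))))
      train <- c(train, s[seq_len(nTrain)])
      val <- c(val, s[-seq_len(nTrain)])
    }
  })
  stopifnot(length(intersect(train, val)) == 0L)  # leakage impossible
  list(train = sort(train), validation = sort(val))
}

#' Group-stratified k folds of subjects
#'
#' Optional driver for k-fold evaluation: subjects are shuffled within each
#' capture group and dealt round-robin into \code{k} folds, so folds are
#' stratified by group and subject-disjoint by construction.
#'
#' @param manifest data frame with \code{subject_id} and \code{group_tag}.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return list of \code{k} character vectors of subject IDs.
#' @export
kFoldSubjects <- function(manifest, k = 3, seed = 1) {
  stopifnot(all(c("subject_id", "group_tag") %in% names(manifest)))
  subs <- unique(manifest[, c("subject_id", "group_tag")])
  if (k < 2 || k > nrow(subs)) stop("k must lie in [2, number of subjects]")
  folds <- vector("list", k)
  .withSeed(seed, {
    i <- 0L
    for (g in sort(unique(subs$group_tag))) {
      for (s in sample(sort(subs$subject_id[subs$group_tag == g]))) {
        i <- i + 1L
        fi <- ((i - 1L) %% k) + 1L
        folds[[fi]] <- c(folds[[fi]], s)
      }
    }
  })
  lapply(folds, sort)
}

#' Augment a pooled window stack
#'
#' Samples one random resized crop (area fraction and aspect ratio from the
#' configured ranges), one brightness/contrast/saturation jitter triple and
#' one horizontal-flip decision, and applies them identically to every channel
#' before resampling to \code{size}. Saturation jitter is drawn for parity but
#' is a no-op on single-intensity channels. Uses the caller's RNG stream.
#'
#' @param stack numeric \code{H x W x n} array in [0, 1] (see [windowStack()]).
#' @param config an [AugmentConfig-class].
#' @param size output spatial size.
#' @return numeric \code{size x size x n} array in [0, 1].
#' @export
augmentWindow <- function(stack, config = augmentConfig(), size = dim(stack)[1]) {
  d <- dim(stack)
  H <- d[1]; W <- d[2]
  scale <- stats::runif(1, config@cropScaleRange[1], config@cropScaleRange[2])
  aspect <- exp(stats::runif(1, log(config@cropAspectRange[1]),
                             log(config@cropAspectRange[2])))
  area <- scale * H * W
  cw <- min(W, max(1L, round(sqrt(area * aspect))))
  ch <- min(H, max(1L, round(sqrt(area / aspect))))
  top <- sample.int(H - ch + 1L, 1L)
  left <- sample.int(W - cw + 1L, 1L)
  bf <- stats::runif(1, 1 - config@brightnessJitter, 1 + config@brightnessJitter)
  cf <- stats::runif(1, 1 - config@contrastJitter, 1 + config@contrastJitter)
  stats::runif(1, 1 - config@saturationJitter, 1 + config@saturationJitter)
  flip <- stats::runif(1) < config@hflipProbability

  x <- stack[top:(top + ch - 1L), left:(left + cw - 1L), , drop = FALSE]
  x <- .resizeStack(x, size)
  x <- x * bf
  mg <- mean(x)                       # grayscale mean of the whole window
  x <- (x - mg) * cf + mg
  x[x < 0] <- 0; x[x > 1] <- 1
  if (flip) x <- x[, dim(x)[2]:1, , drop = FALSE]
  x
}

## Windows -> class indices (1 = negative, 2 = positive)
.windowClasses <- function(windows) {
  match(vapply(windows, function(w) w@label, character(1)), .LABELS)
}

#' Train a pooled-frame classifier
#'
#' Minimizes two-class cross-entropy on softmax logits with Adam, recording
#' train/validation loss and accuracy after each epoch. Stops when the
#' validation loss has not improved for \code{earlyStopPatience} epochs or at
#' \code{maxEpochs}, and returns the weights of the best-validation-loss
#' epoch. One augmentation draw is made per window per epoch; validation
#' windows are only resampled to the input size. The run is deterministic
#' under \code{trainCfg@seed}.
#'
#' @param trainWindows,valWindows non-empty, subject-disjoint lists of
#'   [FrameWindow-class] (use [splitBySubject()] to build the partitions).
#' @param trainCfg a [TrainConfig-class]; \code{inChannels} must match the
#'   window size.
#' @param augCfg an [AugmentConfig-class].
#' @param warmStart optional [SonoModel-class] whose weights initialize the
#'   run instead of a fresh Kaiming draw — typically a single-frame model
#'   whose first convolution has been inflated to the pooled channel count
#'   with [patchFirstConv()], mirroring the study's use of pre-trained
#'   weights for frame-pooled training.
#' @param verbose print one line per epoch.
#' @return a trained [SonoModel-class] with its epoch history in
#'   \code{history} and the best epoch in \code{meta$bestEpoch}.
#' @export
trainModel <- function(trainWindows, valWindows, trainCfg,
                       augCfg = augmentConfig(), warmStart = NULL,
                       verbose = FALSE) {
  validObject(trainCfg)
  if (!length(trainWindows) || !length(valWindows))
    stop("train and validation window sets must be non-empty")
  n <- windowSize(trainWindows[[1]])
  if (n != trainCfg@inChannels)
    stop(sprintf("window size %d does not match inChannels %d",
                 n, as.integer(trainCfg@inChannels)))
  yTr <- .windowClasses(trainWindows)
  yVa <- .windowClasses(valWindows)
  if (length(unique(yVa)) < 2L)
    warning("validation set contains a single class; early stopping still monitors loss",
            call. = FALSE)
  S <- as.integer(trainCfg@inputSize)
  if (!is.null(warmStart)) {
    stopifnot(is(warmStart, "SonoModel"))
    if (dim(warmStart@params$w1)[3] != n)
      stop(sprintf("warmStart expects %d input channels but windows carry %d",
                   dim(warmStart@params$w1)[3], as.integer(n)))
  }

  .withSeed(trainCfg@seed, {
    params <- if (is.null(warmStart)) .initTinyCnn(as.integer(n))
              else warmStart@params
    state <- .adamInit(params)
    ## validation inputs are fixed across epochs: resample once
    valBatch <- .stacksToBatch(lapply(valWindows, function(w)
      .resizeStack(windowStack(w), S)))

    hist <- list()
    best <- list(loss = Inf, epoch = 0L, params = params)
    if (!is.null(warmStart)) {
      ## the warm start itself competes as "epoch 0": fine-tuning an inflated
      ## model on label-noisy windows can only be kept if it helps validation
      vp0 <- .softmaxProbs(.forwardTiny(params, valBatch)$logits)
      best$loss <- .xentLoss(vp0, yVa)
    }
    nTr <- length(trainWindows)
    bs <- as.integer(trainCfg@batchSize)
    for (epoch in seq_len(as.integer(trainCfg@maxEpochs))) {
      ord <- sample.int(nTr)
      epLoss <- 0; epCorrect <- 0L
      for (bStart in seq.int(1L, nTr, by = bs)) {
        take <- ord[bStart:min(bStart + bs - 1L, nTr)]
        xb <- .stacksToBatch(lapply(trainWindows[take], function(w)
          augmentWindow(windowStack(w), augCfg, S)))
        yb <- yTr[take]
        fwd <- .forwardTiny(params, xb, keepCache = TRUE)
        probs <- .softmaxProbs(fwd$logits)
        epLoss <- epLoss + .xentLoss(probs, yb) * length(yb)
        epCorrect <- epCorrect +
          sum((probs[2L, ] >= probs[1L, ]) == (yb == 2L))
        grads <- .backwardTiny(params, fwd$cache, .xentGrad(probs, yb))
        upd <- .adamStep(params, grads, state, trainCfg@learningRate)
        params <- upd$params; state <- upd$state
      }
      vp <- .softmaxProbs(.forwardTiny(params, valBatch)$logits)
      valLoss <- .xentLoss(vp, yVa)
      valAcc <- mean((vp[2L, ] >= vp[1L, ]) == (yVa == 2L))
      hist[[epoch]] <- data.frame(
        epoch = epoch, train_loss = epLoss / nTr, train_acc = epCorrect / nTr,
        val_loss = valLoss, val_acc = valAcc)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f/%.3f  val %.4f/%.3f",
                        epoch, epLoss / nTr, epCorrect / nTr, valLoss, valAcc))
      if (valLoss < best$loss)
        best <- list(loss = valLoss, epoch = epoch, params = params)
      if (.stopAfterPatience(vapply(hist, function(h) h$val_loss, numeric(1)),
                             trainCfg@earlyStopPatience)) break
    }
    new("SonoModel", architecture = trainCfg@architecture,
        inChannels = as.numeric(n), inputSize = as.numeric(S),
        params = best$params, history = do.call(rbind, hist),
        seed = trainCfg@seed,
        meta = list(bestEpoch = best$epoch, trainConfig = trainCfg,
                    augmentConfig = augCfg,
                    warmStarted = !is.null(warmStart)))
  })
}
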