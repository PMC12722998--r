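test_that("metrics match hand-evaluated confusion arithmetic", {
  p <- predFrame(c(rep(0.9, 3), 0.9, 0.1, rep(0.1, 5)),
                 c(rep("positive", 3), "negative", "positive",
                   rep("negative", 5)))
  m <- computeMetrics(p, 0.5)
  expect_equal(c(m@tp, m@fp, m@fn, m@tn), c(3, 1, 1, 5))
  expect_equal(m@accuracy, 0.8)
  expect_equal(m@precision, 0.75)
  expect_equal(m@sensitivity, 0.75)
  expect_equal(m@f1, 0.75)
  expect_length(m@undefined, 0L)

  perfect <- predFrame(c(0.9, 0.9, 0.1), c("positive", "positive", "negative"))
  mp <- computeMetrics(perfect, 0.5)
  expect_equal(mp@accuracy, 1)
  expect_equal(mp@f1, 1)

  ## no positive calls: precision NaN and flagged, never silently 0
  none <- predFrame(c(0.1, 0.2), c("positive", "negative"))
  mn <- computeMetrics(none, 0.9)
  expect_true(is.nan(mn@precision))
  expect_true("precision" %in% mn@undefined)
})

test_that("normalized confusion matrices divide by ground-truth counts", {
  p <- predFrame(c(rep(0.9, 3), 0.9, 0.1, rep(0.1, 5)),
                 c(rep("positive", 3), "negative", "positive",
                   rep("negative", 5)))
  cm <- confusionMatrixNormalized(p, 0.5)
  expect_equal(cm["positive", ], c(positive = 0.75, negative = 0.25))
  expect_equal(cm["negative", ], c(positive = 1 / 6, negative = 5 / 6),
               tolerance = 1e-4)

  onlyNeg <- predFrame(c(0.2, 0.8), c("negative", "negative"))
  cm2 <- confusionMatrixNormalized(onlyNeg, 0.5)
  expect_true(all(is.nan(cm2["positive", ])))
  expect_identical(attr(cm2, "emptyRows"), "positive")

  ident <- predFrame(c(0.9, 0.1), c("positive", "negative"))
  expect_equal(unname(confusionMatrixNormalized(ident, 0.5)), diag(2),
               ignore_attr = TRUE)
})

test_that("trapezoidal AUC equals the exhaustive pairwise probability", {
  sep <- predFrame(c(0.9, 0.8, 0.2, 0.1),
                   c("positive", "positive", "negative", "negative"))
  expect_equal(auc(rocAuc(sep)), 1)

  mixed <- predFrame(c(0.9, 0.6, 0.7, 0.2),
                     c("positive", "positive", "negative", "negative"))
  expect_equal(auc(rocAuc(mixed)), 0.75)

  ## all scores tied: the curve is the chance diagonal
  tied <- predFrame(rep(0.4, 6), rep(c("positive", "negative"), 3))
  roc <- rocAuc(tied)
  expect_equal(auc(roc), 0.5)
  expect_equal(rocPoints(roc)$fpr, rocPoints(roc)$tpr)

  set.seed(99)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    labels <- c("positive", "negative",
                sample(c("positive", "negative"), n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    p <- predFrame(scores, labels)
    expect_equal(auc(rocAuc(p)), bruteAuc(scores, labels))
  }

  expect_error(rocAuc(predFrame(c(0.1, 0.2), c("negative", "negative"))),
               "both classes")
})

test_that("AUC is invariant under strictly increasing score transforms and
           matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- runif(30)
  labels <- sample(c("positive", "negative"), 30, replace = TRUE,
                   prob = c(0.4, 0.6))
  a0 <- auc(rocAuc(predFrame(scores, labels)))
  expect_equal(auc(rocAuc(predFrame(plogis(5 * scores - 2), labels))), a0)
  expect_equal(auc(rocAuc(predFrame(scores^3, labels))), a0)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("negative", "positive"),
    direction = "<", quiet = TRUE)))
  expect_equal(a0, ref)
})

test_that("threshold sweeps report every grid point and select the argmax", {
  p <- predFrame(c(0.9, 0.6, 0.7, 0.2),
                 c("positive", "positive", "negative", "negative"))
  sw <- thresholdSweep(p, grid = c(0, 1))
  expect_equal(sw$table$sensitivity[sw$table$threshold == 0], 1)
  expect_equal(sw$table$sensitivity[sw$table$threshold == 1], 0)

  set.seed(3)
  for (i in 1:20) {
    scores <- runif(12)
    labels <- sample(c("positive", "negative"), 12, replace = TRUE)
    if (length(unique(labels)) < 2) next
    pp <- predFrame(scores, labels)
    grid <- seq(0, 1, by = 0.1)
    sw <- thresholdSweep(pp, grid)
    f1s <- vapply(grid, function(t) {
      m <- computeMetrics(pp, t)
      if (is.nan(m@f1)) -Inf else m@f1
    }, numeric(1))
    expect_equal(max(f1s),
                 ifelse(is.nan(sw$table$f1), -Inf,
                        sw$table$f1)[match(sw$selected, grid)])
    expect_identical(sw$selected, grid[which.max(f1s)])  # ties -> lower
  }

  ## default grid: every achievable operating point of the score set
  swDef <- thresholdSweep(p)
  expect_true(all(c(0, sort(unique(p$video_score)), 1) %in%
                  swDef$table$threshold))
  expect_error(thresholdSweep(p, grid = c(-0.1, 0.5)), "within")
})

test_that("exact McNemar p-values match direct binomial summation", {
  mk <- function(okA, okB) {
    n <- length(okA)
    truth <- rep("positive", n)
    list(a = data.frame(video_id = as.character(seq_len(n)),
                        predicted_label = ifelse(okA, "positive", "negative"),
                        true_label = truth),
         b = data.frame(video_id = as.character(seq_len(n)),
                        predicted_label = ifelse(okB, "positive", "negative"),
                        true_label = truth))
  }

  ## b = 0, c = 10: p = 2 * (1/2)^10
  d <- mk(rep(FALSE, 10), rep(TRUE, 10))
  r <- mcnemarTest(d$a, d$b)
  expect_equal(pValue(r), 0.001953125)
  expect_equal(c(r@b, r@c), c(0, 10))

  ## b = 2, c = 8: p = 2 * sum_{k<=2} C(10,k) / 2^10
  d2 <- mk(c(rep(TRUE, 2), rep(FALSE, 8), rep(TRUE, 5)),
           c(rep(FALSE, 2), rep(TRUE, 8), rep(TRUE, 5)))
  expect_equal(pValue(mcnemarTest(d2$a, d2$b)), 0.109375)

  ## symmetry and the b = c cap at 1
  expect_equal(pValue(mcnemarTest(d2$b, d2$a)),
               pValue(mcnemarTest(d2$a, d2$b)))
  d3 <- mk(c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE))
  expect_equal(pValue(mcnemarTest(d3$a, d3$b)), 1)

  ## no discordant videos: degenerate flag, p = 1
  d4 <- mk(c(TRUE, FALSE), c(TRUE, FALSE))
  r4 <- mcnemarTest(d4$a, d4$b)
  expect_true(r4@degenerate)
  expect_equal(pValue(r4), 1)

  set.seed(17)
  for (i in 1:50) {
    okA <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    okB <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    dd <- mk(okA, okB)
    r <- mcnemarTest(dd$a, dd$b)
    expect_equal(pValue(r), bruteMcnemarP(r@b, r@c))
  }

  ## the continuity-corrected chi-square route agrees with stats::mcnemar.test
  r5 <- mcnemarTest(d2$a, d2$b, method = "chisq")
  ref <- stats::mcnemar.test(matrix(c(5, 2, 8, 0), 2), correct = TRUE)
  expect_equal(pValue(r5), unname(ref$p.value))

  ## mismatched ground truth is an error
  bad <- d2$b; bad$true_label[1] <- "negative"
  expect_error(mcnemarTest(d2$a, bad), "true labels")
})
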