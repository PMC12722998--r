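test_that("the capture-recipe window layouts match brute-force enumeration", {
  ## training recipe: 900 frames, 150-frame windows, stride 15
  idx <- windowIndices(900, windowingConfig(150, 15))
  oracle <- bruteWindows(900, 150, 15)
  expect_identical(idx$start, oracle$start)
  expect_identical(as.integer(idx$n_padded), oracle$n_padded)
  ## every multiple of the stride below T is a start, so trailing windows
  ## are kept and end padded; the last unpadded start is T - n = 750
  expect_identical(nrow(idx), 60L)
  expect_identical(max(idx$start[idx$n_padded == 0]), 750L)

  ## short video: all windows padded, start-0 window padded by 150 - 100
  idx2 <- windowIndices(100, windowingConfig(150, 15))
  expect_identical(idx2$start, as.integer(seq(0, 90, by = 15)))
  expect_identical(idx2$n_padded[1], 50L)
  expect_identical(as.integer(idx2$n_padded), bruteWindows(100, 150, 15)$n_padded)

  ## real-time recipe: one 150-frame window per 30-s video
  idx3 <- windowIndices(900, windowingConfig(150, 900))
  expect_identical(nrow(idx3), 1L)
  expect_identical(idx3$start, 0L)

  ## stride exceeding the video length still yields the start-0 window
  expect_identical(nrow(windowIndices(5, windowingConfig(1, 15))), 1L)

  expect_error(windowIndices(0, windowingConfig(1, 1)), "empty")
})

test_that("window enumeration matches brute force over a parameter sweep", {
  set.seed(42)
  for (i in 1:60) {
    tt <- sample(1:300, 1); n <- sample(1:40, 1); s <- sample(1:30, 1)
    got <- windowIndices(tt, windowingConfig(n, s))
    want <- bruteWindows(tt, n, s)
    expect_identical(got$start, want$start)
    expect_identical(as.integer(got$n_padded), want$n_padded)
    expect_identical(nrow(got), as.integer(ceiling(tt / s)))
  }
})

test_that("windows cover the video and reconstruct it from unpadded prefixes", {
  cfg <- syntheticConfig(fps = 10, durationS = 2, nSubjects = 2, seed = 12)
  v <- simulateVideo(cfg, "S01", "positive")
  w <- makeWindows(v, windowingConfig(7, 3))

  ## coverage: union of [start, start + n) contains every frame index
  covered <- sort(unique(unlist(lapply(w, function(x)
    startIndex(x) + seq_len(windowSize(x)) - 1L))))
  expect_true(all((seq_len(nFrames(v)) - 1L) %in% covered))

  ## padding conservation: unpadded prefixes, deduplicated by frame index,
  ## reproduce the original frame stack exactly
  rebuilt <- array(NA_integer_, dim(frames(v)))
  for (x in w) {
    keep <- seq_len(windowSize(x) - nPadded(x))
    rebuilt[, , startIndex(x) + keep] <- frames(x)[, , keep]
  }
  expect_identical(rebuilt, frames(v))

  ## padded frames repeat the final frame
  last <- w[[length(w)]]
  if (nPadded(last) > 0) {
    n <- windowSize(last)
    expect_identical(frames(last)[, , n], frames(v)[, , nFrames(v)])
  }
})

test_that("n > T yields a single fully padded window, not an error", {
  cfg <- syntheticConfig(fps = 5, durationS = 1, nSubjects = 2, seed = 2)
  v <- simulateVideo(cfg, "S01", "negative")   # T = 5
  w <- makeWindows(v, windowingConfig(12, 15))
  expect_length(w, 1L)
  expect_identical(startIndex(w[[1]]), 0)
  expect_identical(nPadded(w[[1]]), 7)
  expect_identical(dim(frames(w[[1]]))[3], 12L)
})

test_that("window stacks scale to the unit interval and preserve order", {
  fr <- array(0L, c(4, 4, 3))
  fr[, , 1] <- 10L; fr[, , 2] <- 128L; fr[, , 3] <- 255L
  w <- new("FrameWindow", frames = fr, videoId = "v", startIndex = 0,
           nPadded = 0, label = "negative")
  st <- windowStack(w)
  expect_equal(range(st), c(10 / 255, 1))
  expect_equal(st[1, 1, ], c(10, 128, 255) / 255)  # temporal order kept

  wc <- new("FrameWindow", frames = array(255L, c(2, 2, 1)), videoId = "v",
            startIndex = 0, nPadded = 0, label = "negative")
  expect_true(all(windowStack(wc) == 1))
})
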