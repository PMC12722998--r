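#' Create a windowing configuration
#'
#' @param windowSize frames pooled per window (channel count); study values
#'   are 1, 30, 90 and 150.
#' @param stride frame offset between window starts. Training used 15; the
#'   real-time recipe pools 150-channel windows at 30-s strides (900 frames at
#'   30 FPS), i.e. one window per video.
#' @param paddingPolicy only \code{"repeat_last"}: trailing windows are
#'   completed by repeating the final frame.
#' @return a [WindowingConfig-class].
#' @examples
#' windowingConfig(150, 15)
#' @export
windowingConfig <- function(windowSize = 150, stride = 15,
                            paddingPolicy = "repeat_last") {
  new("WindowingConfig", windowSize = windowSize, stride = stride,
      paddingPolicy = paddingPolicy)
}

#' Window start indices and padding for a video length
#'
#' Start indices are every multiple of the stride below the frame count
#' (\code{0, s, 2s, ...  < T}), so the number of windows is
#' \code{ceiling(T / s)} and, whenever \code{s <= n}, every frame is covered by
#' at least one window. Windows extending past the last frame are kept and end
#' padded, not dropped.
#'
#' @param nFrames video length T (frames).
#' @param config a [WindowingConfig-class].
#' @return data frame with one row per window: \code{start} (0-based) and
#'   \code{n_padded} (number of repeated trailing frames).
#' @examples
#' windowIndices(900, windowingConfig(150, 15))   # 60 windows, 9 padded
#' windowIndices(100, windowingConfig(150, 15))   # all 7 windows padded
#' @export
windowIndices <- function(nFrames, config = windowingConfig()) {
  validObject(config)
  if (nFrames < 1) stop("empty video: nFrames must be >= 1")
  starts <- seq.int(0L, as.integer(nFrames) - 1L,
                    by = as.integer(config@stride))
  data.frame(start = as.integer(starts),
             n_padded = pmax(0L, as.integer(starts) +
                                 as.integer(config@windowSize) -
                                 as.integer(nFrames)))
}

#' Slice a video into pooled frame windows
#'
#' Applies [windowIndices()] to the video and materializes one
#' [FrameWindow-class] per start, in start order. A window reaching past frame
#' \code{T - 1} repeats the final frame so every window holds exactly
#' \code{windowSize} frames; \code{n > T} yields a single heavily padded
#' window at start 0 (kept, not an error).
#'
#' @param video a [FrameVideo-class].
#' @param config a [WindowingConfig-class].
#' @return list of [FrameWindow-class], ordered by start index.
#' @examples
#' cfg <- syntheticConfig(fps = 5, durationS = 2, nSubjects = 2)
#' v <- simulateVideo(cfg, "S01", "negative")
#' w <- makeWindows(v, windowingConfig(windowSize = 4, stride = 3))
#' vapply(w, startIndex, numeric(1))
#' @export
makeWindows <- function(video, config = windowingConfig()) {
  stopifnot(is(video, "FrameVideo"))
  nT <- nFrames(video)
  idx <- windowIndices(nT, config)
  n <- as.integer(config@windowSize)
  fr <- frames(video)
  lapply(seq_len(nrow(idx)), function(i) {
    s <- idx$start[i]
    take <- pmin(s + seq_len(n), nT)  # repeat_last padding
    new("FrameWindow", frames = fr[, , take, drop = FALSE],
        videoId = videoId(video), startIndex = as.numeric(s),
        nPadded = as.numeric(idx$n_padded[i]), label = videoLabel(video))
  })
}

#' Convert a window to a unit-scaled channel stack
#'
#' Channels are ordered by temporal index (never resorted) and intensities are
#' scaled from 0..255 to the unit interval; each grayscale frame contributes
#' one channel.
#'
#' @param window a [FrameWindow-class].
#' @return numeric array \code{H x W x n} with values in [0, 1].
#' @export
windowStack <- function(window) {
  stopifnot(is(window, "FrameWindow"))
  window@frames / 255
}

#' Write windows to disk as multi-page TIFFs (debug aid)
#'
#' @param windows list of [FrameWindow-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeWindows <- function(windows, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    p <- file.path(dir, sprintf("%s_start%06d.tiff", w@videoId, w@startIndex))
    EBImage::writeImage(aperm(windowStack(w), c(2, 1, 3)), p, type = "tiff",
                        bits.per.sample = 8L)
    p
  }, character(1))
  invisible(paths)
}
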