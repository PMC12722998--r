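## Disk formats: videos are directories of zero-padded 8-bit grayscale PNG
## frames (frame_000000.png, ...) plus a per-video ground-truth side channel
## (cue_frames.csv, cue_mask.png) when generated; datasets carry a
## manifest.csv. CSV dialect: UTF-8, comma, header row, no index column.

.LUMA <- c(0.299, 0.587, 0.114)

#' Write a video as a directory of PNG frames
#'
#' Frames are written as 8-bit grayscale \code{frame_000000.png, ...} (0-based,
#' zero-padded, lexicographic order equals temporal order). When the video
#' carries a generator ground-truth side channel, \code{cue_frames.csv} (per
#' frame: does it render the cue) and \code{cue_mask.png} (the nominal cue
#' region) are written next to the frames.
#'
#' @param video a [FrameVideo-class].
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
writeVideo <- function(video, dir) {
  stopifnot(is(video, "FrameVideo"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fr <- frames(video)
  nT <- dim(fr)[3]
  for (t in seq_len(nT)) {
    EBImage::writeImage(t(fr[, , t]) / 255,
                        file.path(dir, sprintf("frame_%06d.png", t - 1L)),
                        type = "png", bits.per.sample = 8L)
  }
  if (length(cueFrames(video)) || any(cueMask(video))) {
    utils::write.csv(
      data.frame(frame_index = seq_len(nT) - 1L,
                 cue = as.integer(seq_len(nT) %in% cueFrames(video))),
      file.path(dir, "cue_frames.csv"), row.names = FALSE)
    EBImage::writeImage(t(cueMask(video)) * 1,
                        file.path(dir, "cue_mask.png"), type = "png",
                        bits.per.sample = 8L)
  }
  invisible(dir)
}

.readGrayFrame <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  d <- dim(img)
  if (length(d) == 3L && d[3] >= 3L) {
    warning(sprintf("'%s' has %d channels; converted by luminance weighting",
                    basename(path), d[3]), call. = FALSE)
    img <- .LUMA[1] * img[, , 1] + .LUMA[2] * img[, , 2] + .LUMA[3] * img[, , 3]
  } else if (length(d) == 3L) {
    img <- img[, , 1]
  }
  ## EBImage stores x (width) first; transpose to rows x cols
  t(img)
}

#' Load a video from a frame-sequence directory
#'
#' Reads the PNG/TIFF frames of \code{path} in lexicographic order, converts
#' them to single-channel 8-bit (3-channel frames are collapsed with the
#' standard luminance weights 0.299/0.587/0.114, with a warning), and returns
#' a [FrameVideo-class]. All frames must share one size. The manifest's frame
#' rate overrides anything stored with the frames. The ground-truth side
#' channel, if present on disk, is reattached.
#'
#' @param path directory containing the frames.
#' @param fps frame rate to record.
#' @param videoId,subjectId,scanSite,label,groupTag metadata (normally from
#'   the manifest).
#' @return a [FrameVideo-class].
#' @export
loadVideo <- function(path, fps = 30, videoId = basename(path),
                      subjectId = "unknown", scanSite = "BLD",
                      label = "negative", groupTag = "G1") {
  if (!dir.exists(path)) stop(sprintf("unreadable video source '%s'", path))
  files <- sort(list.files(path, pattern = "^frame_.*\\.(png|tif|tiff)$",
                           full.names = TRUE))
  if (!length(files)) stop(sprintf("no frames found under '%s'", path))
  mats <- lapply(files, .readGrayFrame)
  sizes <- unique(vapply(mats, function(m) paste(dim(m), collapse = "x"),
                         character(1)))
  if (length(sizes) != 1L)
    stop(sprintf("mixed frame sizes in '%s': %s", path,
                 paste(sizes, collapse = ", ")))
  fr <- array(as.integer(round(255 * unlist(mats))),
              c(dim(mats[[1]]), length(mats)))
  cueF <- integer(0); cueM <- matrix(FALSE, dim(fr)[1], dim(fr)[2])
  cfPath <- file.path(path, "cue_frames.csv")
  if (file.exists(cfPath)) {
    cf <- utils::read.csv(cfPath)
    cueF <- as.integer(cf$frame_index[cf$cue == 1] + 1L)
    cmPath <- file.path(path, "cue_mask.png")
    if (file.exists(cmPath)) cueM <- .readGrayFrame(cmPath) > 0.5
  }
  new("FrameVideo", frames = fr, fps = fps, videoId = videoId,
      subjectId = subjectId, scanSite = scanSite,
      label = .matchLabel(label), groupTag = groupTag,
      cueFrames = cueF, cueMask = cueM)
}

#' Write a dataset manifest
#'
#' @param manifest manifest data frame.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a dataset manifest
#'
#' Checks the required columns, unique video IDs, legal labels and — when
#' \code{checkPaths} — that every referenced video directory exists.
#'
#' @param path manifest CSV path.
#' @param checkPaths verify that the \code{path} column resolves (relative to
#'   the manifest's directory).
#' @return the manifest data frame.
#' @export
readManifest <- function(path, checkPaths = TRUE) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("video_id", "subject_id", "scan_site", "label", "group_tag",
            "n_frames", "fps", "path")
  if (!all(need %in% names(man)))
    stop("manifest is missing columns: ",
         paste(setdiff(need, names(man)), collapse = ", "))
  if (anyDuplicated(man$video_id)) stop("video_id values must be unique")
  if (!all(man$label %in% .LABELS))
    stop("labels must be 'negative' or 'positive'")
  if (checkPaths) {
    full <- file.path(dirname(path), man$path)
    miss <- man$path[!dir.exists(full)]
    if (length(miss))
      stop("missing video directories: ", paste(miss, collapse = ", "))
  }
  man
}

#' Write a simulated dataset to disk
#'
#' One directory of PNG frames per video (named by video ID) plus
#' \code{manifest.csv} at the top level; the manifest's \code{path} column is
#' filled with the per-video directory names.
#'
#' @param dataset list with \code{videos} and \code{manifest} as returned by
#'   [simulateDataset()].
#' @param dir output directory.
#' @return invisibly, the updated manifest.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  for (i in seq_len(nrow(man))) {
    vid <- man$video_id[i]
    writeVideo(dataset$videos[[vid]], file.path(dir, vid))
    man$path[i] <- vid
  }
  writeManifest(man, file.path(dir, "manifest.csv"))
  invisible(man)
}

#' Load a dataset written by [writeDataset()]
#'
#' @param dir dataset directory containing \code{manifest.csv}.
#' @return list with \code{videos} and \code{manifest}.
#' @export
loadDataset <- function(dir) {
  man <- readManifest(file.path(dir, "manifest.csv"))
  videos <- lapply(seq_len(nrow(man)), function(i)
    loadVideo(file.path(dir, man$path[i]), fps = man$fps[i],
              videoId = man$video_id[i], subjectId = man$subject_id[i],
              scanSite = man$scan_site[i], label = man$label[i],
              groupTag = man$group_tag[i]))
  names(videos) <- man$video_id
  list(videos = videos, manifest = man)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the weights together with the training, augmentation
#' and seed provenance recorded in the model's \code{meta}.
#'
#' @param model a [SonoModel-class].
#' @param path checkpoint path (RDS).
#' @return \code{saveModel}: invisibly, \code{path}; \code{loadModel}: the
#'   model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "SonoModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  m <- readRDS(path)
  stopifnot(is(m, "SonoModel"))
  m
}
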