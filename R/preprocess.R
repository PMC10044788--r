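# Frame normalization, background modelling, blob segmentation,
# occlusion/non-occlusion frame classification, fragment splitting, and
# automatic ear labelling on single-subject videos.

# 8-connected labelling with a minimum-area filter; returns an integer
# matrix, components relabelled 1..n in descending area order.
labelComponents <- function(mask, min_area = 0) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(cpp_label8(as.logical(mask), H, W), H, W)
  if (max(lab) == 0) return(lab)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  ord <- keep[order(areas[keep], decreasing = TRUE)]
  remap <- integer(length(areas))
  remap[ord] <- seq_along(ord)
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

#' Normalize a frame to a fixed mean intensity
#'
#' Linearly rescales the frame so its mean intensity equals
#' \code{reference}; this corrects slow illumination fluctuations and makes
#' a frame and any positive multiple of it identical after normalization.
#'
#' @param frame numeric matrix of intensities.
#' @param reference target mean intensity (default 128).
#' @return the rescaled frame.
#' @export
normalizeFrame <- function(frame, reference = 128) {
  if (length(frame) < 1) stop("frame must have at least one pixel")
  m <- mean(frame)
  if (m <= 0) stop("degenerate input: frame mean intensity is zero")
  frame * (reference / m)
}

#' Build a background model from subsampled frames
#'
#' The background is the pixel-wise mean (or, more robustly, median) of
#' \code{nSamples} evenly subsampled, mean-normalized frames. The mean is
#' the classical choice and is exact on long recordings where every pixel
#' is background most of the time; the median tolerates a subject dwelling
#' on a spot for up to half the sampled frames and is the default used by
#' the pipeline on short clips.
#'
#' @param seq a \linkS4class{FrameSequence}.
#' @param nSamples number of frames to combine (1..nFrames).
#' @param reference normalization reference mean.
#' @param statistic "mean" or "median".
#' @return numeric matrix, the background image.
#' @export
buildBackground <- function(seq, nSamples = 10, reference = 128,
                            statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  n <- nFrames(seq)
  if (n == 0) stop("empty frame sequence")
  nSamples <- as.integer(nSamples)
  if (nSamples < 1 || nSamples > n) stop("nSamples must be in 1..nFrames")
  idx <- unique(round(seq.int(1, n, length.out = nSamples)))
  d <- frameDim(seq)
  if (statistic == "mean") {
    acc <- 0
    for (i in idx) acc <- acc + normalizeFrame(getFrame(seq, i), reference)
    acc / length(idx)
  } else {
    stack <- vapply(idx, function(i)
      as.numeric(normalizeFrame(getFrame(seq, i), reference)),
      numeric(d[1] * d[2]))
    matrix(apply(stack, 1, median), d[1], d[2])
  }
}

#' Segment foreground blobs in a frame
#'
#' Foreground pixels are those whose absolute difference from the background
#' exceeds \code{threshold}; blobs are 8-connected components with at least
#' \code{minBlobArea} pixels, returned in descending area order.
#'
#' @param frame normalized frame (numeric matrix).
#' @param background background image of the same shape.
#' @param threshold intensity difference threshold.
#' @param minBlobArea minimum component area in pixels.
#' @param frameIndex 0-based frame index stored on each blob.
#' @return list of blobs; each blob is a list with \code{frame},
#'   \code{pixels} (flat 1-based indices into the frame matrix),
#'   \code{bbox} (c(x0, y0, x1, y1), half-open, 0-based), \code{centroid}
#'   (c(x, y)) and \code{area}.
#' @export
segmentBlobs <- function(frame, background, threshold = 25, minBlobArea = 50,
                         frameIndex = 0L) {
  if (!all(dim(frame) == dim(background)))
    stop("frame and background must have the same shape")
  fg <- abs(frame - background) > threshold
  lab <- labelComponents(fg, min_area = minBlobArea)
  nb <- max(lab)
  if (nb == 0) return(list())
  H <- nrow(frame)
  lapply(seq_len(nb), function(b) {
    pix <- which(lab == b)
    ys <- (pix - 1) %% H          # 0-based row
    xs <- (pix - 1) %/% H         # 0-based col
    list(frame = as.integer(frameIndex), pixels = pix,
         bbox = c(min(xs), min(ys), max(xs) + 1, max(ys) + 1),
         centroid = c(mean(xs), mean(ys)), area = length(pix))
  })
}

# Run segmentation over a whole sequence; returns list (per frame) of blob
# lists plus the background used.
segmentSequence <- function(seq, config = loadConfig(NULL)) {
  bg <- buildBackground(seq, min(config$background_samples, nFrames(seq)),
                        config$reference_mean,
                        statistic = config$background_stat)
  blobs <- vector("list", nFrames(seq))
  for (i in seq_len(nFrames(seq))) {
    fr <- normalizeFrame(getFrame(seq, i), config$reference_mean)
    blobs[[i]] <- segmentBlobs(fr, bg, config$blob_threshold,
                               config$min_blob_area, frameIndex = i - 1L)
  }
  list(blobs = blobs, background = bg)
}

#' Classify frames as occlusion or non-occlusion
#'
#' A frame is non-occlusion exactly when its blob count equals the declared
#' number of subjects; any mismatch (fewer blobs from merged subjects, or
#' more from splits) marks an occlusion frame.
#'
#' @param blobCounts integer vector of per-frame blob counts.
#' @param nSubjects declared number of subjects (>= 1).
#' @return character vector, "non_occlusion" or "occlusion" per frame.
#' @export
classifyFrames <- function(blobCounts, nSubjects) {
  if (nSubjects < 1) stop("nSubjects must be >= 1")
  ifelse(blobCounts == nSubjects, "non_occlusion", "occlusion")
}

#' Split classified frames into alternating fragments
#'
#' Maximal runs of equal kind partition the frame range. Each occlusion
#' fragment records the adjacent non-occlusion frames as its flanks
#' (one previous frame, one subsequent frame), absent at sequence
#' boundaries.
#'
#' @param kinds per-frame classification from \code{\link{classifyFrames}}.
#' @return data.frame with columns kind, start, end (0-based, inclusive),
#'   flank_before, flank_after (NA when absent).
#' @export
splitFragments <- function(kinds) {
  if (length(kinds) < 1) stop("need at least one frame")
  r <- rle(kinds)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- data.frame(kind = r$values, start = starts - 1L, end = ends - 1L,
                    flank_before = NA_integer_, flank_after = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    if (out$kind[i] != "occlusion") next
    if (i > 1) out$flank_before[i] <- out$end[i - 1]
    if (i < nrow(out)) out$flank_after[i] <- out$start[i + 1]
  }
  out
}

#' Automatically label ears on a single-subject video
#'
#' Double-threshold auto-labelling: the body blob is segmented against the
#' background; inside the body crop a second, intensity-based threshold
#' separates the ear disks from the darker body, and the two largest ear
#' components become the two labels (boxes in full-frame pixel
#' coordinates, ear identities 1 and 2 by leftmost-in-heading order of
#' appearance). Frames yielding a number of ear components other than two
#' are skipped with a log message.
#'
#' @param seq a single-subject \linkS4class{FrameSequence}.
#' @param config configuration list; uses \code{blob_threshold},
#'   \code{min_blob_area}, \code{reference_mean} and \code{ear_threshold}
#'   (the quantile of the intra-body intensity range that separates ears
#'   from body).
#' @return label data.frame (frame, class, x0, y0, x1, y1, id), plus an
#'   attribute \code{skipped} with the skipped frame indices.
#' @export
autoLabelEars <- function(seq, config = loadConfig(NULL)) {
  sg <- segmentSequence(seq, config)
  labels <- list()
  skipped <- integer()
  prev_centres <- NULL   # 2x2 matrix (x, y) per ear id, for id continuity
  for (i in seq_len(nFrames(seq))) {
    blobs <- sg$blobs[[i]]
    if (length(blobs) != 1)
      stop("auto-labelling requires a single-subject video; frame ", i - 1,
           " has ", length(blobs), " blobs")
    blob <- blobs[[1]]
    fr <- normalizeFrame(getFrame(seq, i), config$reference_mean)
    bb <- blob$bbox
    H <- nrow(fr)
    crop <- fr[(bb[2] + 1):bb[4], (bb[1] + 1):bb[3], drop = FALSE]
    # body mask restricted to the crop
    inblob <- matrix(FALSE, nrow(fr), ncol(fr))
    inblob[blob$pixels] <- TRUE
    cropmask <- inblob[(bb[2] + 1):bb[4], (bb[1] + 1):bb[3], drop = FALSE]
    vals <- crop[cropmask]
    # second threshold between the dark body mode and the brighter ear mode
    thr <- min(vals) + config$ear_threshold * (max(vals) - min(vals))
    earmask <- cropmask & (crop > thr)
    lab <- labelComponents(earmask, min_area = 2)
    ncomp <- max(lab)
    if (ncomp != 2) {
      skipped <- c(skipped, i - 1L)
      logMsg("debug", "frame %d skipped: %d ear components", i - 1L, ncomp)
      next
    }
    # quality control: both components must look like whole ears (similar
    # areas, at least a few pixels each), otherwise skip and log
    areas <- tabulate(lab[lab > 0], nbins = 2)
    if (min(areas) < 6 || max(areas) > 2.5 * min(areas)) {
      skipped <- c(skipped, i - 1L)
      logMsg("debug", "frame %d skipped: implausible ear components (%d, %d)",
             i - 1L, areas[1], areas[2])
      next
    }
    Hc <- nrow(lab)
    boxes <- lapply(1:2, function(b) {
      pix <- which(lab == b)
      ys <- (pix - 1) %% Hc + bb[2]
      xs <- (pix - 1) %/% Hc + bb[1]
      c(min(xs), min(ys), max(xs) + 1, max(ys) + 1)
    })
    centres <- t(vapply(boxes, function(b)
      c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2), numeric(2)))
    # keep ear identities stable across frames by nearest-neighbour
    # continuity; on the first usable frame, order by x then y
    if (is.null(prev_centres)) {
      ord <- order(centres[, 1] * 1e3 + centres[, 2])
    } else {
      d11 <- sum((centres[1, ] - prev_centres[1, ])^2) +
             sum((centres[2, ] - prev_centres[2, ])^2)
      d12 <- sum((centres[1, ] - prev_centres[2, ])^2) +
             sum((centres[2, ] - prev_centres[1, ])^2)
      ord <- if (d11 <= d12) 1:2 else 2:1
    }
    prev_centres <- centres[ord, , drop = FALSE]
    labels[[length(labels) + 1]] <- data.frame(
      frame = i - 1L, class = 0L,
      x0 = vapply(boxes[ord], `[`, 1.0, 1),
      y0 = vapply(boxes[ord], `[`, 1.0, 2),
      x1 = vapply(boxes[ord], `[`, 1.0, 3),
      y1 = vapply(boxes[ord], `[`, 1.0, 4),
      id = 1:2)
  }
  out <- if (length(labels)) do.call(rbind, labels) else
    data.frame(frame = integer(), class = integer(), x0 = numeric(),
               y0 = numeric(), x1 = numeric(), y1 = numeric(), id = integer())
  attr(out, "skipped") <- skipped
  out
}
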