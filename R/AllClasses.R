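#' @import methods
#' @importFrom stats runif rnorm sd quantile kmeans pchisq wilcox.test setNames
#' @importFrom utils head tail read.csv write.csv flush.console
#' @useDynLib MRTrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Ordered video frames with pixel geometry
#'
#' A \code{FrameSequence} holds an ordered list of grayscale frames (numeric
#' matrices indexed \code{[y + 1, x + 1]}, intensities on a 0--255 scale), the
#' frame rate in frames per second, and the pixel geometry. The coordinate
#' convention throughout the package is 0-based, origin at the top-left corner,
#' x rightward (columns), y downward (rows). All stages of the tracking
#' pipeline consume and produce this container.
#'
#' @slot frames list of numeric matrices, all with identical dimensions.
#' @slot frameRate frames per second (positive).
#'
#' @export
setClass("FrameSequence",
  representation(frames = "list", frameRate = "numeric"),
  validity = function(object) {
    if (length(object@frameRate) != 1 || !is.finite(object@frameRate) ||
        object@frameRate <= 0)
      return("frameRate must be a single positive number")
    if (length(object@frames) > 0) {
      dims <- vapply(object@frames, dim, integer(2))
      if (!all(dims[1, ] == dims[1, 1]) || !all(dims[2, ] == dims[2, 1]))
        return("all frames must share identical dimensions")
    }
    TRUE
  })

#' Construct a FrameSequence
#'
#' @param frames list of numeric matrices (grayscale, 0--255) with identical
#'   dimensions.
#' @param frameRate frames per second.
#' @return A \linkS4class{FrameSequence}.
#' @examples
#' fs <- FrameSequence(list(matrix(0, 4, 4), matrix(1, 4, 4)), frameRate = 25)
#' nFrames(fs)
#' @export
FrameSequence <- function(frames, frameRate) {
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3) f <- apply(f, c(1, 2), mean)  # collapse RGB
    storage.mode(f) <- "double"
    f
  })
  new("FrameSequence", frames = frames, frameRate = as.numeric(frameRate))
}

#' @describeIn FrameSequence number of frames
#' @param x a FrameSequence
#' @export
nFrames <- function(x) length(x@frames)

#' @describeIn FrameSequence frame rate in frames/second
#' @export
frameRate <- function(x) x@frameRate

#' @describeIn FrameSequence frame size as c(height, width)
#' @export
frameDim <- function(x) {
  if (nFrames(x) == 0) return(c(0L, 0L))
  dim(x@frames[[1]])
}

#' @describeIn FrameSequence extract frame i (1-based index)
#' @param i frame index, 1-based
#' @export
getFrame <- function(x, i) x@frames[[i]]

setMethod("show", "FrameSequence", function(object) {
  d <- frameDim(object)
  cat(sprintf("FrameSequence: %d frames, %dx%d px, %.6g fps\n",
              nFrames(object), d[2], d[1], object@frameRate))
})

#' Synthetic open-field arena specification
#'
#' Parameters of the synthetic open-field video generator: arena geometry,
#' number of mouse-like subjects, ellipse body axes, ear disk radius, a motion
#' speed scale, frame count and rate, additive Gaussian pixel noise, and the
#' RNG seed. Intensities follow the generator's default scheme (bright
#' featureless background, dark bodies, intermediate-intensity ear disks).
#'
#' @slot width,height arena size in pixels.
#' @slot nSubjects number of subjects, 1--4.
#' @slot bodyAxes c(major, minor) semi-axes of the body ellipse, pixels.
#' @slot earRadius radius of each ear disk, pixels (must be < minor axis).
#' @slot speedScale nominal speed, pixels/frame.
#' @slot nFrames number of frames (>= 2).
#' @slot frameRate frames per second.
#' @slot noiseSd standard deviation of additive Gaussian intensity noise.
#' @slot minSeparation minimum centre-to-centre distance enforced between
#'   subjects (pixels); 0 disables repulsion and allows crossings.
#' @slot intensities named numeric: background, body, ear (0--255).
#' @slot seed integer RNG seed.
#' @export
setClass("ArenaSpec",
  representation(width = "numeric", height = "numeric", nSubjects = "numeric",
                 bodyAxes = "numeric", earRadius = "numeric",
                 speedScale = "numeric", nFrames = "numeric",
                 frameRate = "numeric", noiseSd = "numeric",
                 minSeparation = "numeric", intensities = "numeric",
                 seed = "numeric"),
  validity = function(object) {
    if (object$earRadius >= object$bodyAxes[2])
      return("earRadius must be smaller than the minor body axis")
    if (object$nFrames < 2) return("nFrames must be >= 2")
    if (object$nSubjects < 1 || object$nSubjects > 4)
      return("nSubjects must be in 1..4")
    if (any(c(object$width, object$height, object$bodyAxes,
              object$earRadius, object$frameRate) <= 0))
      return("all sizes and the frame rate must be positive")
    if (2 * object$bodyAxes[1] >= min(object$width, object$height))
      return("subject larger than arena")
    TRUE
  })

#' @export
setMethod("$", "ArenaSpec", function(x, name) slot(x, name))

#' Construct an ArenaSpec
#'
#' Defaults describe the study conditions the synthetic arenas emulate: a
#' 128x128 px featureless arena, two subjects with 12x6 px body semi-axes and
#' 2.5 px ear disks, 25 fps, mild sensor noise. The intensity scheme
#' (background 220, body 60, ears 140 on the 8-bit scale) is a generator
#' default, not a claim about any particular recorded video.
#'
#' @param width,height arena size, pixels.
#' @param nSubjects number of subjects (1--4).
#' @param bodyAxes c(major, minor) body ellipse semi-axes, pixels.
#' @param earRadius ear disk radius, pixels.
#' @param speedScale nominal speed, pixels/frame.
#' @param nFrames number of frames.
#' @param frameRate frames/second.
#' @param noiseSd additive Gaussian noise SD, intensity units.
#' @param minSeparation minimum inter-subject distance (pixels), 0 = off.
#' @param intensities named numeric vector with entries background, body, ear.
#' @param seed integer RNG seed.
#' @return An \linkS4class{ArenaSpec}.
#' @export
ArenaSpec <- function(width = 128, height = 128, nSubjects = 2,
                      bodyAxes = c(12, 6), earRadius = 2.5,
                      speedScale = 2, nFrames = 200, frameRate = 25,
                      noiseSd = 2, minSeparation = 0,
                      intensities = c(background = 220, body = 60, ear = 140),
                      seed = 1) {
  new("ArenaSpec", width = width, height = height, nSubjects = nSubjects,
      bodyAxes = bodyAxes, earRadius = earRadius, speedScale = speedScale,
      nFrames = nFrames, frameRate = frameRate, noiseSd = noiseSd,
      minSeparation = minSeparation, intensities = intensities, seed = seed)
}

setMethod("show", "ArenaSpec", function(object) {
  cat(sprintf(
    "ArenaSpec: %gx%g px, %g subjects, %g frames @ %g fps, noise sd %g, seed %g\n",
    object@width, object@height, object@nSubjects, object@nFrames,
    object@frameRate, object@noiseSd, object@seed))
})

#' Rendered synthetic arena video with ground truth
#'
#' The output of \code{\link{simulateArena}}: a \linkS4class{FrameSequence}
#' plus per-frame, per-subject ground truth (body ellipse, the two ear boxes,
#' occlusion flag) and the trajectory table.
#'
#' @slot frames the rendered \linkS4class{FrameSequence}.
#' @slot truth data.frame with one row per (frame, subject): columns
#'   \code{frame} (0-based), \code{id}, \code{x}, \code{y} (body centre),
#'   \code{heading}, ear box corners \code{e1x0,e1y0,e1x1,e1y1} and
#'   \code{e2x0,...}, ear centres \code{e1x,e1y,e2x,e2y}, and
#'   \code{occluded} (logical).
#' @slot spec the generating \linkS4class{ArenaSpec}.
#' @slot seedUsed the seed that actually produced the video (the generator may
#'   advance the seed to guarantee a crossing event).
#' @export
setClass("ArenaVideo",
  representation(frames = "FrameSequence", truth = "data.frame",
                 spec = "ArenaSpec", seedUsed = "numeric"))

setMethod("show", "ArenaVideo", function(object) {
  cat("ArenaVideo\n  ")
  show(object@frames)
  cat(sprintf("  %d subjects, %d occlusion frames, seed used %g\n",
              object@spec@nSubjects,
              length(unique(object@truth$frame[object@truth$occluded])),
              object@seedUsed))
})

#' @describeIn ArenaVideo the rendered frames
#' @param x an ArenaVideo
#' @export
arenaFrames <- function(x) x@frames

#' @describeIn ArenaVideo the ground-truth table
#' @export
arenaTruth <- function(x) x@truth

#' Anchor-based ear detector model
#'
#' Wraps the network parameter graph, the detector configuration (pyramid
#' levels, widths, anchors, thresholds) and a format version. Built by
#' \code{\link{buildDetector}}, trained by \code{\link{trainDetector}}, used
#' by \code{\link{detectEars}}.
#'
#' @slot params named list of parameter tensors.
#' @slot config detector configuration list (see \code{detectorConfig}).
#' @slot anchors per-level anchor matrix list (w, h in pixels).
#' @slot stats running normalization statistics, frozen at inference.
#' @slot trained logical.
#' @slot version serialization format version.
#' @export
setClass("EarDetector",
  representation(params = "list", config = "list", anchors = "list",
                 stats = "list", trained = "logical",
                 version = "character"))

setMethod("show", "EarDetector", function(object) {
  cat(sprintf("EarDetector: strides {%s}, %d parameters, %strained\n",
              paste(object@config$strides, collapse = ","),
              sum(vapply(object@params, length, 1L)),
              if (object@trained) "" else "un"))
})

#' @describeIn EarDetector total number of scalar parameters
#' @param x an EarDetector
#' @export
nParameters <- function(x) sum(vapply(x@params, length, 1L))

#' Dual-Siamese similarity model
#'
#' Twin convolutional image branch, twin coordinate branch, and a small fully
#' connected fusion head mapping the two branch distance signals to a
#' similarity score in [0, 1]. Both branches apply one shared parameter set to
#' both inputs of a pair.
#'
#' @slot params named list of parameter tensors.
#' @slot config model configuration (crop size, embedding dims, margin).
#' @slot trained logical.
#' @slot version serialization format version.
#' @export
setClass("SiameseModel",
  representation(params = "list", config = "list", stats = "list",
                 trained = "logical", version = "character"))

setMethod("show", "SiameseModel", function(object) {
  cat(sprintf(
    "SiameseModel: crop %d px, embed %d, margin %g, %d parameters, %strained\n",
    object@config$crop_size, object@config$embed_dim, object@config$margin,
    sum(vapply(object@params, length, 1L)),
    if (object@trained) "" else "un"))
})
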