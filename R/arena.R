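# Deterministic synthetic open-field generator: smooth random-walk subjects
# (heading persistence + Gaussian turn noise, reflective walls), ellipse
# bodies with two small ear disks rendered on a featureless bright background,
# and full per-frame ground truth including occlusion flags.

# Body-plus-ears pixel mask of one subject; returns logical H x W matrix.
subjectMask <- function(cx, cy, heading, spec) {
  H <- spec@height; W <- spec@width
  a <- spec@bodyAxes[1]; b <- spec@bodyAxes[2]
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(heading) + dy * sin(heading)
  v <- -dx * sin(heading) + dy * cos(heading)
  mask <- (u / a)^2 + (v / b)^2 <= 1
  ec <- earCentres(cx, cy, heading, spec)
  for (k in 1:2) {
    mask <- mask | ((xs - ec[k, 1])^2 + (ys - ec[k, 2])^2 <= spec@earRadius^2)
  }
  mask
}

# Ear disk centres: two points at +/-35 degrees off the heading axis, at the
# head focus of the body ellipse -- capped so each disk overlaps the body
# silhouette by at least ~1.5 px (the raw focus can sit just outside the
# ellipse boundary at that bearing, and a sub-pixel overlap may rasterize
# into a disconnected disk). Returns 2x2 matrix (x, y).
earCentres <- function(cx, cy, heading, spec) {
  a <- spec@bodyAxes[1]; b <- spec@bodyAxes[2]
  cfoc <- sqrt(max(a^2 - b^2, 0))
  off <- 35 * pi / 180
  # ellipse boundary radius along the ear bearing (body frame)
  rb <- a * b / sqrt((b * cos(off))^2 + (a * sin(off))^2)
  d <- min(cfoc, rb + spec@earRadius - 1.5)
  ang <- heading + c(-off, off)
  cbind(cx + d * cos(ang), cy + d * sin(ang))
}

# Occlusion flags for one frame: a subject is occluded iff its pixel mask
# shares an 8-connected component of the union foreground with another
# subject (i.e. the subjects are in contact at segmentation connectivity).
occlusionFlags <- function(masks) {
  n <- length(masks)
  if (n == 1) return(FALSE)
  un <- Reduce(`|`, masks)
  lab <- labelComponents(un, min_area = 0)
  flags <- logical(n)
  comp_of <- lapply(masks, function(m) unique(lab[m & lab > 0]))
  for (i in seq_len(n)) {
    others <- unique(unlist(comp_of[-i]))
    flags[i] <- length(intersect(comp_of[[i]], others)) > 0
  }
  flags
}

#' Simulate smooth subject trajectories in the arena
#'
#' Subjects follow a smooth random walk: the heading persists and receives
#' Gaussian turn noise each frame (an Ornstein-Uhlenbeck-like angular
#' process), speeds fluctuate mildly around \code{speedScale}, and walls
#' reflect. With \code{minSeparation > 0} a pairwise repulsion keeps subjects
#' apart (non-crossing videos); otherwise a weak mutual attraction makes
#' crossing events likely, and when \code{speedScale * nFrames} exceeds the
#' arena diagonal the generator retries seed offsets until at least one
#' frame shows body contact, recording the seed finally used.
#'
#' @param spec an \linkS4class{ArenaSpec}.
#' @return list with \code{paths} (data.frame frame, id, x, y, heading;
#'   frame 0-based, id 1-based) and \code{seedUsed}.
#' @export
simulateTrajectories <- function(spec) {
  validObject(spec)
  n <- spec@nSubjects
  diagonal <- sqrt(spec@width^2 + spec@height^2)
  want_crossing <- n >= 2 && spec@minSeparation <= 0 &&
    spec@speedScale * spec@nFrames > diagonal
  for (offset in 0:63) {
    seed <- spec@seed + offset
    paths <- simulateOnce(spec, seed)
    if (!want_crossing) return(list(paths = paths, seedUsed = seed))
    if (hasCrossing(paths, spec)) return(list(paths = paths, seedUsed = seed))
  }
  stop("no crossing event found within 64 seed offsets; lengthen the video")
}

simulateOnce <- function(spec, seed) {
  set.seed(seed)
  n <- spec@nSubjects
  margin <- spec@bodyAxes[1] + 1
  W <- spec@width; H <- spec@height
  px <- runif(n, margin, W - 1 - margin)
  py <- runif(n, margin, H - 1 - margin)
  # respect the separation constraint in the initial placement
  if (spec@minSeparation > 0 && n > 1) {
    for (tries in 1:200) {
      d <- as.matrix(dist(cbind(px, py)))
      diag(d) <- Inf
      if (min(d) >= spec@minSeparation) break
      px <- runif(n, margin, W - 1 - margin)
      py <- runif(n, margin, H - 1 - margin)
    }
  }
  theta <- runif(n, 0, 2 * pi)
  out <- vector("list", spec@nFrames)
  for (t in seq_len(spec@nFrames)) {
    out[[t]] <- data.frame(frame = t - 1L, id = seq_len(n),
                           x = px, y = py, heading = theta)
    theta <- theta + rnorm(n, 0, 0.35)
    speed <- spec@speedScale * pmax(0.2, 1 + rnorm(n, 0, 0.3))
    vx <- speed * cos(theta); vy <- speed * sin(theta)
    if (n > 1) {
      if (spec@minSeparation <= 0) {
        # contact avoidance: mice disengage after bumping, so contacts are
        # brief crossings rather than sustained wrestling bouts
        for (i in seq_len(n)) for (j in seq_len(n)) {
          if (i == j) next
          dx <- px[i] - px[j]; dy <- py[i] - py[j]
          d <- sqrt(dx^2 + dy^2)
          avoid <- 2.5 * spec@bodyAxes[2] * 2
          if (d < avoid && d > 1e-9) {
            vx[i] <- vx[i] + 0.4 * spec@speedScale * dx / d
            vy[i] <- vy[i] + 0.4 * spec@speedScale * dy / d
          }
        }
      }
      if (spec@minSeparation > 0) {
        # pairwise repulsion when closer than the floor distance
        for (i in seq_len(n)) for (j in seq_len(n)) {
          if (i == j) next
          dx <- px[i] - px[j]; dy <- py[i] - py[j]
          d <- sqrt(dx^2 + dy^2)
          if (d < spec@minSeparation * 1.3 && d > 1e-9) {
            push <- spec@speedScale * 1.5 * (spec@minSeparation * 1.3 - d) /
              (spec@minSeparation * 1.3)
            vx[i] <- vx[i] + push * dx / d
            vy[i] <- vy[i] + push * dy / d
          }
        }
      }
    }
    px <- px + vx; py <- py + vy
    # solid bodies: centres cannot interpenetrate closer than one body
    # width (contact and partial overlap still occur, pass-through not)
    if (n > 1) {
      core <- max(2 * spec@bodyAxes[2], spec@minSeparation)
      for (iter in 1:2) {
        for (i in seq_len(n - 1)) for (j in (i + 1):n) {
          dx <- px[j] - px[i]; dy <- py[j] - py[i]
          d <- sqrt(dx^2 + dy^2)
          if (d < core && d > 1e-9) {
            push <- (core - d) / 2
            px[i] <- px[i] - push * dx / d; py[i] <- py[i] - push * dy / d
            px[j] <- px[j] + push * dx / d; py[j] <- py[j] + push * dy / d
          }
        }
      }
    }
    # reflective walls
    for (i in seq_len(n)) {
      if (px[i] < margin) { px[i] <- 2 * margin - px[i]; theta[i] <- pi - theta[i] }
      if (px[i] > W - 1 - margin) { px[i] <- 2 * (W - 1 - margin) - px[i]; theta[i] <- pi - theta[i] }
      if (py[i] < margin) { py[i] <- 2 * margin - py[i]; theta[i] <- -theta[i] }
      if (py[i] > H - 1 - margin) { py[i] <- 2 * (H - 1 - margin) - py[i]; theta[i] <- -theta[i] }
    }
    px <- pmin(pmax(px, margin), W - 1 - margin)
    py <- pmin(pmax(py, margin), H - 1 - margin)
  }
  do.call(rbind, out)
}

# TRUE when some frame shows body-mask contact between any pair of subjects.
hasCrossing <- function(paths, spec) {
  reach <- 2 * (spec@bodyAxes[1] + spec@earRadius)
  for (fr in unique(paths$frame)) {
    sub <- paths[paths$frame == fr, ]
    d <- as.matrix(dist(cbind(sub$x, sub$y)))
    diag(d) <- Inf
    if (min(d) > reach) next
    masks <- lapply(seq_len(nrow(sub)), function(i)
      subjectMask(sub$x[i], sub$y[i], sub$heading[i], spec))
    if (any(occlusionFlags(masks))) return(TRUE)
  }
  FALSE
}

#' Render arena frames and ground truth from simulated paths
#'
#' Composes each frame as a uniform bright background plus Gaussian sensor
#' noise, dark ellipse bodies, and two intermediate-intensity ear disks per
#' subject at the head end. Ground truth carries, per (frame, subject), the
#' body centre and heading, the two tight ear boxes (half-open pixel
#' coordinates), and the occlusion flag recomputed from pixel-mask contact.
#'
#' @param paths the \code{paths} data.frame from
#'   \code{\link{simulateTrajectories}}.
#' @param spec the \linkS4class{ArenaSpec}.
#' @param seedUsed seed recorded by the simulation (drives the noise stream).
#' @return An \linkS4class{ArenaVideo}.
#' @export
renderFrames <- function(paths, spec, seedUsed = spec@seed) {
  validObject(spec)
  set.seed(seedUsed + 1000003L)
  H <- spec@height; W <- spec@width
  bg <- spec@intensities[["background"]]
  body_i <- spec@intensities[["body"]]
  ear_i <- spec@intensities[["ear"]]
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  frames <- vector("list", spec@nFrames)
  truth <- vector("list", spec@nFrames)
  for (t in seq_len(spec@nFrames)) {
    sub <- paths[paths$frame == t - 1L, ]
    masks <- lapply(seq_len(nrow(sub)), function(i)
      subjectMask(sub$x[i], sub$y[i], sub$heading[i], spec))
    img <- matrix(bg, H, W)
    for (m in masks) img[m] <- body_i
    ears <- vector("list", nrow(sub))
    for (i in seq_len(nrow(sub))) {
      ec <- earCentres(sub$x[i], sub$y[i], sub$heading[i], spec)
      for (k in 1:2) {
        disk <- (xs - ec[k, 1])^2 + (ys - ec[k, 2])^2 <= spec@earRadius^2
        img[disk] <- ear_i
      }
      ears[[i]] <- ec
    }
    if (spec@noiseSd > 0) {
      img <- img + matrix(rnorm(H * W, 0, spec@noiseSd), H, W)
      img <- pmin(pmax(img, 0), 255)
    }
    frames[[t]] <- img
    occ <- occlusionFlags(masks)
    r <- spec@earRadius
    truth[[t]] <- data.frame(
      frame = t - 1L, id = sub$id, x = sub$x, y = sub$y,
      heading = sub$heading,
      e1x = vapply(ears, function(e) e[1, 1], 1.0),
      e1y = vapply(ears, function(e) e[1, 2], 1.0),
      e2x = vapply(ears, function(e) e[2, 1], 1.0),
      e2y = vapply(ears, function(e) e[2, 2], 1.0),
      occluded = occ)
    truth[[t]]$e1x0 <- truth[[t]]$e1x - r; truth[[t]]$e1x1 <- truth[[t]]$e1x + r
    truth[[t]]$e1y0 <- truth[[t]]$e1y - r; truth[[t]]$e1y1 <- truth[[t]]$e1y + r
    truth[[t]]$e2x0 <- truth[[t]]$e2x - r; truth[[t]]$e2x1 <- truth[[t]]$e2x + r
    truth[[t]]$e2y0 <- truth[[t]]$e2y - r; truth[[t]]$e2y1 <- truth[[t]]$e2y + r
  }
  new("ArenaVideo",
      frames = FrameSequence(frames, frameRate = spec@frameRate),
      truth = do.call(rbind, truth), spec = spec, seedUsed = seedUsed)
}

#' Simulate and render a synthetic arena video
#'
#' Convenience wrapper running \code{\link{simulateTrajectories}} then
#' \code{\link{renderFrames}}.
#'
#' @param spec an \linkS4class{ArenaSpec}.
#' @return An \linkS4class{ArenaVideo}.
#' @examples
#' av <- simulateArena(ArenaSpec(nFrames = 10, nSubjects = 1, noiseSd = 0))
#' av
#' @export
simulateArena <- function(spec) {
  sim <- simulateTrajectories(spec)
  renderFrames(sim$paths, spec, seedUsed = sim$seedUsed)
}

#' Ground-truth ear labels of an arena video
#'
#' Flattens the two ear boxes per subject into the label-record layout used
#' by \code{\link{writeLabels}} (class 0 = ear). Ear identities are numbered
#' \code{2 * subject - 1} and \code{2 * subject}.
#'
#' @param video an \linkS4class{ArenaVideo}.
#' @return data.frame with columns frame, class, x0, y0, x1, y1, id.
#' @export
arenaLabels <- function(video) {
  tr <- video@truth
  rbind(
    data.frame(frame = tr$frame, class = 0L, x0 = tr$e1x0, y0 = tr$e1y0,
               x1 = tr$e1x1, y1 = tr$e1y1, id = 2L * tr$id - 1L),
    data.frame(frame = tr$frame, class = 0L, x0 = tr$e2x0, y0 = tr$e2y0,
               x1 = tr$e2x1, y1 = tr$e2y1, id = 2L * tr$id))
}

#' Ground-truth body-centre tracks of an arena video
#'
#' @param video an \linkS4class{ArenaVideo}.
#' @return track data.frame (frame, id, x, y, conf).
#' @export
arenaTracks <- function(video) {
  tr <- video@truth
  data.frame(frame = tr$frame, id = tr$id, x = tr$x, y = tr$y, conf = 1)
}
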