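# Locomotion analytics on trajectories: per-frame velocity and 5-minute
# block means, the two-dimensional population standard deviation of the
# spatial distribution, 12-region occupancy over the open field's main
# region, and the rank-sum comparison used for group contrasts.

#' Velocity series and block means of a trajectory
#'
#' Per-step speed is the Euclidean step length times the frame rate divided
#' by the pixel calibration, in cm/s. Steps that span a gap (missing frames
#' or positions flagged \code{gap}) are excluded from both the series and
#' the block means. Block means average over non-overlapping windows of
#' \code{blockSeconds} (default 300 s, so a 40-min video yields 8 blocks).
#'
#' @param traj data.frame (frame, x, y, optionally source) of one
#'   individual, pixel coordinates.
#' @param frameRate frames per second.
#' @param pxPerCm pixels per centimetre.
#' @param blockSeconds block length in seconds.
#' @return list with \code{speeds} (data.frame frame, speed),
#'   \code{blockMeans} (one per block), \code{frameRate}, \code{pxPerCm}.
#' @export
velocitySeries <- function(traj, frameRate, pxPerCm, blockSeconds = 300) {
  if (pxPerCm <= 0) stop("pxPerCm must be positive")
  traj <- traj[order(traj$frame), , drop = FALSE]
  if (!is.null(traj$source)) traj <- traj[traj$source != "gap", , drop = FALSE]
  if (nrow(traj) < 2) stop("trajectory must contain at least two positions")
  d <- diff(traj$frame)
  ok <- which(d == 1)
  if (length(ok) == 0) stop("no adjacent-frame steps in trajectory")
  speed <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)[ok] * frameRate / pxPerCm
  frame <- traj$frame[ok]
  duration <- (max(traj$frame) + 1) / frameRate
  n_blocks <- ceiling(duration / blockSeconds)
  block <- pmin(floor(frame / (blockSeconds * frameRate)), n_blocks - 1)
  bm <- rep(NA_real_, n_blocks)
  agg <- tapply(speed, block, mean)
  bm[as.integer(names(agg)) + 1] <- agg
  list(speeds = data.frame(frame = frame, speed = speed),
       blockMeans = bm, frameRate = frameRate, pxPerCm = pxPerCm)
}

#' Two-dimensional spatial standard deviation
#'
#' The population (divide-by-n) standard deviation extended to the plane:
#' \code{sigma = sqrt(sum((x - mean(x))^2 + (y - mean(y))^2) / n)}. Zero
#' exactly when all points coincide; reduces to the 1-D population SD of x
#' when all y are equal.
#'
#' @param x,y coordinates (cm or any consistent unit).
#' @return list with \code{meanX}, \code{meanY}, \code{sigma2d}, \code{n}.
#' @export
spatialSD <- function(x, y) {
  if (length(x) == 0 || length(x) != length(y))
    stop("x and y must be non-empty and of equal length")
  mx <- mean(x); my <- mean(y)
  list(meanX = mx, meanY = my,
       sigma2d = sqrt(sum((x - mx)^2 + (y - my)^2) / length(x)),
       n = length(x))
}

#' Region occupancy over the open field's main region
#'
#' The main region (by default horizontal 320--960, vertical 240--720 at
#' the reference resolution) is divided into a grid of 160 x 160 px cells
#' numbered row-major 1--12 (left to right, then top to bottom); each
#' in-bounds frame increments its cell and fractions are counts divided by
#' the total frame count (so they sum to at most 1, frames outside the main
#' region being excluded).
#'
#' @param traj data.frame (frame, x, y), pixel coordinates at the grid's
#'   reference resolution.
#' @param xRange,yRange main-region bounds, pixels.
#' @param cellSize square cell side, pixels.
#' @param numbering optional integer permutation of the row-major region
#'   numbers.
#' @return list with \code{fractions} (named by region), \code{counts},
#'   \code{nFrames}.
#' @export
regionOccupancy <- function(traj, xRange = c(320, 960), yRange = c(240, 720),
                            cellSize = 160, numbering = NULL) {
  ncol_ <- (xRange[2] - xRange[1]) / cellSize
  nrow_ <- (yRange[2] - yRange[1]) / cellSize
  if (ncol_ %% 1 != 0 || nrow_ %% 1 != 0)
    stop("region bounds are not evenly divisible by the cell size")
  ncol_ <- as.integer(ncol_); nrow_ <- as.integer(nrow_)
  n_regions <- ncol_ * nrow_
  if (is.null(numbering)) numbering <- seq_len(n_regions)
  if (!identical(sort(numbering), seq_len(n_regions)))
    stop("numbering must be a permutation of 1..", n_regions)
  inb <- traj$x >= xRange[1] & traj$x < xRange[2] &
         traj$y >= yRange[1] & traj$y < yRange[2]
  col <- floor((traj$x[inb] - xRange[1]) / cellSize)
  row <- floor((traj$y[inb] - yRange[1]) / cellSize)
  region <- numbering[row * ncol_ + col + 1]
  counts <- tabulate(region, nbins = n_regions)
  names(counts) <- seq_len(n_regions)
  list(fractions = counts / nrow(traj), counts = counts,
       nFrames = nrow(traj))
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact-distribution p-value when the combined sample size is at most 20
#' and no ties are present; normal approximation with tie correction
#' otherwise. Completely tied data (every value equal across both samples)
#' degenerates to p = 1.
#'
#' @param a,b numeric samples.
#' @return two-sided p-value.
#' @export
rankSumTest <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1) {
    logMsg("warn", "rank-sum test on fully tied data; returning p = 1")
    return(1)
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= 20 && !ties
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = !exact)$p.value)
}
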