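# Identity propagation across non-occlusion frames: in adjacent frames of a
# high-frame-rate video a subject barely moves, so the blob sharing the most
# pixels with an identified blob of the previous frame inherits its identity.
# The per-blob rule is enforced as a global bijective matching (one blob, one
# individual), with the tie-break chain overlap -> IoU -> incumbent order.

blobIoU <- function(a, b) {
  inter <- length(intersect(a$pixels, b$pixels))
  inter / (a$area + b$area - inter)
}

#' Propagate identities from one frame's blobs to the next
#'
#' Finds the one-to-one assignment of previous (identified) blobs to next
#' blobs that maximizes total shared-pixel count; each next blob inherits the
#' identity of its matched predecessor. Ties resolve by larger IoU, then by
#' incumbent identity order. A blob with zero overlap against every
#' predecessor falls back to nearest-centroid matching (a warning is
#' logged).
#'
#' @param prevBlobs list of blobs (see \code{\link{segmentBlobs}}), each with
#'   an \code{id} field.
#' @param nextBlobs list of blobs of the following frame, same length.
#' @return \code{nextBlobs} with inherited \code{id} fields.
#' @export
propagateIds <- function(prevBlobs, nextBlobs) {
  n <- length(prevBlobs)
  if (length(nextBlobs) != n)
    stop("blob count mismatch between adjacent non-occlusion frames")
  ids <- vapply(prevBlobs, function(b) b$id, 1L)
  ov <- matrix(0, n, n)
  io <- matrix(0, n, n)
  dist2 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      inter <- length(intersect(prevBlobs[[i]]$pixels, nextBlobs[[j]]$pixels))
      ov[i, j] <- inter
      io[i, j] <- inter / (prevBlobs[[i]]$area + nextBlobs[[j]]$area - inter)
      dist2[i, j] <- sum((prevBlobs[[i]]$centroid - nextBlobs[[j]]$centroid)^2)
    }
  }
  if (any(apply(ov, 2, max) == 0))
    logMsg("warn", "blob with zero overlap; falling back to nearest centroid")
  # lexicographic objective folded into one score: overlap, then IoU, then
  # centroid proximity (the zero-overlap fallback), then a deterministic
  # preference for low incumbent identity taking the earlier (larger) blob
  rank_i <- rank(ids, ties.method = "first")
  pref <- outer(n - rank_i, n - seq_len(n)) * 1e-9
  score <- ov * 1e8 + io * 1e2 + 1 / (1 + dist2) + pref
  assign <- solveAssignment(-score)
  for (i in seq_len(n)) nextBlobs[[assign[i]]]$id <- ids[i]
  nextBlobs
}

#' Track identities through a non-occlusion fragment
#'
#' Applies \code{\link{propagateIds}} frame by frame. Identities on the first
#' frame come from \code{seedIds} (one per blob, blobs in descending area
#' order) when linking supplies them, else 1..n in descending-area order.
#'
#' @param blobsPerFrame list (one element per frame of the fragment) of blob
#'   lists, each of length nSubjects.
#' @param seedIds optional integer vector of first-frame identities.
#' @param startFrame 0-based index of the fragment's first frame.
#' @return list with \code{tracks} (data.frame frame, id, x, y, conf) and
#'   \code{idsPerFrame} (list of per-blob identity vectors, aligned with
#'   \code{blobsPerFrame}).
#' @export
trackFragment <- function(blobsPerFrame, seedIds = NULL, startFrame = 0L) {
  nf <- length(blobsPerFrame)
  if (nf == 0) return(list(tracks = data.frame(), idsPerFrame = list()))
  n <- length(blobsPerFrame[[1]])
  for (t in seq_len(nf)) {
    if (length(blobsPerFrame[[t]]) != n)
      stop("frame ", startFrame + t - 1,
           " has wrong blob count inside a non-occlusion fragment")
  }
  if (is.null(seedIds)) seedIds <- seq_len(n)
  if (length(seedIds) != n) stop("seedIds must have one identity per blob")
  cur <- blobsPerFrame[[1]]
  for (i in seq_len(n)) cur[[i]]$id <- as.integer(seedIds[i])
  idsPerFrame <- vector("list", nf)
  rows <- vector("list", nf)
  for (t in seq_len(nf)) {
    if (t > 1) cur <- propagateIds(cur, blobsPerFrame[[t]])
    idsPerFrame[[t]] <- vapply(cur, function(b) b$id, 1L)
    rows[[t]] <- data.frame(
      frame = startFrame + t - 1L,
      id = idsPerFrame[[t]],
      x = vapply(cur, function(b) b$centroid[1], 1.0),
      y = vapply(cur, function(b) b$centroid[2], 1.0),
      conf = 1)
  }
  tracks <- do.call(rbind, rows)
  tracks <- tracks[order(tracks$frame, tracks$id), ]
  rownames(tracks) <- NULL
  list(tracks = tracks, idsPerFrame = idsPerFrame)
}
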