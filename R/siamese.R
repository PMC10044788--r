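# Dual-Siamese similarity model for ear identity assignment in occlusion
# frames. One Siamese branch embeds the fixed-size ear image crop (a small
# convolutional network applied with shared weights to both crops of a
# pair), the other embeds the ear centroid (a small fully connected network,
# also weight-shared). Each branch is trained with a contrastive loss on its
# embedding distance; a two-layer fully connected fusion head maps the pair
# of branch distance signals to a similarity score in [0, 1], trained with
# binary cross-entropy. Identity assignment across adjacent frames is a
# globally optimal matching on 1 - score.

#' Siamese model configuration
#'
#' @param cropSize side length of the square ear crop in pixels (default 32,
#'   matching the scale at which an ear occupies roughly 30 x 30 pixels in a
#'   full-resolution recording).
#' @param embedDim embedding dimension of both branches.
#' @param margin contrastive-loss margin.
#' @param epochs,batchSize,learningRate,momentum training settings.
#' @param minScore assignment rejection threshold.
#' @param negGapSeconds minimum temporal gap of a negative pair, seconds.
#' @param seed RNG seed.
#' @return named list of settings.
#' @export
siameseConfig <- function(cropSize = 32L, embedDim = 16L, margin = 1,
                          epochs = 10L, batchSize = 16L, learningRate = 0.01,
                          momentum = 0.9, minScore = 0.2, negGapSeconds = 60,
                          seed = 1L) {
  list(crop_size = as.integer(cropSize), embed_dim = as.integer(embedDim),
       margin = margin, epochs = as.integer(epochs),
       batch_size = as.integer(batchSize), learning_rate = learningRate,
       momentum = momentum, min_score = minScore,
       neg_gap_seconds = negGapSeconds, seed = as.integer(seed))
}

#' Build an (untrained) dual-Siamese similarity model
#'
#' @param config from \code{\link{siameseConfig}}.
#' @return A \linkS4class{SiameseModel}.
#' @export
buildSiamese <- function(config = siameseConfig()) {
  set.seed(config$seed)
  e <- config$embed_dim
  p <- list()
  # image branch (shared across the twin inputs)
  p <- addCBL(p, "ic1", 1L, 8L, 3L)
  p <- addCBL(p, "ic2", 8L, 16L, 3L)
  p[["ifc.w"]] <- initFCW(16L, e); p[["ifc.b"]] <- numeric(e)
  # coordinate branch (shared across the twin inputs)
  p[["cf1.w"]] <- initFCW(2L, 16L); p[["cf1.b"]] <- numeric(16L)
  p[["cf2.w"]] <- initFCW(16L, e);  p[["cf2.b"]] <- numeric(e)
  # fusion head on the two branch distance signals
  p[["ff1.w"]] <- initFCW(2L, 8L);  p[["ff1.b"]] <- numeric(8L)
  p[["ff2.w"]] <- initFCW(8L, 1L);  p[["ff2.b"]] <- numeric(1L)
  new("SiameseModel", params = p, config = config, stats = list(),
      trained = FALSE, version = "mrtrack-siamese-1")
}

#' Build an ear observation
#'
#' Extracts the fixed-size crop centred on the detection box (clamped at
#' frame borders) and records the box, centroid and frame index.
#'
#' @param frame numeric matrix, the full frame.
#' @param frameIndex 0-based frame index.
#' @param box numeric c(x0, y0, x1, y1), half-open pixel coordinates.
#' @param id optional ear identity.
#' @param cropSize crop side length.
#' @return list with fields frame, box, crop, centroid, id.
#' @export
makeObservation <- function(frame, frameIndex, box, id = NA_integer_,
                            cropSize = 32L) {
  cx <- (box[1] + box[3]) / 2
  cy <- (box[2] + box[4]) / 2
  H <- nrow(frame); W <- ncol(frame)
  half <- cropSize %/% 2L
  x0 <- round(cx) - half; y0 <- round(cy) - half
  x0 <- min(max(x0, 0), W - cropSize)
  y0 <- min(max(y0, 0), H - cropSize)
  crop <- frame[(y0 + 1):(y0 + cropSize), (x0 + 1):(x0 + cropSize),
                drop = FALSE]
  list(frame = as.integer(frameIndex), box = as.numeric(box), crop = crop,
       centroid = c(cx, cy), id = id)
}

#' Construct training pairs from identified ear observations
#'
#' Positive pairs are the same ear identity in adjacent kept frames;
#' negative pairs are observations separated by more than
#' \code{negGapSeconds * frameRate} frames. Both sets are sampled without
#' replacement to the requested sizes, reproducibly for a given seed.
#'
#' @param observations list of identified observations
#'   (\code{\link{makeObservation}} with \code{id} set).
#' @param frameRate frames per second of the kept frames.
#' @param negGapSeconds minimum temporal gap of a negative, seconds.
#' @param nPos,nNeg requested sample sizes.
#' @param seed RNG seed.
#' @return data.frame with columns \code{i}, \code{j} (indices into
#'   \code{observations}) and \code{label} (1 positive, 0 negative).
#' @export
makePairs <- function(observations, frameRate, negGapSeconds = 60,
                      nPos = 100L, nNeg = 100L, seed = 1L) {
  if (frameRate <= 0) stop("frameRate must be positive")
  ids <- vapply(observations, function(o) as.integer(o$id), 1L)
  frames <- vapply(observations, function(o) o$frame, 1L)
  if (anyNA(ids)) stop("observations must carry identities")
  kept <- sort(unique(frames))
  nextKept <- setNames(c(kept[-1], NA), as.character(kept))
  pos <- list()
  for (id in unique(ids)) {
    sel <- which(ids == id)
    sel <- sel[order(frames[sel])]
    fr <- frames[sel]
    nxt <- match(nextKept[as.character(fr)], fr)
    ok <- which(!is.na(nxt))
    if (length(ok))
      pos[[length(pos) + 1]] <- data.frame(i = sel[ok], j = sel[nxt[ok]])
  }
  pos <- if (length(pos)) do.call(rbind, pos) else
    data.frame(i = integer(), j = integer())
  gap <- negGapSeconds * frameRate
  ut <- which(outer(frames, frames, function(a, b) b - a) > gap, arr.ind = TRUE)
  neg <- data.frame(i = ut[, 1], j = ut[, 2])
  if (nPos > nrow(pos))
    stop("requested ", nPos, " positives but only ", nrow(pos), " available")
  if (nNeg > nrow(neg))
    stop("requested ", nNeg, " negatives but only ", nrow(neg), " available")
  set.seed(seed)
  pos <- pos[sample.int(nrow(pos), nPos), , drop = FALSE]
  neg <- neg[sample.int(nrow(neg), nNeg), , drop = FALSE]
  out <- rbind(cbind(pos, label = 1L), cbind(neg, label = 0L))
  rownames(out) <- NULL
  out
}

#' Contrastive loss
#'
#' \code{label = 1} (same identity): squared distance; \code{label = 0}
#' (different context): squared hinge beyond the margin,
#' \code{max(0, margin - distance)^2}.
#'
#' @param distance nonnegative embedding distance.
#' @param label 0 or 1.
#' @param margin positive margin.
#' @return the loss value.
#' @export
contrastiveLoss <- function(distance, label, margin = 1) {
  if (margin <= 0) stop("margin must be positive")
  if (any(distance < 0)) stop("distance must be nonnegative")
  ifelse(label == 1, distance^2, pmax(0, margin - distance)^2)
}

# Forward the image branch for one crop (values 0-255); returns embedding
# node. Weight sharing is structural: the same parameter nodes serve every
# input passed through this function on one tape.
imageBranch <- function(tape, pid, crop, ctx = NULL) {
  x <- tLeaf(tape, crop / 255 - 0.5, c(dim(crop), 1L))
  h <- fwdCBL(tape, pid, "ic1", x, 3L, 2L, ctx = ctx)
  h <- fwdCBL(tape, pid, "ic2", h, 3L, 2L, ctx = ctx)
  g <- tGlobalMean(tape, h)
  tFC(tape, g, pid[["ifc.w"]], pid[["ifc.b"]])
}

coordBranch <- function(tape, pid, xy01) {
  x <- tLeaf(tape, xy01, 2L)
  h <- tRelu(tape, tFC(tape, x, pid[["cf1.w"]], pid[["cf1.b"]]))
  tFC(tape, h, pid[["cf2.w"]], pid[["cf2.b"]])
}

# Fusion logit node from the two scalar distance nodes.
fusionLogit <- function(tape, pid, dImg, dCoord) {
  z <- tConcatVec(tape, list(dImg, dCoord))
  h <- tRelu(tape, tFC(tape, z, pid[["ff1.w"]], pid[["ff1.b"]]))
  tFC(tape, h, pid[["ff2.w"]], pid[["ff2.b"]])
}

# Per-pair loss node: contrastive on both branch distances + BCE on the
# fusion score.
pairLossNode <- function(tape, pid, oa, ob, label, config, frameDims,
                         ctx = NULL) {
  ea <- imageBranch(tape, pid, oa$crop, ctx = ctx)
  eb <- imageBranch(tape, pid, ob$crop, ctx = ctx)
  dI <- tL2Dist(tape, ea, eb)
  ca <- coordBranch(tape, pid, oa$centroid / frameDims)
  cb <- coordBranch(tape, pid, ob$centroid / frameDims)
  dC <- tL2Dist(tape, ca, cb)
  lI <- tContrastive(tape, dI, label, config$margin)
  lC <- tContrastive(tape, dC, label, config$margin)
  logit <- fusionLogit(tape, pid, dI, dC)
  lF <- tBCE(tape, logit, label)
  tWeightedSum(tape, list(lI, lC, lF), c(1, 1, 1))
}

#' Train the dual-Siamese similarity model
#'
#' Both branch losses are contrastive on the branch embedding distances; the
#' fusion head is trained with binary cross-entropy on the pair labels.
#' Weight sharing between the twin paths is structural (one parameter set,
#' applied to both inputs), so twin parameters are identical after every
#' step by construction.
#'
#' @param model a \linkS4class{SiameseModel}.
#' @param observations list of observations indexed by the pair table.
#' @param pairs data.frame from \code{\link{makePairs}}.
#' @param frameDims c(width, height) in pixels, for coordinate
#'   normalization to [0, 1].
#' @return the trained model, per-epoch mean loss in
#'   \code{@config$loss_log}.
#' @export
trainSimilarity <- function(model, observations, pairs, frameDims) {
  config <- model@config
  if (length(unique(pairs$label)) < 2)
    stop("pairs must contain both classes")
  set.seed(config$seed + 1L)
  params <- model@params
  state <- lapply(params, function(p) array(0, dim(as.array(p))))
  stats <- newStatsStore()
  ctx <- list(train = TRUE, stats = stats, momentum = 0.1)
  n <- nrow(pairs)
  steps_per_epoch <- ceiling(n / config$batch_size)
  total_steps <- config$epochs * steps_per_epoch
  step <- 0
  loss_log <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (bi in seq_len(steps_per_epoch)) {
      sel <- ord[((bi - 1) * config$batch_size + 1):min(bi * config$batch_size, n)]
      step <- step + 1
      lr <- oneCycleLR(step, total_steps, config$learning_rate, 0.2)
      tape <- newTape()
      pid <- paramNodes(tape, params)
      terms <- integer(length(sel))
      for (k in seq_along(sel)) {
        pr <- pairs[sel[k], ]
        terms[k] <- pairLossNode(tape, pid, observations[[pr$i]],
                                 observations[[pr$j]], pr$label, config,
                                 frameDims, ctx = ctx)
      }
      loss <- tWeightedSum(tape, as.list(terms),
                           rep(1 / length(sel), length(sel)))
      grads <- tBackward(tape, loss)
      pg <- paramGrads(grads, pid, params)
      upd <- sgdStep(params, pg, state, lr, config$momentum)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + nodeValue(tape, loss)
    }
    loss_log[ep] <- ep_loss / steps_per_epoch
    logMsg("debug", "siamese epoch %d/%d loss %.4f", ep, config$epochs,
           loss_log[ep])
  }
  model@params <- params
  model@config$loss_log <- loss_log
  model@stats <- as.list(stats)
  model@trained <- TRUE
  model
}

#' Similarity score of two ear observations
#'
#' Runs both Siamese branches and the fusion head; the branch inputs enter
#' symmetrically (the fusion head sees only the two distances), so the score
#' is symmetric in its arguments by construction.
#'
#' @param model a trained \linkS4class{SiameseModel}.
#' @param obsA,obsB observations from \code{\link{makeObservation}}.
#' @param frameDims c(width, height) in pixels.
#' @return similarity score in [0, 1].
#' @export
pairSimilarity <- function(model, obsA, obsB, frameDims) {
  if (!all(dim(obsA$crop) == dim(obsB$crop)) ||
      nrow(obsA$crop) != model@config$crop_size)
    stop("crop size mismatch with the model configuration")
  tape <- newTape()
  pid <- paramNodes(tape, model@params)
  ctx <- list(train = FALSE, stats = model@stats)
  ea <- imageBranch(tape, pid, obsA$crop, ctx = ctx)
  eb <- imageBranch(tape, pid, obsB$crop, ctx = ctx)
  dI <- tL2Dist(tape, ea, eb)
  ca <- coordBranch(tape, pid, obsA$centroid / frameDims)
  cb <- coordBranch(tape, pid, obsB$centroid / frameDims)
  dC <- tL2Dist(tape, ca, cb)
  logit <- fusionLogit(tape, pid, dI, dC)
  1 / (1 + exp(-nodeValue(tape, logit)))
}

#' Assign ear identities across adjacent frames
#'
#' Builds the similarity matrix between identified previous observations and
#' unidentified next observations, solves the globally optimal one-to-one
#' matching on cost \code{1 - score}, and rejects matches whose score falls
#' below \code{minScore} (those observations stay unassigned and surface as
#' misses downstream).
#'
#' @param model a trained \linkS4class{SiameseModel}.
#' @param prevObs identified observations (with \code{id}).
#' @param nextObs unidentified observations.
#' @param frameDims c(width, height) pixels.
#' @param minScore rejection threshold.
#' @return \code{nextObs} with \code{id} fields set (NA where unassigned).
#' @export
assignIdentities <- function(model, prevObs, nextObs, frameDims,
                             minScore = model@config$min_score) {
  if (length(nextObs) == 0) return(nextObs)
  if (length(prevObs) < 1) stop("need at least one identified observation")
  np <- length(prevObs); nn <- length(nextObs)
  S <- matrix(0, np, nn)
  for (i in seq_len(np)) for (j in seq_len(nn))
    S[i, j] <- pairSimilarity(model, prevObs[[i]], nextObs[[j]], frameDims)
  for (j in seq_len(nn)) nextObs[[j]]$id <- NA_integer_
  if (np <= nn) {
    assign <- solveAssignment(1 - S)
    for (i in seq_len(np)) {
      if (S[i, assign[i]] >= minScore)
        nextObs[[assign[i]]]$id <- prevObs[[i]]$id
    }
  } else {
    assign <- solveAssignment(t(1 - S))    # each next obs picks a prev
    for (j in seq_len(nn)) {
      if (S[assign[j], j] >= minScore)
        nextObs[[j]]$id <- prevObs[[assign[j]]]$id
    }
  }
  nextObs
}

#' Track ear identities through an occlusion fragment
#'
#' Seeds identities on the first frame's observations and then assigns each
#' subsequent frame's observations against the most recent observation of
#' every known identity (so a briefly undetected ear can be re-acquired).
#'
#' @param model trained \linkS4class{SiameseModel}.
#' @param obsPerFrame list over frames of observation lists.
#' @param initIds identities of the first frame's observations.
#' @param frameDims c(width, height) pixels.
#' @param frames 0-based frame indices corresponding to obsPerFrame.
#' @return data.frame (frame, ear, x, y) of assigned ear positions.
#' @export
trackEarFragment <- function(model, obsPerFrame, initIds, frameDims,
                             frames = seq_along(obsPerFrame) - 1L) {
  stopifnot(length(obsPerFrame) >= 1)
  first <- obsPerFrame[[1]]
  stopifnot(length(initIds) == length(first))
  lastSeen <- list()
  rows <- list()
  for (k in seq_along(first)) {
    first[[k]]$id <- as.integer(initIds[k])
    lastSeen[[as.character(initIds[k])]] <- first[[k]]
  }
  emit <- function(obs, fr) {
    ids <- vapply(obs, function(o) as.integer(o$id), 1L)
    ok <- which(!is.na(ids))
    if (!length(ok)) return(NULL)
    data.frame(frame = fr, ear = ids[ok],
               x = vapply(obs[ok], function(o) o$centroid[1], 1.0),
               y = vapply(obs[ok], function(o) o$centroid[2], 1.0))
  }
  rows[[1]] <- emit(first, frames[1])
  for (t in seq_along(obsPerFrame)[-1]) {
    obs <- obsPerFrame[[t]]
    if (length(obs) > 0) {
      prev <- unname(lastSeen)
      obs <- assignIdentities(model, prev, obs, frameDims)
      for (o in obs) {
        if (!is.na(o$id)) lastSeen[[as.character(o$id)]] <- o
      }
    }
    rows[[t]] <- emit(obs, frames[t])
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(frame = integer(), ear = integer(),
                                      x = numeric(), y = numeric())
  out
}

#' Group assigned ears into individual positions
#'
#' Each individual owns up to two ear identities (fixed at initialization
#' from the flanking non-occlusion frame by blob membership); its per-frame
#' position is the mean of its visible ear centroids, one visible ear
#' sufficing.
#'
#' @param earTracks data.frame (frame, ear, x, y).
#' @param earToIndividual named integer vector mapping ear identity to
#'   individual label.
#' @return data.frame (frame, ind, x, y).
#' @export
groupEarsToIndividuals <- function(earTracks, earToIndividual) {
  if (nrow(earTracks) == 0)
    return(data.frame(frame = integer(), ind = integer(), x = numeric(),
                      y = numeric()))
  ind <- earToIndividual[as.character(earTracks$ear)]
  if (anyNA(ind)) stop("ear identity assigned to no individual")
  agg <- aggregate(cbind(x, y) ~ frame + ind,
                   data = cbind(earTracks, ind = as.integer(ind)), FUN = mean)
  agg[order(agg$frame, agg$ind), ]
}
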