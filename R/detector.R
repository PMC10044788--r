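# Anchor-based single-class ("ear") detector at desk scale. The backbone is
# a CSP-style convolutional pyramid opened by a Focus (space-to-depth) stem
# and closed by an SPP multi-scale max-pool fusion; the neck performs
# top-down plus bottom-up path aggregation over the configured levels. The
# improvement under study is a fourth, low-level (stride-4) lateral
# connection into the neck with its own prediction head, aimed at objects of
# only a few pixels. Width and depth are config-scaled far below the
# published full-scale network; the topology is the object of interest.

#' Detector configuration
#'
#' @param imgSize input image side length (must be divisible by the largest
#'   stride; images are square at desk scale).
#' @param improved add the stride-4 low-level pyramid connection and head.
#' @param baseWidth channel width unit of the backbone.
#' @param nAnchors anchors per level.
#' @param confidenceThreshold detection score cutoff.
#' @param nmsIoU IoU threshold of non-maximum suppression.
#' @param epochs,batchSize,learningRate,finalLrFactor,momentum training
#'   settings (defaults follow the network's published hyper-parameter
#'   table: SGD, batch 8, lr 0.01, one-cycle final factor 0.2,
#'   momentum 0.937).
#' @param boxWeight,objWeight,posWeight loss term weights (box regression,
#'   objectness, positive-cell emphasis).
#' @param seed RNG seed for initialization and batch shuffling.
#' @return named list of detector settings; strides are \{8, 16, 32\}
#'   for the baseline and \{4, 8, 16, 32\} when improved.
#' @export
detectorConfig <- function(imgSize = 128L, improved = TRUE, baseWidth = 8L,
                           nAnchors = 2L, confidenceThreshold = 0.5,
                           nmsIoU = 0.45, epochs = 50L, batchSize = 8L,
                           learningRate = 0.01, finalLrFactor = 0.2,
                           momentum = 0.937, boxWeight = 1, objWeight = 1,
                           posWeight = 20, seed = 1L) {
  strides <- if (improved) c(4L, 8L, 16L, 32L) else c(8L, 16L, 32L)
  if (imgSize %% max(strides) != 0)
    stop("imgSize must be divisible by the largest stride (",
         max(strides), ")")
  list(img_size = as.integer(imgSize), improved = improved,
       strides = strides, base_width = as.integer(baseWidth),
       n_anchors = as.integer(nAnchors),
       confidence_threshold = confidenceThreshold, nms_iou = nmsIoU,
       epochs = as.integer(epochs), batch_size = as.integer(batchSize),
       learning_rate = learningRate, final_lr_factor = finalLrFactor,
       momentum = momentum, box_weight = boxWeight, obj_weight = objWeight,
       pos_weight = posWeight, seed = as.integer(seed))
}

#' Focus (space-to-depth) transform
#'
#' Rearranges the four 2x2 spatial phases of an image into channels:
#' (H, W, C) becomes (H/2, W/2, 4C). Lossless; \code{inverse = TRUE}
#' inverts it.
#'
#' @param x numeric array (H, W, C) or matrix (H, W).
#' @param inverse undo the transform.
#' @return the transformed array.
#' @export
focusTransform <- function(x, inverse = FALSE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  if (!inverse) {
    if (d[1] %% 2 != 0 || d[2] %% 2 != 0)
      stop("spatial dimensions must be even")
    H <- d[1]; W <- d[2]; C <- d[3]
    out <- array(0, c(H / 2, W / 2, 4 * C))
    out[, , 1:C] <- x[seq(1, H, 2), seq(1, W, 2), , drop = FALSE]
    out[, , (C + 1):(2 * C)] <- x[seq(2, H, 2), seq(1, W, 2), , drop = FALSE]
    out[, , (2 * C + 1):(3 * C)] <- x[seq(1, H, 2), seq(2, W, 2), , drop = FALSE]
    out[, , (3 * C + 1):(4 * C)] <- x[seq(2, H, 2), seq(2, W, 2), , drop = FALSE]
    out
  } else {
    if (d[3] %% 4 != 0) stop("channel count must be divisible by 4")
    C <- d[3] / 4; H <- 2 * d[1]; W <- 2 * d[2]
    out <- array(0, c(H, W, C))
    out[seq(1, H, 2), seq(1, W, 2), ] <- x[, , 1:C, drop = FALSE]
    out[seq(2, H, 2), seq(1, W, 2), ] <- x[, , (C + 1):(2 * C), drop = FALSE]
    out[seq(1, H, 2), seq(2, W, 2), ] <- x[, , (2 * C + 1):(3 * C), drop = FALSE]
    out[seq(2, H, 2), seq(2, W, 2), ] <- x[, , (3 * C + 1):(4 * C), drop = FALSE]
    out
  }
}

# ---- parameter construction ---------------------------------------------

addCBL <- function(params, name, cin, cout, k) {
  params[[paste0(name, ".w")]] <- initConvW(k, cin, cout)
  params[[paste0(name, ".b")]] <- numeric(cout)
  params[[paste0(name, ".g")]] <- rep(1, cout)
  params[[paste0(name, ".be")]] <- numeric(cout)
  params
}

addCSP <- function(params, name, c) {
  h <- max(c %/% 2L, 2L)
  params <- addCBL(params, paste0(name, ".ca"), c, h, 1L)
  params <- addCBL(params, paste0(name, ".cb"), c, h, 1L)
  params <- addCBL(params, paste0(name, ".r1"), h, h, 1L)
  params <- addCBL(params, paste0(name, ".r2"), h, h, 3L)
  addCBL(params, paste0(name, ".out"), 2L * h, c, 1L)
}

buildDetectorParams <- function(config) {
  w <- config$base_width
  p <- list()
  p <- addCBL(p, "stem", 4L, w, 3L)
  p <- addCBL(p, "d2", w, 2L * w, 3L);      p <- addCSP(p, "c2", 2L * w)
  p <- addCBL(p, "d3", 2L * w, 4L * w, 3L); p <- addCSP(p, "c3", 4L * w)
  p <- addCBL(p, "d4", 4L * w, 6L * w, 3L); p <- addCSP(p, "c4", 6L * w)
  p <- addCBL(p, "d5", 6L * w, 8L * w, 3L)
  p <- addCBL(p, "spp.a", 8L * w, 4L * w, 1L)
  p <- addCBL(p, "spp.b", 12L * w, 8L * w, 1L)
  p <- addCSP(p, "c5", 8L * w)
  # top-down neck
  p <- addCBL(p, "p5", 8L * w, 4L * w, 1L)
  p <- addCBL(p, "n4a", 10L * w, 4L * w, 1L)
  p <- addCBL(p, "n4b", 4L * w, 4L * w, 3L)
  p <- addCBL(p, "p4", 4L * w, 2L * w, 1L)
  p <- addCBL(p, "n3a", 6L * w, 2L * w, 1L)
  p <- addCBL(p, "n3b", 2L * w, 2L * w, 3L)
  if (config$improved) {
    # the extra low-level (stride-4) lateral connection
    p <- addCBL(p, "p3", 2L * w, 2L * w, 1L)
    p <- addCBL(p, "n2a", 4L * w, 2L * w, 1L)
    p <- addCBL(p, "n2b", 2L * w, 2L * w, 3L)
    p <- addCBL(p, "u3", 2L * w, 2L * w, 3L)
    p <- addCBL(p, "m3a", 4L * w, 2L * w, 1L)
    p <- addCBL(p, "m3b", 2L * w, 2L * w, 3L)
  }
  # bottom-up path
  p <- addCBL(p, "u4", 2L * w, 2L * w, 3L)
  p <- addCBL(p, "m4a", 6L * w, 4L * w, 1L)
  p <- addCBL(p, "m4b", 4L * w, 4L * w, 3L)
  p <- addCBL(p, "u5", 4L * w, 4L * w, 3L)
  p <- addCBL(p, "m5a", 8L * w, 4L * w, 1L)
  p <- addCBL(p, "m5b", 4L * w, 4L * w, 3L)
  # heads: 1x1 conv to n_anchors * 5 channels per level
  no <- config$n_anchors * 5L
  if (config$improved) p[["h2.w"]] <- initConvW(1L, 2L * w, no)
  if (config$improved) p[["h2.b"]] <- numeric(no)
  p[["h3.w"]] <- initConvW(1L, 2L * w, no); p[["h3.b"]] <- numeric(no)
  p[["h4.w"]] <- initConvW(1L, 4L * w, no); p[["h4.b"]] <- numeric(no)
  p[["h5.w"]] <- initConvW(1L, 4L * w, no); p[["h5.b"]] <- numeric(no)
  p
}

# ---- forward pass --------------------------------------------------------

# `ctx` carries the normalization mode: list(train = TRUE, stats = <env>,
# momentum = 0.1) during training (running stats recorded), or
# list(train = FALSE, stats = <list>) at inference (frozen stats applied).
fwdCBL <- function(tape, pid, name, x, k, s = 1L, ctx = NULL) {
  y <- tConv(tape, x, pid[[paste0(name, ".w")]], pid[[paste0(name, ".b")]],
             k, s)
  g <- pid[[paste0(name, ".g")]]
  be <- pid[[paste0(name, ".be")]]
  if (is.null(ctx) || isTRUE(ctx$train)) {
    rec <- if (!is.null(ctx))
      function(mu, va) updateStats(ctx$stats, name, mu, va, ctx$momentum)
    y <- tNorm(tape, y, g, be, record = rec)
  } else {
    st <- ctx$stats[[name]]
    y <- if (is.null(st)) tNorm(tape, y, g, be) else
      tNorm(tape, y, g, be, stats = st)
  }
  tLeaky(tape, y)
}

fwdCSP <- function(tape, pid, name, x, ctx = NULL) {
  a <- fwdCBL(tape, pid, paste0(name, ".ca"), x, 1L, ctx = ctx)
  r <- fwdCBL(tape, pid, paste0(name, ".r1"), a, 1L, ctx = ctx)
  r <- fwdCBL(tape, pid, paste0(name, ".r2"), r, 3L, ctx = ctx)
  a <- tAdd(tape, a, r)                       # residual unit
  b <- fwdCBL(tape, pid, paste0(name, ".cb"), x, 1L, ctx = ctx)
  fwdCBL(tape, pid, paste0(name, ".out"), tConcat(tape, list(a, b)), 1L,
         ctx = ctx)
}

fwdSPP <- function(tape, pid, x, ctx = NULL) {
  a <- fwdCBL(tape, pid, "spp.a", x, 1L, ctx = ctx)
  p1 <- tMaxPool(tape, a, 3L, 1L, 1L)
  p2 <- tMaxPool(tape, a, 5L, 1L, 2L)
  fwdCBL(tape, pid, "spp.b", tConcat(tape, list(a, p1, p2)), 1L, ctx = ctx)
}

# Returns head output node ids, named by stride.
detectorForward <- function(tape, pid, x, config, ctx = NULL) {
  f <- tFocus(tape, x)
  c1 <- fwdCBL(tape, pid, "stem", f, 3L, ctx = ctx)
  c2 <- fwdCSP(tape, pid, "c2",
               fwdCBL(tape, pid, "d2", c1, 3L, 2L, ctx = ctx), ctx = ctx)
  c3 <- fwdCSP(tape, pid, "c3",
               fwdCBL(tape, pid, "d3", c2, 3L, 2L, ctx = ctx), ctx = ctx)
  c4 <- fwdCSP(tape, pid, "c4",
               fwdCBL(tape, pid, "d4", c3, 3L, 2L, ctx = ctx), ctx = ctx)
  c5 <- fwdCSP(tape, pid, "c5",
               fwdSPP(tape, pid,
                      fwdCBL(tape, pid, "d5", c4, 3L, 2L, ctx = ctx),
                      ctx = ctx), ctx = ctx)
  p5 <- fwdCBL(tape, pid, "p5", c5, 1L, ctx = ctx)
  t4 <- tConcat(tape, list(tUpsample2(tape, p5), c4))
  n4 <- fwdCBL(tape, pid, "n4b",
               fwdCBL(tape, pid, "n4a", t4, 1L, ctx = ctx), 3L, ctx = ctx)
  p4 <- fwdCBL(tape, pid, "p4", n4, 1L, ctx = ctx)
  t3 <- tConcat(tape, list(tUpsample2(tape, p4), c3))
  n3 <- fwdCBL(tape, pid, "n3b",
               fwdCBL(tape, pid, "n3a", t3, 1L, ctx = ctx), 3L, ctx = ctx)
  heads <- list()
  if (config$improved) {
    p3 <- fwdCBL(tape, pid, "p3", n3, 1L, ctx = ctx)
    t2 <- tConcat(tape, list(tUpsample2(tape, p3), c2))
    n2 <- fwdCBL(tape, pid, "n2b",
                 fwdCBL(tape, pid, "n2a", t2, 1L, ctx = ctx), 3L, ctx = ctx)
    heads[["4"]] <- tConv(tape, n2, pid[["h2.w"]], pid[["h2.b"]], 1L, 1L)
    d3 <- fwdCBL(tape, pid, "u3", n2, 3L, 2L, ctx = ctx)
    m3 <- fwdCBL(tape, pid, "m3b",
                 fwdCBL(tape, pid, "m3a", tConcat(tape, list(d3, n3)), 1L,
                        ctx = ctx), 3L, ctx = ctx)
  } else {
    m3 <- n3
  }
  heads[["8"]] <- tConv(tape, m3, pid[["h3.w"]], pid[["h3.b"]], 1L, 1L)
  d4 <- fwdCBL(tape, pid, "u4", m3, 3L, 2L, ctx = ctx)
  m4 <- fwdCBL(tape, pid, "m4b",
               fwdCBL(tape, pid, "m4a", tConcat(tape, list(d4, n4)), 1L,
                      ctx = ctx), 3L, ctx = ctx)
  heads[["16"]] <- tConv(tape, m4, pid[["h4.w"]], pid[["h4.b"]], 1L, 1L)
  d5 <- fwdCBL(tape, pid, "u5", m4, 3L, 2L, ctx = ctx)
  m5 <- fwdCBL(tape, pid, "m5b",
               fwdCBL(tape, pid, "m5a", tConcat(tape, list(d5, p5)), 1L,
                      ctx = ctx), 3L, ctx = ctx)
  heads[["32"]] <- tConv(tape, m5, pid[["h5.w"]], pid[["h5.b"]], 1L, 1L)
  heads
}

# ---- anchors -------------------------------------------------------------

# Shape IoU of two centred (w, h) sizes.
shapeIoU <- function(w1, h1, w2, h2) {
  inter <- pmin(w1, w2) * pmin(h1, h2)
  inter / (w1 * h1 + w2 * h2 - inter)
}

# Fit per-level anchors to label sizes (adaptive anchors): k-means on (w, h)
# over all labels, clusters sorted by area and dealt to levels smallest
# stride first. With no labels, defaults scale with the stride.
fitAnchors <- function(config, labels = NULL) {
  ns <- length(config$strides)
  na <- config$n_anchors
  if (is.null(labels) || nrow(labels) < ns * na) {
    return(lapply(config$strides, function(s)
      cbind(w = s * c(1, 1.8)[seq_len(na)], h = s * c(1, 1.8)[seq_len(na)])))
  }
  wh <- cbind(labels$x1 - labels$x0, labels$y1 - labels$y0)
  wh <- wh + matrix(runif(length(wh), -1e-3, 1e-3), nrow(wh))  # break ties
  km <- suppressWarnings(kmeans(wh, centers = ns * na, nstart = 3,
                                iter.max = 50))
  cent <- km$centers[order(km$centers[, 1] * km$centers[, 2]), , drop = FALSE]
  # anchors never drop below their level's stride, so an object is matched
  # at the level whose receptive scale fits it (the assignment would be
  # degenerate when every training object has the same size)
  lapply(seq_len(ns), function(l) {
    s <- config$strides[l]
    cbind(w = pmax(cent[((l - 1) * na + 1):(l * na), 1], s, 1),
          h = pmax(cent[((l - 1) * na + 1):(l * na), 2], s, 1))
  })
}

#' Build an (untrained) ear detector
#'
#' Instantiates the parameter set for the configured topology. When labels
#' are supplied, anchors are k-means-fit to the label sizes (the adaptive-
#' anchor idea); otherwise stride-proportional defaults are used.
#'
#' @param config from \code{\link{detectorConfig}}.
#' @param labels optional label data.frame (pixel boxes) for anchor fitting.
#' @return An \linkS4class{EarDetector}.
#' @export
buildDetector <- function(config = detectorConfig(), labels = NULL) {
  set.seed(config$seed)
  params <- buildDetectorParams(config)
  anchors <- fitAnchors(config, labels)
  names(anchors) <- as.character(config$strides)
  new("EarDetector", params = params, config = config, anchors = anchors,
      stats = list(), trained = FALSE, version = "mrtrack-detector-1")
}

# Assign labels of one image to (level, cell, anchor) positives.
# Returns data.frame: stride, gy, gx (0-based cell), anchor, and the target
# box (cx, cy, w, h) in pixels.
assignAnchors <- function(labels, detector) {
  config <- detector@config
  if (nrow(labels) == 0)
    return(data.frame(stride = integer(), gy = integer(), gx = integer(),
                      anchor = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric()))
  out <- list()
  for (i in seq_len(nrow(labels))) {
    cx <- (labels$x0[i] + labels$x1[i]) / 2
    cy <- (labels$y0[i] + labels$y1[i]) / 2
    w <- labels$x1[i] - labels$x0[i]
    h <- labels$y1[i] - labels$y0[i]
    best <- lapply(seq_along(config$strides), function(l) {
      iou <- shapeIoU(w, h, detector@anchors[[l]][, "w"],
                      detector@anchors[[l]][, "h"])
      list(level = l, iou = iou)
    })
    lvl <- which.max(vapply(best, function(b) max(b$iou), 1.0))
    ok <- which(best[[lvl]]$iou >= 0.3)
    if (length(ok) == 0) next
    s <- config$strides[lvl]
    g <- config$img_size %/% s
    out[[length(out) + 1]] <- data.frame(
      stride = s,
      gy = min(max(floor(cy / s), 0), g - 1),
      gx = min(max(floor(cx / s), 0), g - 1),
      anchor = ok, cx = cx, cy = cy, w = w, h = h)
  }
  if (length(out) == 0)
    return(data.frame(stride = integer(), gy = integer(), gx = integer(),
                      anchor = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric()))
  unique(do.call(rbind, out))
}

# Flat (H,W,C)-layout index of (gy, gx, channel) in a g x g x C tensor.
gridIndex <- function(gy, gx, ch, g) gy + g * gx + g * g * ch + 1L

# IoU of two centre-format boxes.
iouCXY <- function(a, b) {
  ax0 <- a[1] - a[3] / 2; ax1 <- a[1] + a[3] / 2
  ay0 <- a[2] - a[4] / 2; ay1 <- a[2] + a[4] / 2
  bx0 <- b[1] - b[3] / 2; bx1 <- b[1] + b[3] / 2
  by0 <- b[2] - b[4] / 2; by1 <- b[2] + b[4] / 2
  iw <- max(0, min(ax1, bx1) - max(ax0, bx0))
  ih <- max(0, min(ay1, by1) - max(ay0, by0))
  inter <- iw * ih
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# Decode raw (tx, ty, tw, th) at cell (gy, gx) with a given anchor.
decodeBox <- function(t, gx, gy, s, aw, ah) {
  sg <- 1 / (1 + exp(-t))
  c(cx = (2 * sg[1] - 0.5 + gx) * s,
    cy = (2 * sg[2] - 0.5 + gy) * s,
    w = (2 * sg[3])^2 * aw,
    h = (2 * sg[4])^2 * ah)
}

# Box-regression loss node over the gathered raw coords of the positives:
# mean of (1 - IoU(decoded, target)); gradient by central differences (the
# positive set is tiny).
tBoxLoss <- function(tape, gathered, meta) {
  npos <- nrow(meta)
  tv <- nodeValue(tape, gathered)
  lossOf <- function(v) {
    tot <- 0
    for (r in seq_len(npos)) {
      t4 <- v[(4 * r - 3):(4 * r)]
      dec <- decodeBox(t4, meta$gx[r], meta$gy[r], meta$stride[r],
                       meta$aw[r], meta$ah[r])
      tot <- tot + (1 - iouCXY(dec, c(meta$cx[r], meta$cy[r],
                                      meta$w[r], meta$h[r])))
    }
    tot / npos
  }
  val <- lossOf(tv)
  addNode(tape, val, 1L, gathered,
          bw = function(g) {
            eps <- 1e-4
            gr <- numeric(length(tv))
            for (k in seq_along(tv)) {
              vp <- tv; vp[k] <- vp[k] + eps
              vm <- tv; vm[k] <- vm[k] - eps
              gr[k] <- (lossOf(vp) - lossOf(vm)) / (2 * eps)
            }
            list(g * gr)
          })
}

# Per-image detection loss on a tape; returns scalar node.
detectionLossNode <- function(tape, pid, img, labels, detector, ctx = NULL) {
  config <- detector@config
  x <- tLeaf(tape, img / 255 - 0.5, c(dim(img), 1L))
  heads <- detectorForward(tape, pid, x, config, ctx = ctx)
  pos <- assignAnchors(labels, detector)
  terms <- list(); ws <- numeric()
  for (li in seq_along(config$strides)) {
    s <- config$strides[li]
    g <- config$img_size %/% s
    head <- heads[[as.character(s)]]
    na <- config$n_anchors
    # objectness channels: 5a + 4 for anchor a
    obj_idx <- unlist(lapply(0:(na - 1), function(a)
      gridIndex(rep(0:(g - 1), g), rep(0:(g - 1), each = g), 5 * a + 4, g)))
    target <- numeric(length(obj_idx))
    weight <- rep(1, length(obj_idx))
    psub <- pos[pos$stride == s, , drop = FALSE]
    if (nrow(psub) > 0) {
      flat <- (psub$anchor - 1) * g * g + psub$gx * g + psub$gy + 1
      target[flat] <- 1
      weight[flat] <- config$pos_weight
    }
    obj_node <- tGather(tape, head, obj_idx)
    terms[[length(terms) + 1]] <- tBCE(tape, obj_node, target, weight)
    ws <- c(ws, config$obj_weight)
    if (nrow(psub) > 0) {
      box_idx <- unlist(lapply(seq_len(nrow(psub)), function(r)
        gridIndex(psub$gy[r], psub$gx[r],
                  5 * (psub$anchor[r] - 1) + 0:3, g)))
      meta <- data.frame(gx = psub$gx, gy = psub$gy, stride = s,
                         aw = detector@anchors[[li]][psub$anchor, "w"],
                         ah = detector@anchors[[li]][psub$anchor, "h"],
                         cx = psub$cx, cy = psub$cy, w = psub$w, h = psub$h)
      box_node <- tGather(tape, head, box_idx)
      terms[[length(terms) + 1]] <- tBoxLoss(tape, box_node, meta)
      ws <- c(ws, config$box_weight)
    }
  }
  tWeightedSum(tape, terms, ws)
}

#' Train the ear detector
#'
#' SGD with momentum under a one-cycle learning-rate schedule; the loss is
#' IoU-based box regression on matched anchors plus binary objectness over
#' every grid cell. Deterministic for a fixed seed and thread count.
#'
#' @param detector an \linkS4class{EarDetector}.
#' @param seq training \linkS4class{FrameSequence} (frames sized
#'   \code{config$img_size}).
#' @param labels label data.frame (pixel boxes with a \code{frame} column
#'   matching 0-based frame indices of \code{seq}).
#' @return the trained detector, with the per-epoch mean loss in
#'   \code{@config$loss_log}.
#' @export
trainDetector <- function(detector, seq, labels) {
  config <- detector@config
  d <- frameDim(seq)
  if (d[1] != config$img_size || d[2] != config$img_size)
    stop("frames must be img_size x img_size (",
         config$img_size, "); got ", d[1], "x", d[2])
  frames_with <- sort(unique(labels$frame))
  if (nFrames(seq) < 1) stop("need at least one labelled frame")
  if (nrow(assignAnchors(labels, detector)) == 0)
    stop("no positive anchors matchable to any label")
  set.seed(config$seed + 1L)
  params <- detector@params
  state <- lapply(params, function(p) array(0, dim(as.array(p))))
  stats <- newStatsStore()
  ctx <- list(train = TRUE, stats = stats, momentum = 0.1)
  n <- nFrames(seq)
  steps_per_epoch <- ceiling(n / config$batch_size)
  total_steps <- config$epochs * steps_per_epoch
  step <- 0
  loss_log <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (bi in seq_len(steps_per_epoch)) {
      idx <- ord[((bi - 1) * config$batch_size + 1):min(bi * config$batch_size, n)]
      step <- step + 1
      lr <- oneCycleLR(step, total_steps, config$learning_rate,
                       config$final_lr_factor)
      tape <- newTape()
      pid <- paramNodes(tape, params)
      per_img <- integer(length(idx))
      for (k in seq_along(idx)) {
        fr <- idx[k] - 1L
        lab <- labels[labels$frame == fr, , drop = FALSE]
        per_img[k] <- detectionLossNode(tape, pid, getFrame(seq, idx[k]),
                                        lab, detector, ctx = ctx)
      }
      loss <- tWeightedSum(tape, as.list(per_img),
                           rep(1 / length(idx), length(idx)))
      grads <- tBackward(tape, loss)
      pg <- paramGrads(grads, pid, params)
      upd <- sgdStep(params, pg, state, lr, config$momentum)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + nodeValue(tape, loss)
    }
    loss_log[ep] <- ep_loss / steps_per_epoch
    logMsg("debug", "detector epoch %d/%d loss %.4f", ep, config$epochs,
           loss_log[ep])
  }
  detector@params <- params
  detector@config$loss_log <- loss_log
  detector@stats <- as.list(stats)
  detector@trained <- TRUE
  detector
}

#' Non-maximum suppression
#'
#' Greedy suppression by descending confidence: a detection is kept unless
#' it overlaps an already-kept detection with IoU >= \code{iouThreshold}.
#'
#' @param detections data.frame with x0, y0, x1, y1, conf.
#' @param iouThreshold suppression threshold in (0, 1].
#' @return the surviving detections, sorted by descending confidence.
#' @export
nms <- function(detections, iouThreshold = 0.45) {
  if (iouThreshold <= 0 || iouThreshold > 1)
    stop("iouThreshold must be in (0, 1]")
  if (nrow(detections) == 0) return(detections)
  det <- detections[order(-detections$conf), , drop = FALSE]
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (iou(as.numeric(det[i, c("x0", "y0", "x1", "y1")]),
              as.numeric(det[j, c("x0", "y0", "x1", "y1")])) >= iouThreshold) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  out <- det[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect ears in a frame
#'
#' Runs the network, decodes every anchor at every level, keeps boxes whose
#' objectness score clears the confidence threshold, clips them to the frame
#' and applies NMS.
#'
#' @param detector a trained \linkS4class{EarDetector}.
#' @param frame numeric matrix sized img_size x img_size.
#' @param confidenceThreshold score cutoff (default from config).
#' @param nmsIoU NMS threshold (default from config).
#' @return data.frame x0, y0, x1, y1, conf (full-frame pixel coordinates).
#' @export
detectEars <- function(detector, frame,
                       confidenceThreshold = detector@config$confidence_threshold,
                       nmsIoU = detector@config$nms_iou) {
  config <- detector@config
  if (nrow(frame) != config$img_size || ncol(frame) != config$img_size)
    stop("frame size incompatible with the configured strides")
  tape <- newTape()
  pid <- paramNodes(tape, detector@params)
  x <- tLeaf(tape, frame / 255 - 0.5, c(dim(frame), 1L))
  heads <- detectorForward(tape, pid, x, config,
                           ctx = list(train = FALSE, stats = detector@stats))
  out <- list()
  for (li in seq_along(config$strides)) {
    s <- config$strides[li]
    g <- config$img_size %/% s
    hv <- array(nodeValue(tape, heads[[as.character(s)]]),
                c(g, g, 5 * config$n_anchors))
    for (a in seq_len(config$n_anchors)) {
      obj <- 1 / (1 + exp(-hv[, , 5 * a]))
      hits <- which(obj >= confidenceThreshold, arr.ind = TRUE)
      if (nrow(hits) == 0) next
      for (r in seq_len(nrow(hits))) {
        gy <- hits[r, 1] - 1; gx <- hits[r, 2] - 1
        t4 <- hv[hits[r, 1], hits[r, 2], (5 * a - 4):(5 * a - 1)]
        dec <- decodeBox(t4, gx, gy, s, detector@anchors[[li]][a, "w"],
                         detector@anchors[[li]][a, "h"])
        out[[length(out) + 1]] <- data.frame(
          x0 = dec[1] - dec[3] / 2, y0 = dec[2] - dec[4] / 2,
          x1 = dec[1] + dec[3] / 2, y1 = dec[2] + dec[4] / 2,
          conf = obj[hits[r, 1], hits[r, 2]])
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                      y1 = numeric(), conf = numeric()))
  det <- do.call(rbind, out)
  det$x0 <- pmax(det$x0, 0); det$y0 <- pmax(det$y0, 0)
  det$x1 <- pmin(det$x1, config$img_size)
  det$y1 <- pmin(det$y1, config$img_size)
  det <- det[det$x1 > det$x0 & det$y1 > det$y0, , drop = FALSE]
  rownames(det) <- NULL
  nms(det, nmsIoU)
}

#' Save or load a detector or similarity model
#'
#' Models are serialized with their configuration, weights and a format
#' version tag.
#'
#' @param model an \linkS4class{EarDetector} or \linkS4class{SiameseModel}.
#' @param path file path.
#' @return \code{loadModel} returns the model object.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(version = model@version, class = class(model),
               params = model@params, config = model@config,
               anchors = if (is(model, "EarDetector")) model@anchors,
               stats = model@stats, trained = model@trained),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$version) || !startsWith(obj$version, "mrtrack-"))
    stop("unrecognized model file format")
  st <- if (is.null(obj$stats)) list() else obj$stats
  if (obj$class == "EarDetector")
    new("EarDetector", params = obj$params, config = obj$config,
        anchors = obj$anchors, stats = st, trained = obj$trained,
        version = obj$version)
  else
    new("SiameseModel", params = obj$params, config = obj$config,
        stats = st, trained = obj$trained, version = obj$version)
}
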