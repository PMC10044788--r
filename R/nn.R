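# A compact reverse-mode automatic-differentiation engine for the package's
# two small networks (the ear detector and the dual-Siamese similarity
# model). Tensors are numeric vectors in (H, W, C) column-major layout with a
# `dims` attribute; convolution/pooling/upsampling forward and adjoint
# passes run in C++ (src/kernels.cpp). Nodes are created in topological
# order, so a single reverse sweep computes all gradients.

newTape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- list()
  tape$n <- 0L
  tape
}

addNode <- function(tape, value, dims, parents = integer(), bw = NULL) {
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- list(value = value, dims = dims,
                               parents = parents, bw = bw)
  tape$n
}

# NOTE: `id` must be forced before tape$nodes is read -- evaluating a nested
# op expression appends nodes to the tape, and reading the list first would
# index a stale copy.
nodeValue <- function(tape, id) {
  force(id)
  tape$nodes[[id]]$value
}
nodeDims <- function(tape, id) {
  force(id)
  tape$nodes[[id]]$dims
}

# Leaf node (input or parameter).
tLeaf <- function(tape, value, dims = NULL) {
  if (is.null(dims))
    dims <- if (!is.null(dim(value))) dim(value) else length(value)
  addNode(tape, as.numeric(value), dims)
}

# Reverse sweep from scalar node `loss`; returns list of gradients indexed by
# node id (NULL where unreached).
tBackward <- function(tape, loss) {
  grads <- vector("list", tape$n)
  grads[[loss]] <- 1
  for (id in rev(seq_len(tape$n))) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tape$nodes[[id]]
    if (is.null(node$bw)) next
    pg <- node$bw(g)
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      if (is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

# ---- tensor ops ----------------------------------------------------------

# 2D convolution: x (H,W,C); w matrix (k*k*C) x Cout; b length Cout.
tConv <- function(tape, x, w, b, k, s = 1L, p = (k - 1L) %/% 2L) {
  xd <- nodeDims(tape, x)
  H <- xd[1]; W <- xd[2]; C <- if (length(xd) > 2) xd[3] else 1L
  wv <- matrix(nodeValue(tape, w), ncol = length(nodeValue(tape, b)))
  bv <- nodeValue(tape, b)
  cols <- cpp_im2col(nodeValue(tape, x), H, W, C, k, s, p)
  out <- crossprod(wv, cols) + bv              # Cout x P
  Ho <- (H + 2 * p - k) %/% s + 1L
  Wo <- (W + 2 * p - k) %/% s + 1L
  Cout <- length(bv)
  addNode(tape, as.numeric(t(out)), c(Ho, Wo, Cout), c(x, w, b),
          bw = function(g) {
            G <- t(matrix(g, Ho * Wo, Cout))   # Cout x P
            dW <- cols %*% t(G)
            db <- rowSums(G)
            dx <- cpp_col2im(wv %*% G, H, W, C, k, s, p)
            list(dx, as.numeric(dW), db)
          })
}

# Per-channel batch normalization over the spatial plane. During training
# the current activation statistics are used (and optionally recorded into
# running averages via `record`); at inference, frozen running statistics
# are supplied via `stats`, so the features do not depend on the global
# content of the test image (a detector trained on single-subject clips
# must transfer to multi-subject frames).
tNorm <- function(tape, x, gamma, beta, eps = 1e-5, stats = NULL,
                  record = NULL) {
  xd <- nodeDims(tape, x)
  H <- xd[1]; W <- xd[2]; C <- xd[3]
  n <- H * W
  xv <- matrix(nodeValue(tape, x), n, C)
  gv <- nodeValue(tape, gamma); bv <- nodeValue(tape, beta)
  if (!is.null(stats)) {
    sdv <- sqrt(stats$var + eps)
    xhat <- sweep(sweep(xv, 2, stats$mean), 2, sdv, "/")
    y <- sweep(sweep(xhat, 2, gv, "*"), 2, bv, "+")
    return(addNode(tape, as.numeric(y), xd, c(x, gamma, beta),
                   bw = function(g) {
                     G <- matrix(g, n, C)
                     list(as.numeric(sweep(G, 2, gv / sdv, "*")),
                          colSums(G * xhat), colSums(G))
                   }))
  }
  mu <- colMeans(xv)
  va <- colMeans(xv^2) - mu^2
  if (!is.null(record)) record(mu, va)
  sdv <- sqrt(va + eps)
  xhat <- sweep(sweep(xv, 2, mu), 2, sdv, "/")
  y <- sweep(sweep(xhat, 2, gv, "*"), 2, bv, "+")
  addNode(tape, as.numeric(y), xd, c(x, gamma, beta),
          bw = function(g) {
            G <- matrix(g, n, C)
            dgamma <- colSums(G * xhat)
            dbeta <- colSums(G)
            dxhat <- sweep(G, 2, gv, "*")
            # dx = (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) / sd
            m1 <- colMeans(dxhat)
            m2 <- colMeans(dxhat * xhat)
            dx <- sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, "*")
            dx <- sweep(dx, 2, sdv, "/")
            list(as.numeric(dx), dgamma, dbeta)
          })
}

tLeaky <- function(tape, x, alpha = 0.1) {
  xv <- nodeValue(tape, x)
  mask <- xv > 0
  addNode(tape, ifelse(mask, xv, alpha * xv), nodeDims(tape, x), x,
          bw = function(g) list(ifelse(mask, g, alpha * g)))
}

tRelu <- function(tape, x) tLeaky(tape, x, alpha = 0)

tAdd <- function(tape, a, b) {
  addNode(tape, nodeValue(tape, a) + nodeValue(tape, b), nodeDims(tape, a),
          c(a, b), bw = function(g) list(g, g))
}

# Channel concatenation of (H,W,C_i) tensors.
tConcat <- function(tape, xs) {
  ds <- lapply(xs, function(x) nodeDims(tape, x))
  H <- ds[[1]][1]; W <- ds[[1]][2]
  Cs <- vapply(ds, function(d) if (length(d) > 2) as.integer(d[3]) else 1L, 1L)
  vals <- unlist(lapply(xs, function(x) nodeValue(tape, x)))
  splits <- c(0, cumsum(H * W * Cs))
  addNode(tape, vals, c(H, W, sum(Cs)), as.integer(xs),
          bw = function(g) {
            lapply(seq_along(xs), function(i)
              g[(splits[i] + 1):splits[i + 1]])
          })
}

tMaxPool <- function(tape, x, k, s = k, p = 0L) {
  xd <- nodeDims(tape, x)
  H <- xd[1]; W <- xd[2]; C <- if (length(xd) > 2) xd[3] else 1L
  res <- cpp_maxpool(nodeValue(tape, x), H, W, C, k, s, p)
  len <- H * W * C
  addNode(tape, res$value, c(res$Ho, res$Wo, C), x,
          bw = function(g) list(cpp_maxpool_backward(g, res$argmax, len)))
}

tUpsample2 <- function(tape, x) {
  xd <- nodeDims(tape, x)
  addNode(tape, cpp_upsample2(nodeValue(tape, x), xd[1], xd[2], xd[3]),
          c(2L * xd[1], 2L * xd[2], xd[3]), x,
          bw = function(g) list(cpp_upsample2_backward(g, xd[1], xd[2], xd[3])))
}

# Focus / space-to-depth: the four 2x2 phase slices concatenated along
# channels; lossless (H,W,C) -> (H/2,W/2,4C).
tFocus <- function(tape, x) {
  xd <- nodeDims(tape, x)
  H <- xd[1]; W <- xd[2]; C <- if (length(xd) > 2) xd[3] else 1L
  if (H %% 2 != 0 || W %% 2 != 0) stop("Focus requires even spatial dims")
  arr <- array(nodeValue(tape, x), c(H, W, C))
  phases <- list(arr[seq(1, H, 2), seq(1, W, 2), , drop = FALSE],
                 arr[seq(2, H, 2), seq(1, W, 2), , drop = FALSE],
                 arr[seq(1, H, 2), seq(2, W, 2), , drop = FALSE],
                 arr[seq(2, H, 2), seq(2, W, 2), , drop = FALSE])
  addNode(tape, as.numeric(do.call(c, phases)), c(H %/% 2L, W %/% 2L, 4L * C),
          x, bw = function(g) {
            ga <- array(g, c(H %/% 2, W %/% 2, 4 * C))
            out <- array(0, c(H, W, C))
            cs <- function(i) ((i - 1) * C + 1):(i * C)
            out[seq(1, H, 2), seq(1, W, 2), ] <- ga[, , cs(1)]
            out[seq(2, H, 2), seq(1, W, 2), ] <- ga[, , cs(2)]
            out[seq(1, H, 2), seq(2, W, 2), ] <- ga[, , cs(3)]
            out[seq(2, H, 2), seq(2, W, 2), ] <- ga[, , cs(4)]
            list(as.numeric(out))
          })
}

# Gather elements at (unique) 1-based indices of the parent's value vector.
tGather <- function(tape, x, idx) {
  len <- length(nodeValue(tape, x))
  addNode(tape, nodeValue(tape, x)[idx], length(idx), x,
          bw = function(g) {
            gp <- numeric(len)
            gp[idx] <- g               # indices are unique by construction
            list(gp)
          })
}

# Fully connected layer on a flat vector: w matrix (in x out), b length out.
tFC <- function(tape, x, w, b) {
  xv <- nodeValue(tape, x)
  wv <- matrix(nodeValue(tape, w), nrow = length(xv))
  bv <- nodeValue(tape, b)
  addNode(tape, as.numeric(crossprod(wv, xv)) + bv, length(bv), c(x, w, b),
          bw = function(g) list(as.numeric(wv %*% g),
                                as.numeric(outer(xv, g)), g))
}

# Global average pooling (H,W,C) -> C-vector.
tGlobalMean <- function(tape, x) {
  xd <- nodeDims(tape, x)
  n <- xd[1] * xd[2]
  xv <- matrix(nodeValue(tape, x), n, xd[3])
  addNode(tape, colMeans(xv), xd[3], x,
          bw = function(g) list(as.numeric(matrix(g / n, n, xd[3], byrow = TRUE))))
}

tConcatVec <- function(tape, xs) {
  lens <- vapply(xs, function(x) length(nodeValue(tape, x)), 1L)
  splits <- c(0, cumsum(lens))
  addNode(tape, unlist(lapply(xs, function(x) nodeValue(tape, x))),
          sum(lens), as.integer(xs),
          bw = function(g) lapply(seq_along(xs), function(i)
            g[(splits[i] + 1):splits[i + 1]]))
}

# Euclidean distance between two equal-length vectors (scalar node).
tL2Dist <- function(tape, a, b, eps = 1e-8) {
  av <- nodeValue(tape, a); bv <- nodeValue(tape, b)
  d <- sqrt(sum((av - bv)^2) + eps)
  addNode(tape, d, 1L, c(a, b),
          bw = function(g) list(g * (av - bv) / d, -g * (av - bv) / d))
}

# Contrastive loss on a scalar distance node: label 1 -> d^2,
# label 0 -> max(0, margin - d)^2.
tContrastive <- function(tape, d, label, margin) {
  dv <- nodeValue(tape, d)
  if (dv < 0) stop("distance must be nonnegative")
  val <- if (label == 1) dv^2 else max(0, margin - dv)^2
  addNode(tape, val, 1L, d,
          bw = function(g) {
            dd <- if (label == 1) 2 * dv else -2 * max(0, margin - dv)
            list(g * dd)
          })
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Weighted binary cross-entropy with logits; mean over weighted elements.
tBCE <- function(tape, x, target, weight = NULL) {
  xv <- nodeValue(tape, x)
  if (is.null(weight)) weight <- rep(1, length(xv))
  norm <- max(sum(weight), 1e-12)
  val <- sum(weight * (softplus(xv) - target * xv)) / norm
  addNode(tape, val, 1L, x,
          bw = function(g) list(g * weight * (1 / (1 + exp(-xv)) - target) / norm))
}

# Sigmoid on a vector node.
tSigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-nodeValue(tape, x)))
  addNode(tape, s, nodeDims(tape, x), x, bw = function(g) list(g * s * (1 - s)))
}

# Weighted sum of scalar nodes.
tWeightedSum <- function(tape, xs, ws) {
  vals <- vapply(xs, function(x) nodeValue(tape, x), 1.0)
  addNode(tape, sum(vals * ws), 1L, as.integer(xs),
          bw = function(g) as.list(g * ws))
}

# ---- parameters and optimizer -------------------------------------------

# He-style initializer for a conv (k*k*Cin x Cout) weight matrix.
initConvW <- function(k, cin, cout) {
  matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
         k * k * cin, cout)
}

initFCW <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

# SGD with momentum; lr handled by the caller per step.
sgdStep <- function(params, grads, state, lr, momentum) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    v <- momentum * state[[nm]] + g
    state[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * v
  }
  list(params = params, state = state)
}

# One-cycle learning-rate schedule: brief linear warmup, then cosine decay
# from the initial rate to initial * final_factor.
oneCycleLR <- function(step, total, lr0, final_factor = 0.2) {
  warm <- max(1, round(0.1 * total))
  if (step <= warm) return(lr0 * step / warm)
  frac <- (step - warm) / max(1, total - warm)
  lr_min <- lr0 * final_factor
  lr_min + (lr0 - lr_min) * (1 + cos(pi * frac)) / 2
}

# Running-statistics store for normalization layers: an environment mapping
# layer name -> list(mean, var), updated by exponential moving average.
newStatsStore <- function() new.env(parent = emptyenv())

updateStats <- function(store, name, mu, va, momentum = 0.1) {
  old <- store[[name]]
  if (is.null(old)) {
    store[[name]] <- list(mean = mu, var = va)
  } else {
    store[[name]] <- list(mean = (1 - momentum) * old$mean + momentum * mu,
                          var = (1 - momentum) * old$var + momentum * va)
  }
}

# Register a named parameter set on a tape; returns node-id map.
paramNodes <- function(tape, params) {
  ids <- vector("list", length(params))
  names(ids) <- names(params)
  for (nm in names(params)) ids[[nm]] <- tLeaf(tape, params[[nm]])
  ids
}

# Collect parameter gradients from a backward sweep.
paramGrads <- function(grads, ids, params) {
  out <- vector("list", length(ids))
  names(out) <- names(ids)
  for (nm in names(ids)) {
    g <- grads[[ids[[nm]]]]
    if (!is.null(g)) out[[nm]] <- array(g, dim(as.array(params[[nm]])))
    if (!is.null(g) && is.matrix(params[[nm]]))
      out[[nm]] <- matrix(g, nrow(params[[nm]]), ncol(params[[nm]]))
  }
  out
}
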