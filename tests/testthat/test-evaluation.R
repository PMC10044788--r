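test_that("IoU follows half-open box arithmetic", {
  expect_equal(iou(box(0, 0, 2, 2), box(0, 0, 2, 2)), 1)
  expect_equal(iou(box(0, 0, 2, 2), box(5, 5, 7, 7)), 0)
  expect_equal(iou(box(0, 0, 2, 2), box(1, 1, 3, 3)), 1 / 7)
  expect_error(iou(box(0, 0, 0, 2), box(0, 0, 1, 1)), "degenerate")
})

test_that("average precision handles the closed-form cases", {
  truth <- data.frame(frame = 0L, x0 = 0, y0 = 0, x1 = 10, y1 = 10)
  det <- data.frame(frame = 0L, x0 = 0.5, y0 = 0.5, x1 = 10, y1 = 10,
                    conf = 0.9)
  expect_equal(averagePrecision(det, truth, 0.5), 1)
  expect_error(averagePrecision(det, truth[0, ], 0.5), "no ground truth")
})

test_that("mAP over thresholds is the mean of per-threshold AP", {
  # construct a case with AP 1 at loose thresholds and 0 at tight ones:
  # detection overlaps truth with IoU exactly 0.75
  truth <- data.frame(frame = 0L, x0 = 0, y0 = 0, x1 = 100, y1 = 10)
  det <- data.frame(frame = 0L, x0 = 25, y0 = 0, x1 = 100, y1 = 10,
                    conf = 1)
  ap <- vapply(seq(0.5, 0.9, 0.1), function(t)
    averagePrecision(det, truth, t), 1.0)
  expect_equal(ap, c(1, 1, 1, 0, 0))
  expect_equal(mapMetric(det, truth), 0.6)
})

test_that("AP equals a brute-force precision-recall oracle", {
  # oracle: walk detections in confidence order, greedily matching the
  # best-IoU unmatched truth, accumulating the PR curve point by point,
  # then integrate the precision envelope by direct summation
  oracleAP <- function(det, truth, thr) {
    det <- det[order(-det$conf), ]
    used <- rep(FALSE, nrow(truth))
    tps <- logical(nrow(det))
    for (i in seq_len(nrow(det))) {
      best <- 0; bj <- 0
      for (j in seq_len(nrow(truth))) {
        if (used[j] || truth$frame[j] != det$frame[i]) next
        v <- iou(as.numeric(det[i, c("x0", "y0", "x1", "y1")]),
                 as.numeric(truth[j, c("x0", "y0", "x1", "y1")]))
        if (v > best) { best <- v; bj <- j }
      }
      if (bj > 0 && best >= thr) { tps[i] <- TRUE; used[bj] <- TRUE }
    }
    rec <- cumsum(tps) / nrow(truth)
    pre <- cumsum(tps) / seq_along(tps)
    total <- 0
    prev_r <- 0
    for (i in seq_along(rec)) {
      p_env <- max(pre[i:length(pre)])
      total <- total + (rec[i] - prev_r) * p_env
      prev_r <- rec[i]
    }
    total
  }
  set.seed(99)
  for (case in 1:40) {
    nt <- sample(1:4, 1)
    nd <- sample(1:6, 1)
    truth <- data.frame(frame = 0L, x0 = runif(nt, 0, 40),
                        y0 = runif(nt, 0, 40))
    truth$x1 <- truth$x0 + runif(nt, 4, 14)
    truth$y1 <- truth$y0 + runif(nt, 4, 14)
    det <- truth[sample.int(nt, nd, replace = TRUE), ]
    det$x0 <- det$x0 + rnorm(nd, 0, 3); det$x1 <- det$x1 + rnorm(nd, 0, 3)
    det <- det[det$x1 > det$x0 + 1, , drop = FALSE]
    if (nrow(det) == 0) next
    det$conf <- runif(nrow(det))
    for (thr in c(0.5, 0.7, 0.9)) {
      expect_equal(averagePrecision(det, truth, thr),
                   oracleAP(det, truth, thr), tolerance = 1e-12,
                   label = paste("case", case, "thr", thr))
    }
  }
})

test_that("NMS equals the exhaustive fixed-point oracle for n <= 8", {
  # oracle: the survivor set is the unique subset where a box survives
  # exactly when no higher-confidence survivor overlaps it at or above
  # the threshold; enumerate all subsets and find that fixed point
  oracleNMS <- function(det, thr) {
    n <- nrow(det)
    det <- det[order(-det$conf), ]
    for (mask in 0:(2^n - 1)) {
      keep <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
      ok <- TRUE
      for (i in seq_len(n)) {
        suppressed <- FALSE
        for (j in seq_len(n)) {
          if (j >= i || !keep[j]) next
          if (iou(as.numeric(det[i, c("x0", "y0", "x1", "y1")]),
                  as.numeric(det[j, c("x0", "y0", "x1", "y1")])) >= thr)
            suppressed <- TRUE
        }
        if (keep[i] == suppressed) { ok <- FALSE; break }
      }
      if (ok) return(det[keep, , drop = FALSE])
    }
    stop("no fixed point")
  }
  set.seed(5)
  for (case in 1:25) {
    n <- sample(2:8, 1)
    det <- data.frame(x0 = runif(n, 0, 30), y0 = runif(n, 0, 30))
    det$x1 <- det$x0 + runif(n, 5, 15)
    det$y1 <- det$y0 + runif(n, 5, 15)
    det$conf <- round(runif(n), 3)
    got <- nms(det, 0.4)
    want <- oracleNMS(det, 0.4)
    expect_equal(got, want, ignore_attr = TRUE, label = paste("case", case))
  }
  # trivial contracts
  two <- data.frame(x0 = 0, y0 = 0, x1 = 4, y1 = 4, conf = c(0.9, 0.8))
  expect_equal(nrow(nms(two, 0.5)), 1)
  expect_equal(nms(two, 0.5)$conf, 0.9)
  far <- data.frame(x0 = c(0, 20), y0 = 0, x1 = c(4, 24), y1 = 4,
                    conf = c(0.9, 0.8))
  expect_equal(nrow(nms(far, 0.5)), 2)
  expect_error(nms(two, 0), "iouThreshold")
})

test_that("MOTA and ICR implement their defining arithmetic", {
  expect_equal(mota(errorCounts(fn = 0, fp = 0, idsw = 0, gt = 100)), 1)
  expect_equal(mota(errorCounts(fn = 10, fp = 5, idsw = 5, gt = 100)), 0.8)
  expect_equal(mota(errorCounts(fn = 60, fp = 60, idsw = 0, gt = 100)), -0.2)
  expect_equal(icr(errorCounts(gt = 50)), 1)
  expect_error(icr(errorCounts(gt = 0)), "positive")
  expect_error(errorCounts(miss = -1, gt = 10), "nonnegative")

  # strictly decreasing in each error tally
  base <- icr(errorCounts(miss = 5, switch = 5, drift = 5, gt = 1000))
  for (fld in c("miss", "switch", "drift")) {
    cnt <- errorCounts(miss = 5, switch = 5, drift = 5, gt = 1000)
    cnt[[fld]] <- cnt[[fld]] + 1
    expect_lt(icr(cnt), base)
  }
})

test_that("track scoring matches hand-enumerated toy cases", {
  frames <- 0:59
  truth <- rbind(
    data.frame(frame = frames, id = 1L, x = 10, y = 10),
    data.frame(frame = frames, id = 2L, x = 50, y = 50))
  # perfect prediction
  perfect <- truth
  cnt <- scoreTracks(perfect, truth, matchRadius = 10, driftRadius = 3,
                     window = 10)
  expect_equal(unlist(cnt[c("miss", "switch", "drift", "fn", "fp", "idsw")]),
               c(miss = 0, switch = 0, drift = 0, fn = 0, fp = 0, idsw = 0))
  expect_equal(icr(cnt), 1)

  # identities swapped from frame 30 onward: 2 switches per frame after the
  # mapping (frozen by the first 10 matched frames) disagrees
  swapped <- truth
  sel <- swapped$frame >= 30
  swapped$id[sel] <- 3L - swapped$id[sel]
  cnt2 <- scoreTracks(swapped, truth, matchRadius = 10, driftRadius = 3,
                      window = 10)
  expect_equal(cnt2$switch, 2 * 30)
  expect_equal(cnt2$miss, 0)
  expect_equal(cnt2$idsw, 2)     # CLEAR counts one change per track

  # one identity deleted for 7 frames -> 7 misses
  holes <- truth[!(truth$id == 2 & truth$frame %in% 10:16), ]
  cnt3 <- scoreTracks(holes, truth, matchRadius = 10, driftRadius = 3,
                      window = 10)
  expect_equal(cnt3$miss, 7)
  expect_equal(cnt3$fn, 7)

  # position pushed beyond the drift radius but identity consistent
  drifty <- truth
  sel <- drifty$id == 1 & drifty$frame %in% 40:44
  drifty$x[sel] <- drifty$x[sel] + 6
  cnt4 <- scoreTracks(drifty, truth, matchRadius = 10, driftRadius = 3,
                      window = 10)
  expect_equal(cnt4$drift, 5)

  # inconsistent truth identity sets are rejected
  broken <- truth[-1, ]
  expect_error(scoreTracks(perfect, broken, 10, 3), "inconsistent")
})

test_that("the N-1 chi-squared test matches its closed form", {
  same <- n1Chisq(50, 100, 50, 100)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1, tolerance = 1e-9)

  r <- n1Chisq(90, 100, 60, 100)
  # Pearson chi2 = 200*(90*40-10*60)^2/(100*100*150*50) = 24, scaled by
  # (N-1)/N = 199/200
  expect_equal(r$statistic, 24 * 199 / 200)
  expect_lt(r$p.value, 0.001)
  expect_error(n1Chisq(100, 100, 100, 100), "margin")
  expect_error(n1Chisq(5, 4, 1, 10), "exceed")
})
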