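test_that("the Focus transform is a lossless space-to-depth bijection", {
  x <- array(seq_len(4 * 4), c(4, 4, 1))
  f <- focusTransform(x)
  expect_equal(dim(f), c(2, 2, 4))
  expect_equal(focusTransform(f, inverse = TRUE), x)
  # constant image stays constant
  cv <- focusTransform(matrix(7, 6, 6))
  expect_true(all(cv == 7))
  expect_error(focusTransform(matrix(0, 5, 4)), "even")

  set.seed(1)
  r <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  expect_equal(focusTransform(focusTransform(r), inverse = TRUE), r)
})

test_that("head grids follow stride arithmetic and improved adds a level", {
  ns <- asNamespace("MRTrack")
  probe <- function(improved, size = 160L) {
    cfg <- detectorConfig(imgSize = size, improved = improved, baseWidth = 4,
                          seed = 1)
    det <- buildDetector(cfg)
    tape <- ns$newTape()
    pid <- ns$paramNodes(tape, det@params)
    x <- ns$tLeaf(tape, matrix(0, size, size), c(size, size, 1L))
    heads <- ns$detectorForward(tape, pid, x, cfg)
    vapply(heads, function(h) as.integer(ns$nodeDims(tape, h)[1]), 1L)
  }
  base <- probe(FALSE)
  expect_equal(unname(base), c(20L, 10L, 5L))
  imp <- probe(TRUE)
  expect_equal(unname(imp), c(40L, 20L, 10L, 5L))

  # the improved topology is a strict superset in parameters
  n_base <- nParameters(buildDetector(detectorConfig(improved = FALSE,
                                                     baseWidth = 4)))
  n_imp <- nParameters(buildDetector(detectorConfig(improved = TRUE,
                                                    baseWidth = 4)))
  expect_gt(n_imp, n_base)

  expect_error(detectorConfig(imgSize = 100L), "divisible")
})

test_that("anchors fit label sizes but never undercut their stride", {
  labels <- data.frame(frame = 0L, class = 0L, x0 = 0, y0 = 0,
                       x1 = rep(c(4, 5, 6), 10), y1 = rep(c(4, 5, 6), 10))
  det <- buildDetector(detectorConfig(imgSize = 64, baseWidth = 4, seed = 2),
                       labels)
  for (li in seq_along(det@config$strides)) {
    s <- det@config$strides[li]
    expect_true(all(det@anchors[[li]] >= s))
  }
  # a ~5 px label lands on the finest level at the nearest cell
  ns <- asNamespace("MRTrack")
  pos <- ns$assignAnchors(data.frame(frame = 0L, x0 = 30, y0 = 18,
                                     x1 = 35, y1 = 23), det)
  expect_true(all(pos$stride == 4))
  expect_equal(unique(pos$gx), 8)    # floor(32.5 / 4)
  expect_equal(unique(pos$gy), 5)    # floor(20.5 / 4)
})

test_that("short training reduces the loss and is seed-reproducible", {
  av <- simulateArena(ArenaSpec(width = 64, height = 64, nSubjects = 1,
                                bodyAxes = c(9, 4.5), earRadius = 2,
                                nFrames = 8, noiseSd = 2, seed = 31,
                                speedScale = 3))
  labels <- arenaLabels(av)
  cfg <- detectorConfig(imgSize = 64, improved = TRUE, baseWidth = 4,
                        nAnchors = 1L, epochs = 4, batchSize = 4,
                        learningRate = 0.02, seed = 5)
  det1 <- trainDetector(buildDetector(cfg, labels), arenaFrames(av), labels)
  expect_lt(tail(det1@config$loss_log, 1), det1@config$loss_log[1])

  det2 <- trainDetector(buildDetector(cfg, labels), arenaFrames(av), labels)
  expect_identical(det1@config$loss_log, det2@config$loss_log)

  # a threshold of 1 admits no detections; size mismatches are rejected
  expect_equal(nrow(detectEars(det1, getFrame(arenaFrames(av), 1),
                               confidenceThreshold = 1 + 1e-9)), 0)
  expect_error(detectEars(det1, matrix(0, 32, 32)), "incompatible")

  # detections, when any, are clipped to the frame
  d <- detectEars(det1, getFrame(arenaFrames(av), 1),
                  confidenceThreshold = 0.01)
  if (nrow(d) > 0) {
    expect_true(all(d$x0 >= 0 & d$y0 >= 0 & d$x1 <= 64 & d$y1 <= 64))
  }

  # labels that no anchor can match raise a data error
  tiny <- data.frame(frame = 0L, class = 0L, x0 = 0, y0 = 0, x1 = 0.5,
                     y1 = 0.5, id = 1L)
  expect_error(trainDetector(buildDetector(cfg, labels), arenaFrames(av),
                             tiny), "no positive anchors")
})

test_that("a small improved detector clears mAP@0.5 0.80 on held-out data", {
  det <- acceptanceModels()$detector
  cfg <- acceptanceConfig()
  held <- simulateArena(ArenaSpec(width = cfg$img_size, height = cfg$img_size,
                                  nSubjects = 2,
                                  bodyAxes = c(cfg$body_major,
                                               cfg$body_minor),
                                  earRadius = cfg$ear_radius, nFrames = 15,
                                  noiseSd = cfg$noise_sd, seed = 99,
                                  speedScale = cfg$speed_scale))
  truth <- arenaLabels(held)
  dets <- do.call(rbind, lapply(1:15, function(i) {
    d <- detectEars(det, getFrame(arenaFrames(held), i),
                    confidenceThreshold = 0.05)
    if (nrow(d)) cbind(frame = i - 1L, d) else NULL
  }))
  expect_gte(mapMetric(dets, truth, 0.5), 0.80)
  # an empty arena frame (background plus sensor noise, no subject)
  # yields nothing at the working threshold
  set.seed(1)
  blank <- matrix(220, cfg$img_size, cfg$img_size) +
    matrix(rnorm(cfg$img_size^2, 0, cfg$noise_sd), cfg$img_size)
  expect_equal(nrow(detectEars(det, blank, confidenceThreshold = 0.5)), 0)
})
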