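test_that("normalization fixes the mean and is scale invariant", {
  expect_equal(normalizeFrame(matrix(64, 5, 5)), matrix(128, 5, 5))
  f <- matrix(runif(64, 10, 200), 8, 8)
  expect_equal(normalizeFrame(f), normalizeFrame(2 * f))
  cb <- matrix(c(0, 200), 4, 4)
  expect_equal(mean(normalizeFrame(cb)), 128)
  expect_error(normalizeFrame(matrix(0, 3, 3)), "degenerate")
})

test_that("background model averages evenly subsampled frames", {
  const <- FrameSequence(replicate(6, matrix(77, 4, 4), simplify = FALSE), 10)
  expect_equal(buildBackground(const, 3, reference = 77), matrix(77, 4, 4))

  # with the reference at 120, frames at 100 and 140 both normalize to a
  # constant 120, and so does their mean
  two <- FrameSequence(list(matrix(100, 4, 4), matrix(140, 4, 4)), 10)
  expect_equal(buildBackground(two, 2, reference = 120), matrix(120, 4, 4))

  # nSamples == nFrames is the plain mean of all (normalized) frames
  frames <- lapply(1:4, function(i) matrix(100 + i * 5, 3, 3))
  seq4 <- FrameSequence(frames, 10)
  ref <- Reduce(`+`, lapply(frames, normalizeFrame)) / 4
  expect_equal(buildBackground(seq4, 4), ref)

  expect_error(buildBackground(const, 99), "nSamples")
  # the median variant is exact on a constant background
  expect_equal(buildBackground(two, 2, reference = 120,
                               statistic = "median"), matrix(120, 4, 4))
})

test_that("blob segmentation finds subjects and nothing else", {
  bg <- matrix(128, 32, 32)
  expect_length(segmentBlobs(bg, bg, 25, 10), 0)

  fr <- bg
  fr[10:14, 20:24] <- 20          # 25-px square at x 19..23, y 9..13
  blobs <- segmentBlobs(fr, bg, threshold = 25, minBlobArea = 10)
  expect_length(blobs, 1)
  expect_equal(blobs[[1]]$area, 25)
  expect_equal(blobs[[1]]$centroid, c(21, 11))
  expect_equal(blobs[[1]]$bbox, c(19, 9, 24, 14))
})

test_that("segmentation is translation equivariant", {
  bg <- matrix(128, 40, 40)
  fr <- bg
  fr[5:9, 6:11] <- 10
  b0 <- segmentBlobs(fr, bg, 25, 5)
  shift <- function(m, dy, dx) {
    out <- matrix(128, nrow(m), ncol(m))
    out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <-
      m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
    out
  }
  b1 <- segmentBlobs(shift(fr, 7, 3), bg, 25, 5)
  expect_equal(b1[[1]]$centroid, b0[[1]]$centroid + c(3, 7))
  expect_equal(b1[[1]]$area, b0[[1]]$area)
})

test_that("segmented blob centroids track the rendered subject", {
  av <- tinyArena(nSubjects = 1, nFrames = 60, seed = 9, noiseSd = 0,
                  speedScale = 3)
  sg <- MRTrack:::segmentSequence(arenaFrames(av))
  tr <- arenaTruth(av)
  for (i in 1:6) {
    expect_length(sg$blobs[[i]], 1)
    t1 <- tr[tr$frame == i - 1, ]
    d <- sqrt((sg$blobs[[i]][[1]]$centroid[1] - t1$x)^2 +
              (sg$blobs[[i]][[1]]$centroid[2] - t1$y)^2)
    expect_lt(d, 2)
  }
})

test_that("frame classification is the exact blob-count rule", {
  expect_equal(classifyFrames(c(2, 2, 2), 2), rep("non_occlusion", 3))
  expect_equal(classifyFrames(1, 2), "occlusion")
  expect_equal(classifyFrames(3, 2), "occlusion")
  expect_error(classifyFrames(c(1, 2), 0), "nSubjects")
})

test_that("fragment splitting partitions frames with correct flanks", {
  k <- c("non_occlusion", "non_occlusion", "occlusion", "occlusion",
         "non_occlusion")
  fr <- splitFragments(k)
  expect_equal(nrow(fr), 3)
  expect_equal(fr$start, c(0, 2, 4))
  expect_equal(fr$end, c(1, 3, 4))
  expect_equal(fr$flank_before[2], 1)
  expect_equal(fr$flank_after[2], 4)

  one <- splitFragments(rep("non_occlusion", 5))
  expect_equal(nrow(one), 1)
  expect_true(is.na(one$flank_before) && is.na(one$flank_after))

  oo <- splitFragments(c("occlusion", "occlusion"))
  expect_equal(nrow(oo), 1)
  expect_true(is.na(oo$flank_before) && is.na(oo$flank_after))

  # concatenated fragment ranges reproduce the index set exactly
  av_kinds <- sample(c("occlusion", "non_occlusion"), 40, replace = TRUE)
  fr2 <- splitFragments(av_kinds)
  covered <- unlist(mapply(seq, fr2$start, fr2$end, SIMPLIFY = FALSE))
  expect_identical(as.integer(covered), 0:39)
  expect_true(all(rle(fr2$kind)$lengths == 1))   # alternating kinds
})

test_that("double-threshold auto-labelling recovers both ear disks", {
  av <- tinyArena(nSubjects = 1, nFrames = 60, seed = 11, noiseSd = 0,
                  speedScale = 3)
  labels <- autoLabelEars(arenaFrames(av))
  kept <- setdiff(0:59, attr(labels, "skipped"))
  expect_equal(sort(unique(labels$frame)), kept)
  expect_true(all(table(labels$frame) == 2))
  ear <- av@spec@intensities[["ear"]]
  for (r in seq_len(nrow(labels))) {
    f <- getFrame(arenaFrames(av), labels$frame[r] + 1L)
    patch <- f[(labels$y0[r] + 1):labels$y1[r],
               (labels$x0[r] + 1):labels$x1[r]]
    expect_true(any(abs(patch - ear) < 1e-9))
  }

  # multi-subject input violates the single-subject precondition
  av2 <- tinyArena(nSubjects = 2, nFrames = 50, seed = 1, noiseSd = 0,
                   speedScale = 3, minSeparation = 45)
  expect_error(autoLabelEars(arenaFrames(av2)), "single-subject")
})
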