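# Linker tests drive linkFragments with synthetic blobs and controlled ear
# tracks, independent of the neural models.

test_that("a video without occlusion fragments reproduces the blob tracks", {
  av <- tinyArena(nSubjects = 2, nFrames = 50, seed = 6, noiseSd = 0,
                  speedScale = 3, minSeparation = 45)
  sg <- MRTrack:::segmentSequence(arenaFrames(av))
  kinds <- classifyFrames(vapply(sg$blobs, length, 1L), 2)
  frags <- splitFragments(kinds)
  expect_equal(nrow(frags), 1)
  linked <- linkFragments(frags, sg$blobs, vector("list", 1), 2,
                          frameDim(arenaFrames(av))[1])
  direct <- trackFragment(sg$blobs, startFrame = 0L)$tracks
  expect_equal(linked$x, direct$x)
  expect_equal(linked$id, direct$id)
  expect_true(all(linked$source == "blob"))
  expect_equal(nrow(attr(linked, "gaps")), 0)
})

test_that("perfect ear tracks bridge a crossing with full identity recovery", {
  av <- tinyArena(nSubjects = 2, nFrames = 150, seed = 2, noiseSd = 0,
                  speedScale = 3)
  truth <- arenaTruth(av)
  sg <- MRTrack:::segmentSequence(arenaFrames(av))
  kinds <- classifyFrames(vapply(sg$blobs, length, 1L), 2)
  frags <- splitFragments(kinds)
  expect_gt(sum(frags$kind == "occlusion"), 0)
  # feed ground-truth body positions as the occlusion-fragment "ear" tracks
  earTracks <- vector("list", nrow(frags))
  for (k in which(frags$kind == "occlusion")) {
    f0 <- if (!is.na(frags$flank_before[k])) frags$flank_before[k] else
      frags$start[k]
    f1 <- if (!is.na(frags$flank_after[k])) frags$flank_after[k] else
      frags$end[k]
    sub <- truth[truth$frame >= f0 & truth$frame <= f1, ]
    earTracks[[k]] <- data.frame(frame = sub$frame, ind = sub$id,
                                 x = sub$x, y = sub$y)
  }
  linked <- linkFragments(frags, sg$blobs, earTracks, 2,
                          frameDim(arenaFrames(av))[1])
  cnt <- scoreTracks(linked, arenaTracks(av), matchRadius = 20,
                     driftRadius = 8, window = 30)
  expect_equal(cnt$switch, 0)
  expect_equal(icr(cnt), 1)
})

test_that("an occlusion fragment at the start seeds from its after flank", {
  av <- tinyArena(nSubjects = 2, nFrames = 150, seed = 2, noiseSd = 0,
                  speedScale = 3)
  truth <- arenaTruth(av)
  sg <- MRTrack:::segmentSequence(arenaFrames(av))
  kinds <- classifyFrames(vapply(sg$blobs, length, 1L), 2)
  occ1 <- which(kinds == "occlusion")[1]
  # truncate the video so it OPENS mid-occlusion
  keep <- occ1:length(kinds)
  blobs <- sg$blobs[keep]
  kinds2 <- kinds[keep]
  frags <- splitFragments(kinds2)
  expect_equal(frags$kind[1], "occlusion")
  expect_true(is.na(frags$flank_before[1]))
  truth2 <- truth[truth$frame >= occ1 - 1, ]
  truth2$frame <- truth2$frame - (occ1 - 1L)
  earTracks <- vector("list", nrow(frags))
  for (k in which(frags$kind == "occlusion")) {
    f0 <- if (!is.na(frags$flank_before[k])) frags$flank_before[k] else
      frags$start[k]
    f1 <- if (!is.na(frags$flank_after[k])) frags$flank_after[k] else
      frags$end[k]
    sub <- truth2[truth2$frame >= f0 & truth2$frame <= f1, ]
    earTracks[[k]] <- data.frame(frame = sub$frame, ind = sub$id,
                                 x = sub$x, y = sub$y)
  }
  linked <- linkFragments(frags, blobs, earTracks, 2,
                          frameDim(arenaFrames(av))[1])
  tt <- data.frame(frame = truth2$frame, id = truth2$id, x = truth2$x,
                   y = truth2$y)
  cnt <- scoreTracks(linked, tt, matchRadius = 20, driftRadius = 8,
                     window = 30)
  expect_equal(cnt$switch, 0)
  # identity conservation: each identity at most once per frame
  expect_equal(anyDuplicated(linked[, c("frame", "id")]), 0)
})
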