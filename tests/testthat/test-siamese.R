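test_that("contrastive loss matches its closed form", {
  expect_equal(contrastiveLoss(0, 1), 0)
  expect_equal(contrastiveLoss(1, 0, margin = 1), 0)    # at the margin
  expect_equal(contrastiveLoss(0.5, 0, margin = 1), 0.25)
  expect_equal(contrastiveLoss(0.7, 1), 0.49)
  expect_equal(contrastiveLoss(2, 0, margin = 1), 0)    # beyond the margin
  expect_error(contrastiveLoss(-0.1, 1), "nonnegative")
  expect_error(contrastiveLoss(1, 1, margin = 0), "margin")
})

test_that("pair construction follows the adjacency and gap rules", {
  # a 5-frame track of one identity admits at most 4 positive pairs
  frame <- matrix(128, 40, 40)
  obs <- lapply(0:4, function(f)
    makeObservation(frame, f, c(10, 10, 14, 14), id = 1L, cropSize = 16))
  expect_error(makePairs(obs, 10, negGapSeconds = 0.05, nPos = 5, nNeg = 1),
               "only 4 available")

  # negatives demand a separation above negGapSeconds * frameRate frames
  obs2 <- lapply(seq(0, 2000, by = 40), function(f)
    makeObservation(frame, f, c(10, 10, 14, 14), id = 1L, cropSize = 16))
  pr <- makePairs(obs2, frameRate = 20, negGapSeconds = 60, nPos = 10,
                  nNeg = 20, seed = 4)
  frames <- vapply(obs2, function(o) o$frame, 1L)
  neg <- pr[pr$label == 0, ]
  expect_true(all(frames[neg$j] - frames[neg$i] > 1200))
  pos <- pr[pr$label == 1, ]
  kept <- sort(unique(frames))
  expect_true(all(frames[pos$j] - frames[pos$i] == 40))  # adjacent kept

  # reproducible for a fixed seed
  pr2 <- makePairs(obs2, 20, 60, 10, 20, seed = 4)
  expect_identical(pr, pr2)
})

test_that("similarity scores are bounded, symmetric and size-checked", {
  frame <- matrix(runif(64 * 64, 0, 255), 64, 64)
  model <- buildSiamese(siameseConfig(cropSize = 16, seed = 2))
  a <- makeObservation(frame, 0, c(5, 5, 9, 9), cropSize = 16)
  b <- makeObservation(frame, 1, c(30, 40, 34, 44), cropSize = 16)
  s1 <- pairSimilarity(model, a, b, c(64, 64))
  s2 <- pairSimilarity(model, b, a, c(64, 64))
  expect_true(s1 >= 0 && s1 <= 1)
  expect_lt(abs(s1 - s2), 1e-5)

  big <- makeObservation(frame, 0, c(5, 5, 9, 9), cropSize = 32)
  expect_error(pairSimilarity(model, a, big, c(64, 64)), "crop size")
})

test_that("identity assignment equals the exhaustive permutation oracle", {
  # a stub model is unnecessary: drive assignIdentities' core through
  # solveAssignment semantics on random score matrices
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(2:4, 1)
    S <- matrix(runif(n * n), n, n)
    got <- solveAssignment(1 - S)
    oracle <- bruteAssign(1 - S)
    expect_equal(sum(1 - S[cbind(seq_len(n), got)]), oracle$cost,
                 tolerance = 1e-12)
  }
})

test_that("assignment propagates, rejects low scores, handles empty input", {
  frame <- matrix(128, 64, 64)
  frame[10:14, 10:14] <- 200
  frame[40:44, 40:44] <- 200
  model <- buildSiamese(siameseConfig(cropSize = 16, seed = 3))
  mkobs <- function(f, x, y, id = NA_integer_)
    makeObservation(frame, f, c(x - 2, y - 2, x + 3, y + 3), id = id,
                    cropSize = 16)
  prev <- list(mkobs(0, 12, 12, 1L), mkobs(0, 42, 42, 2L))
  nxt <- list(mkobs(1, 43, 41), mkobs(1, 11, 13))
  # with min_score 0 the assignment is purely the best global matching
  out <- assignIdentities(model, prev, nxt, c(64, 64), minScore = 0)
  expect_setequal(vapply(out, function(o) o$id, 1L), 1:2)

  # a threshold above every score leaves all observations unassigned
  out2 <- assignIdentities(model, prev, nxt, c(64, 64), minScore = 1.1)
  expect_true(all(is.na(vapply(out2, function(o) o$id, 1L))))

  expect_identical(assignIdentities(model, prev, list(), c(64, 64)), list())
})

test_that("training separates adjacent-frame pairs from distant ones", {
  # synthetic single-subject clip; ear observations from ground truth
  av <- tinyArena(nSubjects = 1, nFrames = 120, seed = 21, noiseSd = 2,
                  speedScale = 3)
  labels <- arenaLabels(av)
  obs <- lapply(seq_len(nrow(labels)), function(r)
    makeObservation(getFrame(arenaFrames(av), labels$frame[r] + 1L),
                    labels$frame[r],
                    as.numeric(labels[r, c("x0", "y0", "x1", "y1")]),
                    id = labels$id[r], cropSize = 32))
  pairs <- makePairs(obs, frameRate = 25, negGapSeconds = 2,
                     nPos = 100, nNeg = 100, seed = 5)
  tr_idx <- sample(seq_len(nrow(pairs)))[1:150]
  model <- buildSiamese(siameseConfig(epochs = 6, seed = 6))
  model <- trainSimilarity(model, obs, pairs[tr_idx, ], c(128, 128))

  # loss decreases over training
  expect_lt(tail(model@config$loss_log, 1), model@config$loss_log[1])

  # held-out AUC of the fused score
  held <- pairs[-tr_idx, ]
  scores <- vapply(seq_len(nrow(held)), function(k)
    pairSimilarity(model, obs[[held$i[k]]], obs[[held$j[k]]], c(128, 128)),
    1.0)
  auc <- function(s, y) {
    r <- rank(s)
    (sum(r[y == 1]) - sum(y == 1) * (sum(y == 1) + 1) / 2) /
      (sum(y == 1) * sum(y == 0))
  }
  expect_gte(auc(scores, held$label), 0.9)

  # negative control: shuffled labels give chance-level AUC
  set.seed(9)
  shuf <- pairs[tr_idx, ]
  shuf$label <- sample(shuf$label)
  model0 <- buildSiamese(siameseConfig(epochs = 24, seed = 7))
  model0 <- trainSimilarity(model0, obs, shuf, c(128, 128))
  scores0 <- vapply(seq_len(nrow(held)), function(k)
    pairSimilarity(model0, obs[[held$i[k]]], obs[[held$j[k]]], c(128, 128)),
    1.0)
  expect_lt(abs(auc(scores0, held$label) - 0.5), 0.15)

  # determinism: same seed, same loss log
  model2 <- buildSiamese(siameseConfig(epochs = 6, seed = 6))
  model2 <- trainSimilarity(model2, obs, pairs[tr_idx, ], c(128, 128))
  expect_identical(model@config$loss_log, model2@config$loss_log)

  # a trained score ranks an observation's own successor above a distant one
  o_now <- obs[[1]]
  o_next <- obs[[3]]    # same ear, next frame
  far_frame <- which(vapply(obs, function(o) o$frame, 1L) > 80)[1]
  s_near <- pairSimilarity(model, o_now, o_next, c(128, 128))
  s_far <- pairSimilarity(model, o_now, obs[[far_frame]], c(128, 128))
  expect_gte(s_near, s_far)
})

test_that("single-class pair sets are rejected", {
  frame <- matrix(128, 40, 40)
  obs <- lapply(0:3, function(f)
    makeObservation(frame, f, c(10, 10, 14, 14), id = 1L, cropSize = 16))
  pairs <- data.frame(i = 1:3, j = 2:4, label = 1L)
  model <- buildSiamese(siameseConfig(cropSize = 16))
  expect_error(trainSimilarity(model, obs, pairs, c(40, 40)), "both classes")
})

test_that("ear grouping averages visible ear centroids per individual", {
  et <- data.frame(frame = c(0, 0, 0, 1), ear = c(1L, 2L, 3L, 1L),
                   x = c(10, 14, 30, 11), y = c(10, 10, 20, 10))
  map <- c("1" = 1L, "2" = 1L, "3" = 2L)
  g <- groupEarsToIndividuals(et, map)
  expect_equal(g$x[g$frame == 0 & g$ind == 1], 12)
  expect_equal(g$y[g$frame == 0 & g$ind == 1], 10)
  expect_equal(g$x[g$frame == 0 & g$ind == 2], 30)   # one ear suffices
  expect_equal(g$x[g$frame == 1 & g$ind == 1], 11)
  expect_error(groupEarsToIndividuals(et, c("1" = 1L)), "no individual")
})
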