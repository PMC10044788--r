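test_that("velocity series implements the calibration arithmetic", {
  still <- data.frame(frame = 0:9, x = 5, y = 5)
  vs <- velocitySeries(still, frameRate = 40, pxPerCm = 2)
  expect_true(all(vs$speeds$speed == 0))

  # 10 px/frame at 40 fps with 2 px/cm is 200 cm/s
  mov <- data.frame(frame = 0:9, x = seq(0, 90, 10), y = 0)
  vs2 <- velocitySeries(mov, frameRate = 40, pxPerCm = 2)
  expect_true(all(abs(vs2$speeds$speed - 200) < 1e-12))

  # doubling the calibration halves every speed
  vs3 <- velocitySeries(mov, frameRate = 40, pxPerCm = 4)
  expect_equal(vs3$speeds$speed, vs2$speeds$speed / 2)

  # a 40-minute recording yields 8 five-minute blocks
  n <- 40 * 60 * 5          # 40 min at 5 fps
  long <- data.frame(frame = 0:(n - 1), x = seq_len(n), y = 0)
  vs4 <- velocitySeries(long, frameRate = 5, pxPerCm = 10)
  expect_length(vs4$blockMeans, 8)
  expect_true(all(is.finite(vs4$blockMeans)))

  # gap frames are excluded, not interpolated
  gappy <- data.frame(frame = c(0, 1, 2, 10, 11), x = c(0, 1, 2, 50, 51),
                      y = 0)
  vs5 <- velocitySeries(gappy, frameRate = 1, pxPerCm = 1)
  expect_equal(nrow(vs5$speeds), 3)   # steps 0-1, 1-2, 10-11 only
  expect_true(all(vs5$speeds$speed == 1))

  expect_error(velocitySeries(still[1, ], 40, 2), "two positions")
})

test_that("the 2D spatial SD matches its closed population form", {
  expect_equal(spatialSD(rep(3, 5), rep(7, 5))$sigma2d, 0)
  expect_equal(spatialSD(c(0, 2), c(0, 0))$sigma2d, 1)

  set.seed(2)
  x <- rnorm(40); y <- rnorm(40)
  s <- spatialSD(x, y)$sigma2d
  expect_equal(spatialSD(x + 13, y - 4)$sigma2d, s)        # translation
  # dimensional reduction: all y equal reduces to the 1D population SD of x
  expect_equal(spatialSD(x, rep(1, 40))$sigma2d,
               sqrt(mean((x - mean(x))^2)))
  expect_error(spatialSD(numeric(), numeric()), "non-empty")
})

test_that("region occupancy follows the 12-cell main-region grid", {
  # (400, 300) falls in column 0, row 0 of the 320-960 x 240-720 grid
  traj <- data.frame(frame = 0:9, x = 400, y = 300)
  occ <- regionOccupancy(traj)
  expect_equal(unname(occ$fractions[1]), 1)
  expect_equal(sum(occ$fractions), 1)
  expect_length(occ$fractions, 12)

  outside <- data.frame(frame = 0:9, x = 10, y = 10)
  expect_equal(sum(regionOccupancy(outside)$fractions), 0)

  # region numbering is row-major: (500, 500) is column 1, row 1 -> 6
  mid <- data.frame(frame = 0, x = 500, y = 500)
  expect_equal(unname(which(regionOccupancy(mid)$fractions > 0)), 6)

  # fractions over an in-region trajectory sum to exactly 1
  set.seed(4)
  inr <- data.frame(frame = 0:999, x = runif(1000, 320, 959.99),
                    y = runif(1000, 240, 719.99))
  expect_equal(sum(regionOccupancy(inr)$fractions), 1, tolerance = 1e-12)

  expect_error(regionOccupancy(traj, xRange = c(0, 100), cellSize = 33),
               "divisible")
  expect_error(regionOccupancy(traj, numbering = c(1:11, 11)), "permutation")
})

test_that("uniform coverage spreads occupancy evenly across regions", {
  set.seed(11)
  n <- 120000
  traj <- data.frame(frame = seq_len(n) - 1,
                     x = runif(n, 320, 960), y = runif(n, 240, 720))
  occ <- regionOccupancy(traj)
  p <- 1 / 12
  tol <- 3 * sqrt(p * (1 - p) / n)
  expect_true(all(abs(occ$fractions - p) < tol))
})

test_that("the rank-sum test matches the exact permutation distribution", {
  expect_equal(rankSumTest(c(1, 2, 3), c(1, 2, 3)), 1)

  # fully separated samples: the most extreme of the C(8,4)=70 rank splits,
  # two-sided exact p = 2/70
  expect_equal(rankSumTest(c(1, 2, 3, 4), c(10, 11, 12, 13)), 2 / 70)

  # all tied data degenerates to p = 1
  expect_equal(suppressMessages(rankSumTest(rep(5, 4), rep(5, 6))), 1)

  # large tied samples use the normal approximation without error
  set.seed(1)
  a <- sample(1:5, 30, replace = TRUE)
  b <- sample(2:6, 30, replace = TRUE)
  p <- rankSumTest(a, b)
  expect_true(p >= 0 && p <= 1)
  expect_error(rankSumTest(numeric(), 1:3), "non-empty")
})
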