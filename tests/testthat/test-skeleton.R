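test_that("a 3x50 bar thins to a single midline polyline", {
  m <- matrix(FALSE, 40, 80)
  m[19:21, 11:60] <- TRUE
  cs <- skeletonizeMask(RoiMask(m, "microvessel"), prunePx = 5)
  expect_length(centerlines(cs), 1)
  len <- polylineLength(centerlines(cs)[[1]])
  expect_gte(len, 47)  # medial axis of the bar is 49, end effects tolerated
  expect_lte(len, 51)
  expect_true(all(abs(centerlines(cs)[[1]][, 1] - 20) <= 1))
  expect_equal(nrow(cs@junctions), 0)
  expect_identical(curveSource(cs), "skeleton")
})

test_that("objects below 2 px yield no curve", {
  s <- matrix(FALSE, 10, 10); s[5, 5] <- TRUE
  expect_length(centerlines(skeletonizeMask(RoiMask(s, "x"), 5)), 0)
  expect_error(skeletonizeMask(matrix(FALSE, 5, 5)), "empty")
})

test_that("a plus sign decomposes into 4 branches at 1 junction node", {
  cs <- skeletonizeMask(RoiMask(plusMask(), "microvessel"), prunePx = 5)
  expect_length(centerlines(cs), 4)
  expect_equal(nrow(cs@junctions), 1)
  ## all four branches meet near the center
  expect_lt(max(abs(cs@junctions - 30)), 2)
})

test_that("skeletons are subsets of their masks with unit-step polylines", {
  masks <- list(plusMask(),
                tubeMask(c(64, 64), c(20, 10), c(50, 55), 3))
  for (m in masks) {
    sk <- thinMask(m)
    expect_true(all(m[sk]))          # subset of the mask
    expect_identical(thinMask(sk), sk)  # thinning is idempotent
    cs <- skeletonizeMask(RoiMask(m, "microvessel"), prunePx = 5)
    for (cv in centerlines(cs)) {
      steps <- sqrt(rowSums(diff(cv)^2))
      expect_lte(max(steps), sqrt(2) + 1e-9)
    }
  }
})

test_that("tube skeleton length matches the centerline within w + 2*prune", {
  a <- c(32, 10); b <- c(36, 120)
  w <- 3; prune <- 5
  m <- tubeMask(c(64, 128), a, b, w)
  cs <- skeletonizeMask(RoiMask(m, "microvessel"), prunePx = prune)
  len <- sum(vapply(centerlines(cs), polylineLength, numeric(1)))
  L <- sqrt(sum((b - a)^2))
  expect_lte(abs(len - L), w + 2 * prune)
})

test_that("spur pruning removes short side twigs but keeps real branches", {
  m <- matrix(FALSE, 50, 90)
  m[24:26, 6:85] <- TRUE       # main bar
  m[21:23, 40] <- TRUE         # 3 px spur off the side
  cs <- skeletonizeMask(RoiMask(m, "microvessel"), prunePx = 5)
  expect_length(centerlines(cs), 1)
  expect_equal(nrow(cs@junctions), 0)
  ## with pruning off, the twig survives as its own branch
  cs0 <- skeletonizeMask(RoiMask(m, "microvessel"), prunePx = 0)
  expect_gt(length(centerlines(cs0)), 1)
})
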