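test_that("finite differences follow the definition pixel by pixel", {
  A <- matrix(0.3, 6, 6)
  d <- finiteDifferences(CineLoop(array(A, c(6, 6, 3))))
  expect_equal(nDiffs(d), 2L)
  expect_true(all(diffImages(d) == 0))

  fr <- array(0, c(6, 6, 2)); fr[, , 2] <- 0.7
  d2 <- finiteDifferences(CineLoop(fr))
  expect_true(all(diffImages(d2) == 0.7))

  fr3 <- array(0.2, c(4, 4, 3)); fr3[2, 3, ] <- c(0.1, 0.5, 0.2)
  d3 <- finiteDifferences(CineLoop(fr3))
  expect_equal(diffImages(d3)[2, 3, ], c(0.4, 0.3))
  expect_error(CineLoop(array(0, c(4, 4, 1))), "T >= 2")
})

test_that("batch angiogram equals the independent per-pixel oracle", {
  set.seed(21)
  for (i in 1:5) {
    loop <- randomLoop(9, 7, sample(2:8, 1))
    ang <- angiogramBatch(loop)
    expect_lt(max(abs(angioImage(ang) - angiogramOracle(loop))), 1e-12)
    expect_equal(tUsed(ang), nFrames(loop) - 1L)
  }
})

test_that("a pixel alternating 0 and a accumulates exactly a", {
  a <- 0.37
  fr <- array(0.1, c(5, 5, 16))
  fr[3, 3, ] <- rep(c(0, a), 8)
  ang <- angiogramBatch(CineLoop(fr))
  expect_identical(angioImage(ang)[3, 3], a)
  expect_identical(angioImage(ang)[1, 1], 0)
})

test_that("online updates match their closed forms and the batch mean", {
  D <- matrix(runif(36), 6, 6)
  a1 <- angiogramOnlineUpdate(emptyAngiogram(c(6, 6)), D)
  expect_identical(angioImage(a1), D)
  D2 <- matrix(runif(36), 6, 6)
  a2 <- angiogramOnlineUpdate(a1, D2)
  expect_equal(angioImage(a2), (D + D2) / 2, tolerance = 1e-15)
  expect_error(angiogramOnlineUpdate(a1, matrix(0, 3, 3)), "shape")
  expect_error(angiogramOnlineUpdate(a1, -D), "nonnegative")

  set.seed(22)
  loop <- randomLoop(16, 16, 12)
  expect_lt(max(abs(angioImage(angiogramOnline(loop)) -
                    angioImage(angiogramBatch(loop)))), 1e-9)
})

test_that("angiogram is homogeneous, shift-invariant and nonnegative", {
  set.seed(23)
  for (i in 1:10) {
    loop <- randomLoop(8, 8, sample(2:10, 1))
    base <- angioImage(angiogramBatch(loop))
    expect_gte(min(base), 0)
    alpha <- runif(1, 0, 2)
    scaled <- CineLoop(frames(loop) * alpha)
    expect_equal(angioImage(angiogramBatch(scaled)), base * alpha,
                 tolerance = 1e-12)
    shifted <- CineLoop(frames(loop) + 0.5)
    expect_equal(angioImage(angiogramBatch(shifted)), base,
                 tolerance = 1e-12)
  }
  ## pixels with constant traces are exactly zero even in a moving scene
  fr <- array(runif(128), c(4, 4, 8))
  fr[1, 1, ] <- 0.42
  expect_identical(angioImage(angiogramBatch(CineLoop(fr)))[1, 1], 0)
})

test_that("display enhancement clips at the percentile and rescales", {
  z <- enhanceForDisplay(Angiogram(matrix(0, 8, 8), tUsed = 3L))
  expect_true(all(z$display == 0))
  expect_equal(displayRange(z$angio), c(0, 0))

  vals <- matrix(0:99 / 10, 10, 10)
  e <- enhanceForDisplay(Angiogram(vals, tUsed = 1L),
                         clipPercentile = 100)
  expect_equal(min(e$display), 0)
  expect_equal(max(e$display), 1)
  ## linear below the clip
  expect_equal(e$display, vals / max(vals), tolerance = 1e-12)

  ## a single huge outlier is clipped at the 99th percentile: the rest
  ## then spans nearly the full range (explicit percentile-clip oracle)
  v <- matrix(runif(400), 20, 20)
  v[5, 5] <- 100
  e2 <- enhanceForDisplay(Angiogram(v, tUsed = 1L), clipPercentile = 99)
  hi <- as.numeric(quantile(v, 0.99, names = FALSE))
  expect_equal(e2$display, pmin(v / hi, 1), tolerance = 1e-12)
  expect_equal(e2$display[5, 5], 1)
  expect_gt(max(e2$display[-(5 + 4 * 20)]), 0.9)
  expect_error(enhanceForDisplay(Angiogram(v, tUsed = 1L), 40),
               "clipPercentile")
})

test_that("angiograms persist through TIFF + sidecar", {
  set.seed(24)
  ang <- angiogramBatch(randomLoop(12, 12, 6))
  e <- enhanceForDisplay(ang)
  p <- withr::local_tempfile(fileext = ".tif")
  writeAngiogram(e$angio, p)
  back <- readAngiogram(p)
  expect_equal(tUsed(back), tUsed(ang))
  expect_equal(angioImage(back), angioImage(ang),
               tolerance = max(angioImage(ang)) / 65535)
  expect_equal(displayRange(back), displayRange(e$angio))
})
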