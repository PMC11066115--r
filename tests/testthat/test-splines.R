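test_that("boundary interpolation passes through every knot", {
  square <- rbind(c(10, 10), c(10, 30), c(30, 30), c(30, 10))
  b <- interpolateBoundary(PointAnnotation(square, closed = TRUE),
                           samplesPerSegment = 2)
  cv <- boundaryCurve(b)
  for (i in 1:4) {
    d <- sqrt(rowSums((cv - matrix(square[i, ], nrow(cv), 2,
                                   byrow = TRUE))^2))
    expect_lt(min(d), 1e-9)
  }
  expect_gte(nrow(cv), 8)
  expect_identical(curveSource(b), "manual")
  expect_gt(polygonArea(cv), 0)
})

test_that("8 knots on a circle reconstruct it within half a pixel", {
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  pts <- cbind(60 + 20 * sin(th), 60 + 20 * cos(th))
  b <- interpolateBoundary(PointAnnotation(pts, closed = TRUE),
                           samplesPerSegment = 25)
  cv <- boundaryCurve(b)
  rad <- sqrt((cv[, 1] - 60)^2 + (cv[, 2] - 60)^2)
  expect_lt(max(abs(rad - 20)), 0.5)
})

test_that("degenerate but legal boundaries stay valid closed curves", {
  thin <- rbind(c(10, 10), c(10.4, 30), c(10.8, 10.2))
  b <- interpolateBoundary(PointAnnotation(thin, closed = TRUE), 5)
  expect_gt(polygonArea(boundaryCurve(b)), 0)
  expect_error(
    interpolateBoundary(PointAnnotation(rbind(c(1, 1), c(2, 2), c(1, 1.5)),
                                        closed = FALSE)),
    "closed")
  dup <- rbind(c(10, 10), c(10, 10), c(10, 30), c(30, 20))
  expect_warning(interpolateBoundary(PointAnnotation(dup, closed = TRUE)),
                 "duplicate")
})

test_that("open curves interpolate through knots, linear when forced", {
  seg <- interpolateCurve(PointAnnotation(rbind(c(5, 5), c(15, 25))), 10)
  expect_equal(seg[1, ], c(5, 5))
  expect_equal(seg[nrow(seg), ], c(15, 25))
  t <- seq(0, 1, length.out = nrow(seg))
  expect_equal(seg, cbind(5 + 10 * t, 5 + 20 * t), tolerance = 1e-9)

  ## natural spline of collinear knots is the same line
  col3 <- rbind(c(2, 3), c(7, 13), c(12, 23))
  cv <- interpolateCurve(PointAnnotation(col3), 10)
  expect_lt(max(abs(cv[, 2] - (2 * cv[, 1] - 1))), 1e-9)
})

test_that("5 knots on a sine arc reconstruct it within half a pixel", {
  x <- seq(10, 50, length.out = 5)
  pts <- cbind(40 + 8 * sin((x - 10) / 40 * pi), x)
  cv <- interpolateCurve(PointAnnotation(pts), 20)
  xd <- seq(10, 50, by = 0.05)
  arc <- cbind(40 + 8 * sin((xd - 10) / 40 * pi), xd)
  err <- vapply(seq_len(nrow(cv)), function(i)
    min(sqrt((arc[, 1] - cv[i, 1])^2 + (arc[, 2] - cv[i, 2])^2)),
    numeric(1))
  expect_lt(max(err), 0.5)
})
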