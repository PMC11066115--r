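test_that("integer cines normalize by the dtype maximum, idempotently", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(replicate(3, matrix(1, 8, 8), simplify = FALSE), path,
                  bits.per.sample = 8L)
  loop <- readCine(path, normalize = TRUE)
  expect_equal(nFrames(loop), 3L)
  expect_true(all(frames(loop) == 1.0))

  ## half-scale 8-bit values map to 128/255, not to a per-file max of 1
  path2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(replicate(2, matrix(128 / 255, 8, 8),
                            simplify = FALSE), path2,
                  bits.per.sample = 8L)
  loop2 <- readCine(path2)
  expect_equal(max(frames(loop2)), 128 / 255)
})

test_that("lossless TIFF cine round trips bit-exactly", {
  set.seed(11)
  loop <- randomLoop(12, 10, 6)
  path <- withr::local_tempfile(fileext = ".tif")
  writeCine(loop, path, bitDepth = 16L)
  back <- readCine(path)
  ## the writer quantizes; a second round trip must be the identity
  path2 <- withr::local_tempfile(fileext = ".tif")
  writeCine(back, path2, bitDepth = 16L)
  expect_identical(frames(readCine(path2)), frames(back))
  expect_lt(max(abs(frames(back) - frames(loop))), 1 / (2 * 65535) + 1e-12)
})

test_that("RGB cines with equal channels match their grayscale twin", {
  set.seed(12)
  vals <- matrix(runif(64), 8, 8)
  vals <- .roundHalfUpTest(vals * 255) / 255
  rgbPath <- withr::local_tempfile(fileext = ".tif")
  grayPath <- withr::local_tempfile(fileext = ".tif")
  rgbFrame <- array(vals, c(8, 8, 3))
  tiff::writeTIFF(list(rgbFrame, rgbFrame), rgbPath, bits.per.sample = 8L)
  tiff::writeTIFF(list(vals, vals), grayPath, bits.per.sample = 8L)
  expect_equal(frames(readCine(rgbPath)), frames(readCine(grayPath)))
  ## channel-average oracle for unequal channels
  rgb2 <- array(runif(8 * 8 * 3), c(8, 8, 3))
  rgb2 <- .roundHalfUpTest(rgb2 * 255) / 255
  p <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(rgb2, rgb2), p, bits.per.sample = 8L)
  expect_equal(frames(readCine(p))[, , 1],
               apply(rgb2, c(1, 2), mean), tolerance = 1e-12)
})

test_that("degenerate cine files are rejected with clear errors", {
  expect_error(readCine(file.path(tempdir(), "no-such-file.tif")),
               "cannot read")
  one <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 8, 8), one)
  expect_error(readCine(one), "T >= 2")
  expect_error(readCine("clip.avi"), "cannot read|AVI")
})

test_that("writeImage quantizes with round-half-away-from-zero", {
  p <- withr::local_tempfile(fileext = ".png")
  writeImage(matrix(0.5, 4, 4), p, bitDepth = 8L)
  expect_true(all(png::readPNG(p) * 255 == 128))
  writeImage(matrix(0, 4, 4), p, bitDepth = 8L)
  expect_true(all(png::readPNG(p) == 0))
  expect_error(writeImage(matrix(1.5, 4, 4), p), "normalize")

  set.seed(13)
  img <- matrix(runif(100), 10, 10)
  for (bits in c(8L, 16L)) {
    q <- withr::local_tempfile(fileext = ".tif")
    writeImage(img, q, bitDepth = bits)
    expect_lte(max(abs(readImageGray(q) - img)),
               1 / (2 * (2^bits - 1)) + 1e-12)
  }
})

test_that("annotation JSON round trips losslessly", {
  path <- withr::local_tempfile(fileext = ".json")
  pts <- matrix(c(10.25, 20.5, 30.125, 40.0625, 12.3, 4.7, 9.99, 3.14),
                4, 2)
  ann <- PointAnnotation(pts, closed = TRUE, label = "cam_vessel")
  m <- matrix(FALSE, 5, 7); m[1, 1] <- TRUE
  writeAnnotations(list(ann, RoiMask(m, "microvessel")), path)
  back <- readAnnotations(path)
  expect_length(back, 2)
  expect_identical(annotationPoints(back[[1]]), pts)
  expect_true(isClosed(back[[1]]))
  expect_identical(maskImage(back[[2]]), m)
  expect_identical(annotationLabel(back[[2]]), "microvessel")
})

test_that("annotation schema violations name the failing field", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines('{"items":[{"type":"points","closed":true,
               "points":[[0.5,5],[3,3],[4,4]]}]}', p)
  expect_error(readAnnotations(p), "items\\[1\\].points")
  writeLines('{"items":[{"type":"blob"}]}', p)
  expect_error(readAnnotations(p), "items\\[1\\].type")
  writeLines('{"nothing":true}', p)
  expect_error(readAnnotations(p), "items")
  ## out-of-extent points against a known frame shape
  ann <- PointAnnotation(rbind(c(2, 2), c(50, 2)), closed = FALSE)
  expect_error(checkAnnotationExtent(ann, c(10, 10)), "extent")
})
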