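test_that("a zero-vessel, zero-jitter scene is perfectly static", {
  sc <- SynthScene(shape = c(48L, 48L), vessels = list(),
                   backgroundJitterSd = 0, nFrames = 8L, seed = 3L)
  res <- renderScene(sc)
  fr <- frames(res$loop)
  for (t in 2:8) expect_identical(fr[, , t], fr[, , 1])
  expect_true(all(angioImage(angiogramBatch(res$loop)) == 0))
  expect_false(any(res$groundTruth$vessel_mask))
  expect_equal(res$groundTruth$branch_count, 0L)
})

test_that("rendering is bit-deterministic in the seed", {
  r1 <- renderScene(tinyScene(seed = 9L, jitter = 0.01))
  r2 <- renderScene(tinyScene(seed = 9L, jitter = 0.01))
  expect_identical(frames(r1$loop), frames(r2$loop))
  r3 <- renderScene(tinyScene(seed = 10L, jitter = 0.01))
  expect_false(identical(frames(r1$loop), frames(r3$loop)))
})

test_that("non-vessel pixels are frozen and angiogram support is confined", {
  sc <- tinyScene(seed = 4L, jitter = 0)
  res <- renderScene(sc)
  fr <- frames(res$loop)
  v <- sc@vessels[[1]]
  d <- camangio:::.distToPolyline(c(64L, 64L), v$centerline)
  dilated <- d <= v$half_width_px + 3 * (v$half_width_px / 2)
  outside <- which(!dilated)
  for (t in 2:dim(fr)[3])
    expect_identical(fr[, , t][outside], fr[, , 1][outside])
  ang <- angioImage(angiogramBatch(res$loop))
  expect_true(all(ang[!dilated] == 0))
  expect_gt(mean(ang[res$groundTruth$vessel_mask]), 0)
})

test_that("the background does not depend on the frame count", {
  a <- renderScene(tinyScene(seed = 5L, nFrames = 2L))
  b <- renderScene(tinyScene(seed = 5L, nFrames = 12L))
  expect_identical(frames(a$loop)[, , 1], frames(b$loop)[, , 1])
})

test_that("benchmark scenes carry their documented ground truth", {
  expect_equal(renderScene(defaultBenchmarkScene("bifurcation", 1)
                           )$groundTruth$branch_count, 1L)
  sc <- defaultBenchmarkScene("tree3", 1)
  expect_equal(camangio:::.sceneBranchCount(sc), 3L)
  st <- defaultBenchmarkScene("single_tube", 1)
  expect_equal(camangio:::.arcParam(st@vessels[[1]]$centerline)$total, 200)
  expect_error(defaultBenchmarkScene("spiral", 1))
})

test_that("scenes reject tubes outside the frame and round-trip YAML", {
  expect_error(SynthScene(shape = c(32L, 32L),
                          vessels = list(list(centerline = rbind(c(2, 2),
                                                                 c(30, 30)),
                                              half_width_px = 4,
                                              flow_px_per_frame = 1,
                                              scatterer_density = 2)),
                          nFrames = 4L),
               "outside")
  sc <- tinyScene(seed = 6L)
  p <- withr::local_tempfile(fileext = ".yaml")
  writeScene(sc, p)
  back <- readScene(p)
  expect_equal(back@vessels[[1]]$centerline, sc@vessels[[1]]$centerline)
  expect_identical(frames(renderScene(back)$loop),
                   frames(renderScene(sc)$loop))
})
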