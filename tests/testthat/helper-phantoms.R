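## Phantom builders shared across the suite. Everything is generated in
## code; coordinates are 1-based (row, col) with pixel centers at
## integers.

.roundHalfUpTest <- function(x) floor(x + 0.5)

diskImage <- function(M = 128, center = c(64, 64), radius = 30,
                      contrast = 1) {
  rr <- matrix(seq_len(M), M, M)
  cc <- t(rr)
  ((rr - center[1])^2 + (cc - center[2])^2 <= radius^2) * contrast
}

diskMask <- function(M = 128, center = c(64, 64), radius = 40) {
  diskImage(M, center, radius, 1) > 0
}

## analytic tube mask: pixels with distance to the segment a-b strictly
## below halfWidth (the rasterization the simulator ground truth uses)
tubeMask <- function(shape, a, b, halfWidth) {
  M <- shape[1]; N <- shape[2]
  pr <- rep(seq_len(M), N); pc <- rep(seq_len(N), each = M)
  ab <- b - a
  len2 <- sum(ab^2)
  t <- pmin(pmax(((pr - a[1]) * ab[1] + (pc - a[2]) * ab[2]) / len2, 0), 1)
  d <- sqrt((pr - (a[1] + t * ab[1]))^2 + (pc - (a[2] + t * ab[2]))^2)
  matrix(d < halfWidth, M, N)
}

plusMask <- function() {
  p <- matrix(FALSE, 60, 60)
  p[29:31, 10:50] <- TRUE
  p[10:50, 29:31] <- TRUE
  p
}

randomLoop <- function(M = 16, N = 16, T = 5) {
  CineLoop(array(runif(M * N * T), c(M, N, T)))
}

## independent per-pixel oracle for the batch angiogram: walks each
## pixel's temporal trace, never touching the package's array slicing
angiogramOracle <- function(loop) {
  apply(frames(loop), c(1, 2), function(v) sum(abs(diff(v))) / (length(v) - 1))
}

tinyScene <- function(seed = 1L, jitter = 0, nFrames = 16L) {
  tube <- list(centerline = rbind(c(32, 10), c(32, 54)), half_width_px = 3,
               flow_px_per_frame = 2, scatterer_density = 2)
  SynthScene(shape = c(64L, 64L), vessels = list(tube),
             backgroundJitterSd = jitter, nFrames = nFrames, seed = seed)
}
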