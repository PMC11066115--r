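## Synthetic UHF-like B-mode cine simulator. The contrast mechanism the
## virtual angiography exploits is moving speckle inside vessels against
## a static background, so the simulator renders exactly that: a frozen
## Rayleigh-speckle background plus bright Gaussian scatterers (stand-ins
## for flowing erythrocytes) advected along each vessel centerline,
## wrapping at the tube ends (conveyor model) so density is stationary.
## Blobs are truncated at 3 sd, so with zero jitter the angiogram is
## exactly zero outside the dilated tube. Everything is driven by three
## deterministically derived RNG substreams (background / scatterers /
## jitter), so changing the frame count never changes the background.

.subSeed <- function(seed, k) (abs(seed) %% 1000000000L) * 2L + k

## arc-length parameterization of a polyline
.arcParam <- function(cl) {
  seg <- sqrt(rowSums(diff(cl)^2))
  list(s = c(0, cumsum(seg)), total = sum(seg))
}

## point and unit normal at arc length s (vectorized over s)
.pointAt <- function(cl, par, s) {
  r <- approx(par$s, cl[, 1], xout = s, rule = 2)$y
  c <- approx(par$s, cl[, 2], xout = s, rule = 2)$y
  seg <- findInterval(s, par$s, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), nrow(cl) - 1L)
  dr <- cl[seg + 1, 1] - cl[seg, 1]
  dc <- cl[seg + 1, 2] - cl[seg, 2]
  nrm <- sqrt(dr^2 + dc^2)
  list(r = r, c = c, nr = -dc / nrm, nc = dr / nrm)
}

## distance from every pixel center to a polyline (min over segments)
.distToPolyline <- function(shape, cl) {
  M <- shape[1]; N <- shape[2]
  pr <- rep(seq_len(M), N); pc <- rep(seq_len(N), each = M)
  d2 <- rep(Inf, M * N)
  for (i in seq_len(nrow(cl) - 1)) {
    a <- cl[i, ]; b <- cl[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 > 0)
      pmin(pmax(((pr - a[1]) * ab[1] + (pc - a[2]) * ab[2]) / len2, 0), 1)
    else 0
    dd <- (pr - (a[1] + t * ab[1]))^2 + (pc - (a[2] + t * ab[2]))^2
    d2 <- pmin(d2, dd)
  }
  matrix(sqrt(d2), M, N)
}

## add a truncated Gaussian blob (cut at 3 sd) in place
.addBlob <- function(img, r0, c0, sd, amp) {
  M <- nrow(img); N <- ncol(img)
  R <- ceiling(3 * sd)
  rs <- max(1, floor(r0 - R)):min(M, ceiling(r0 + R))
  cs <- max(1, floor(c0 - R)):min(N, ceiling(c0 + R))
  if (!length(rs) || !length(cs)) return(img)
  d2 <- outer((rs - r0)^2, (cs - c0)^2, `+`)
  blob <- amp * exp(-d2 / (2 * sd^2))
  blob[d2 > (3 * sd)^2] <- 0
  img[rs, cs] <- img[rs, cs] + blob
  img
}

#' Render a synthetic scene into a cine loop with ground truth
#'
#' The background (speckle mean plus Rayleigh noise, optionally Gaussian
#' blurred, clipped to [0, 1]) is frozen across frames; per-frame
#' variation comes only from scatterer motion inside the vessel tubes and
#' from optional additive Gaussian jitter. Identical seeds give
#' bit-identical loops. Ground truth derives analytically from the scene:
#' the vessel mask contains pixels with distance to a centerline strictly
#' below the half-width, and the branch count is the number of positions
#' where at least three vessel-segment endpoints coincide.
#'
#' @param scene a \linkS4class{SynthScene}.
#' @return list with \code{loop} (\linkS4class{CineLoop}) and
#'   \code{groundTruth} (list: \code{vessel_mask}, \code{centerlines},
#'   \code{branch_count}, \code{total_length_px}).
#' @export
renderScene <- function(scene) {
  stopifnot(is(scene, "SynthScene"))
  validObject(scene)
  M <- scene@shape[1]; N <- scene@shape[2]
  sp <- scene@speckle

  ## substream 0: frozen background
  set.seed(.subSeed(scene@seed, 0L))
  ray <- sp$rayleigh_sigma * sqrt(-2 * log(runif(M * N)))
  bg <- matrix(sp$mean + ray, M, N)
  if (sp$blur_sigma_px > 0)
    bg <- EBImage::gblur(bg, sigma = sp$blur_sigma_px)
  bg <- pmin(pmax(bg, 0), 1)

  ## substream 1: scatterer placement
  set.seed(.subSeed(scene@seed, 1L))
  scat <- list()
  for (v in scene@vessels) {
    par <- .arcParam(v$centerline)
    area <- par$total * 2 * v$half_width_px
    n <- rpois(1, v$scatterer_density / 100 * area)
    scat[[length(scat) + 1L]] <-
      list(v = v, par = par, s0 = runif(n, 0, par$total),
           u = runif(n, -v$half_width_px, v$half_width_px))
  }

  ## substream 2: per-frame jitter (drawn even when sd = 0 would skip,
  ## only if needed, to keep the zero-jitter path exactly static)
  jitterSeed <- .subSeed(scene@seed, 2L)

  frames <- vector("list", scene@nFrames)
  for (t in seq_len(scene@nFrames)) {
    img <- bg
    for (sc in scat) {
      if (!length(sc$s0)) next
      s <- (sc$s0 + (t - 1) * sc$v$flow_px_per_frame) %% sc$par$total
      p <- .pointAt(sc$v$centerline, sc$par, s)
      sdBlob <- sc$v$half_width_px / 2
      for (i in seq_along(s))
        img <- .addBlob(img, p$r[i] + sc$u[i] * p$nr[i],
                        p$c[i] + sc$u[i] * p$nc[i], sdBlob, 0.5)
    }
    img <- pmin(pmax(img, 0), 1)
    frames[[t]] <- img
  }
  if (scene@backgroundJitterSd > 0) {
    set.seed(jitterSeed)
    for (t in seq_len(scene@nFrames))
      frames[[t]] <- pmin(pmax(
        frames[[t]] + matrix(rnorm(M * N, 0, scene@backgroundJitterSd),
                             M, N), 0), 1)
  }

  mask <- matrix(FALSE, M, N)
  total <- 0
  for (v in scene@vessels) {
    mask <- mask | (.distToPolyline(scene@shape, v$centerline) <
                      v$half_width_px)
    total <- total + .arcParam(v$centerline)$total
  }
  cls <- CenterlineSet(lapply(scene@vessels, `[[`, "centerline"),
                       source = "manual")
  list(loop = CineLoop(frames),
       groundTruth = list(vessel_mask = mask, centerlines = cls,
                          branch_count = .sceneBranchCount(scene),
                          total_length_px = total))
}

## branch points = positions where >= 3 vessel-polyline endpoints meet
.sceneBranchCount <- function(scene) {
  if (!length(scene@vessels)) return(0L)
  ends <- do.call(rbind, lapply(scene@vessels, function(v)
    v$centerline[c(1, nrow(v$centerline)), , drop = FALSE]))
  used <- rep(FALSE, nrow(ends))
  count <- 0L
  for (i in seq_len(nrow(ends))) {
    if (used[i]) next
    same <- which(!used &
                    abs(ends[, 1] - ends[i, 1]) < 1e-6 &
                    abs(ends[, 2] - ends[i, 2]) < 1e-6)
    used[same] <- TRUE
    if (length(same) >= 3L) count <- count + 1L
  }
  count
}

#' Frozen benchmark scenes
#'
#' Three documented scenes used throughout the test-bench, all 256 x 256,
#' 64 frames, half-width 4 px, flow 2 px/frame, scatterer density 2 per
#' 100 px^2 (sparse enough that overlapping blobs do not saturate the
#' lumen), default speckle (mean 0.25, Rayleigh sigma 0.06, blur 1 px):
#' \describe{
#'   \item{single_tube}{one straight horizontal tube along row 128 from
#'     col 28 to 228 (centerline length 200 px), 0 branch points.}
#'   \item{bifurcation}{a Y: trunk (40,128)-(128,128) splitting into two
#'     oblique branches, 1 branch point.}
#'   \item{tree3}{a binary tree with a trunk and two generations of
#'     splits, 3 branch points.}
#' }
#'
#' @param kind one of \code{"single_tube"}, \code{"bifurcation"},
#'   \code{"tree3"}.
#' @param seed RNG seed for the scene.
#' @param backgroundJitterSd per-frame Gaussian jitter sd (default 0,
#'   i.e. a perfectly static background).
#' @return a \linkS4class{SynthScene}.
#' @export
defaultBenchmarkScene <- function(kind = c("single_tube", "bifurcation",
                                           "tree3"),
                                  seed = 1L, backgroundJitterSd = 0) {
  kind <- match.arg(kind)
  tube <- function(a, b) list(centerline = rbind(a, b), half_width_px = 4,
                              flow_px_per_frame = 2, scatterer_density = 2)
  vessels <- switch(kind,
    single_tube = list(tube(c(128, 28), c(128, 228))),
    bifurcation = list(tube(c(40, 128), c(128, 128)),
                       tube(c(128, 128), c(216, 68)),
                       tube(c(128, 128), c(216, 188))),
    tree3 = list(tube(c(30, 128), c(100, 128)),
                 tube(c(100, 128), c(170, 70)),
                 tube(c(100, 128), c(170, 186)),
                 tube(c(170, 70), c(230, 40)),
                 tube(c(170, 70), c(230, 100)),
                 tube(c(170, 186), c(230, 156)),
                 tube(c(170, 186), c(230, 216))))
  SynthScene(shape = c(256L, 256L), vessels = vessels,
             backgroundJitterSd = backgroundJitterSd, nFrames = 64L,
             seed = seed)
}

#' Serialize a scene to YAML / read it back
#' @param scene a \linkS4class{SynthScene}.
#' @param path YAML destination.
#' @export
writeScene <- function(scene, path) {
  x <- list(shape = as.integer(scene@shape),
            vessels = lapply(scene@vessels, function(v) {
              v$centerline <- lapply(seq_len(nrow(v$centerline)),
                                     function(i) as.numeric(v$centerline[i, ]))
              v
            }),
            speckle = scene@speckle,
            background_jitter_sd = scene@backgroundJitterSd,
            n_frames = scene@nFrames, seed = scene@seed)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeScene
#' @export
readScene <- function(path) {
  x <- yaml::read_yaml(path)
  vessels <- lapply(x$vessels, function(v) {
    v$centerline <- do.call(rbind, v$centerline)
    v
  })
  SynthScene(shape = x$shape, vessels = vessels, speckle = x$speckle,
             backgroundJitterSd = x$background_jitter_sd,
             nFrames = x$n_frames, seed = x$seed)
}
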