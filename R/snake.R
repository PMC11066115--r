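## Semi-automatic CAM-vessel segmentation: a classical parametric active
## contour (snake). The contour minimizes internal energy (elasticity
## alpha on the first derivative, rigidity beta on the second) plus an
## external edge energy, the negative gradient magnitude of the
## Gaussian-smoothed display image. Evolution is the standard
## semi-implicit scheme: the internal-energy pentadiagonal system is
## solved implicitly (its inverse is precomputed once), the image force
## explicitly, with per-step displacement capped at one pixel.

.bilinear <- function(img, r, c) {
  M <- nrow(img); N <- ncol(img)
  r <- pmin(pmax(r, 1), M); c <- pmin(pmax(c, 1), N)
  r0 <- pmin(floor(r), M - 1L); c0 <- pmin(floor(c), N - 1L)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

## central-difference gradient along rows (d/drow) and cols (d/dcol),
## one-sided at the borders
.gradient <- function(img) {
  M <- nrow(img); N <- ncol(img)
  gr <- img; gc <- img
  gr[2:(M - 1), ] <- (img[3:M, ] - img[1:(M - 2), ]) / 2
  gr[1, ] <- img[2, ] - img[1, ]; gr[M, ] <- img[M, ] - img[M - 1, ]
  gc[, 2:(N - 1)] <- (img[, 3:N] - img[, 1:(N - 2)]) / 2
  gc[, 1] <- img[, 2] - img[, 1]; gc[, N] <- img[, N] - img[, N - 1]
  list(gr = gr, gc = gc)
}

## outer contour of the largest connected component of a mask, as a
## closed (row, col) polyline in pixel coordinates
.maskOuterContour <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) == 0) stop("empty ROI mask")
  sizes <- tabulate(lab[lab > 0])
  comp <- (lab == which.max(sizes)) * 1
  oc <- EBImage::ocontour(EBImage::Image(comp))[[1]]
  cbind(oc[, 1] + 1, oc[, 2] + 1)  # 0-based -> 1-based (row, col)
}

## resample a closed polyline to n points, uniformly by arc length
.resampleClosed <- function(curve, n) {
  cv <- rbind(curve, curve[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(cv)^2))
  s <- c(0, cumsum(seg))
  keep <- c(TRUE, seg > 0)
  cv <- cv[keep, , drop = FALSE]; s <- s[keep]
  tout <- seq(0, s[length(s)], length.out = n + 1L)[-(n + 1L)]
  cbind(approx(s, cv[, 1], xout = tout)$y,
        approx(s, cv[, 2], xout = tout)$y)
}

## cyclic pentadiagonal internal-energy matrix and its regularized inverse
.snakeSystemInverse <- function(n, alpha, beta, gamma) {
  eye <- diag(n)
  rot <- function(k) eye[(seq_len(n) - 1 + k) %% n + 1, ]
  d2 <- rot(1) + rot(-1) - 2 * eye
  d4 <- rot(2) + rot(-2) - 4 * rot(1) - 4 * rot(-1) + 6 * eye
  solve(-alpha * d2 + beta * d4 + gamma * eye)
}

#' Segment a CAM vessel with an active contour seeded by a rough mask
#'
#' The initial contour is the outer contour of the largest connected
#' component of the ROI mask, resampled to \code{nPoints}. It evolves
#' under internal elasticity/rigidity and an external force pulling it
#' onto edges of the Gaussian-smoothed display image (gradient of the
#' gradient-magnitude map, sampled bilinearly). Iteration stops when the
#' mean point displacement in one step drops below \code{tol}, or at
#' \code{maxIter}; non-convergence is reported on the result, not raised.
#'
#' @param display the enhanced angiogram display image, values in [0, 1].
#' @param roi a \linkS4class{RoiMask} overlapping the image.
#' @param params a \linkS4class{SnakeParams} object.
#' @return a \linkS4class{VesselBoundary} with \code{source = "snake"} and
#'   the \code{converged} flag set.
#' @export
snakeSegment <- function(display, roi, params = SnakeParams()) {
  stopifnot(is(roi, "RoiMask"), is(params, "SnakeParams"))
  mask <- maskImage(roi)
  if (!identical(dim(mask), dim(display)))
    stop("ROI mask shape does not match the image")
  validObject(params)

  img <- display
  if (params@sigma > 0) img <- EBImage::gblur(img, sigma = params@sigma)
  g <- .gradient(img)
  edge <- sqrt(g$gr^2 + g$gc^2)
  if (max(edge) > 0) edge <- edge / max(edge)  # contrast-invariant
  f <- .gradient(edge)  # external force = grad |grad img|
  ## scale the force so its maximum is 2 * gamma: strong enough to trap
  ## the contour at edges, weak enough that near-equilibrium steps
  ## contract and the displacement test can fire
  fmax <- max(sqrt(f$gr^2 + f$gc^2))
  if (fmax > 0) {
    sc <- 2 * params@gamma / fmax
    f$gr <- f$gr * sc
    f$gc <- f$gc * sc
  }

  x <- .resampleClosed(.maskOuterContour(mask), params@nPoints)
  inv <- .snakeSystemInverse(params@nPoints, params@alpha, params@beta,
                             params@gamma)
  gamma <- params@gamma
  maxMove <- 1.0
  converged <- FALSE
  for (it in seq_len(params@maxIter)) {
    fr <- .bilinear(f$gr, x[, 1], x[, 2])
    fc <- .bilinear(f$gc, x[, 1], x[, 2])
    xn <- cbind(inv %*% (gamma * x[, 1] + fr),
                inv %*% (gamma * x[, 2] + fc))
    step <- maxMove * tanh(xn - x)
    x <- x + step
    if (mean(sqrt(rowSums(step^2))) < params@tol) {
      converged <- TRUE
      break
    }
  }
  new("VesselBoundary", curve = unname(x), source = "snake",
      converged = converged)
}
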