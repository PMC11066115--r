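## Manual annotation: interpolating splines through annotated points.
## Boundaries use a periodic cubic spline (closed), microvessel curves a
## natural cubic spline (open); both pass through every knot exactly,
## which is the point of click-based annotation.

.collapseDuplicates <- function(pts, closed) {
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-12)
  if (closed && nrow(pts) > 1 &&
      sum(abs(pts[nrow(pts), ] - pts[1, ])) <= 1e-12)
    keep[nrow(pts)] <- FALSE
  if (!all(keep)) {
    warning("collapsed ", sum(!keep), " duplicate consecutive point(s)")
    pts <- pts[keep, , drop = FALSE]
  }
  pts
}

#' Interpolate a closed vessel boundary through annotated points
#'
#' Fits a periodic cubic interpolating spline through the points in click
#' order (parameterized by point index) and resamples it uniformly in
#' parameter. Every annotated point is reproduced exactly; the returned
#' boundary has at least 8 samples (\code{samplesPerSegment} is raised if
#' needed, keeping the knots on the sample grid).
#'
#' @param ann a closed \linkS4class{PointAnnotation} with >= 3 points.
#' @param samplesPerSegment samples per knot-to-knot segment (>= 1).
#' @return a \linkS4class{VesselBoundary} with \code{source = "manual"}.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 9)[-9]
#' ann <- PointAnnotation(cbind(50 + 20 * sin(th), 50 + 20 * cos(th)),
#'                        closed = TRUE)
#' b <- interpolateBoundary(ann, 10)
#' @export
interpolateBoundary <- function(ann, samplesPerSegment = 10L) {
  stopifnot(is(ann, "PointAnnotation"))
  if (!isClosed(ann))
    stop("interpolateBoundary needs a closed annotation")
  pts <- .collapseDuplicates(annotationPoints(ann), closed = TRUE)
  k <- nrow(pts)
  if (k < 3L) stop("a closed boundary needs >= 3 distinct points")
  sps <- max(as.integer(samplesPerSegment), 1L)
  sps <- max(sps, ceiling(8 / k))
  ## periodic spline needs y[1] == y[n]: close the knot sequence
  par <- 0:k
  rr <- c(pts[, 1], pts[1, 1])
  cc <- c(pts[, 2], pts[1, 2])
  tout <- seq(0, k, length.out = k * sps + 1L)[-(k * sps + 1L)]
  curve <- cbind(
    spline(par, rr, method = "periodic", xout = tout)$y,
    spline(par, cc, method = "periodic", xout = tout)$y)
  new("VesselBoundary", curve = curve, source = "manual", converged = TRUE)
}

#' Interpolate an open microvessel curve through annotated points
#'
#' Natural cubic interpolating spline through the points in order; with
#' exactly two points this is the straight segment between them. Knots
#' are reproduced exactly.
#'
#' @param ann an open \linkS4class{PointAnnotation} with >= 2 points.
#' @param samplesPerSegment samples per knot-to-knot segment (>= 1).
#' @return a \code{K x 2} (row, col) polyline matrix.
#' @export
interpolateCurve <- function(ann, samplesPerSegment = 10L) {
  stopifnot(is(ann, "PointAnnotation"))
  if (isClosed(ann))
    stop("interpolateCurve needs an open annotation")
  pts <- .collapseDuplicates(annotationPoints(ann), closed = FALSE)
  k <- nrow(pts)
  if (k < 2L) stop("an open curve needs >= 2 distinct points")
  sps <- max(as.integer(samplesPerSegment), 1L)
  par <- seq_len(k) - 1
  tout <- seq(0, k - 1, length.out = (k - 1) * sps + 1L)
  cbind(spline(par, pts[, 1], method = "natural", xout = tout)$y,
        spline(par, pts[, 2], method = "natural", xout = tout)$y)
}
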