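#' @import methods
#' @importFrom stats spline rnorm runif rpois approx quantile
#' @importFrom grDevices png dev.off
#' @importFrom utils write.csv packageVersion
NULL

## Central containers. Frames are plain numeric matrices (M rows x N cols,
## row 1 at the top); continuous (row, col) coordinates place pixel centers
## at integers, 1-based, consistently across every module.

#' CineLoop: an ordered stack of co-registered grayscale frames
#'
#' Container for a B-mode ultrasound cine loop: \code{T} frames of identical
#' size stored as an \code{M x N x T} numeric array, in acquisition order.
#' Frame order matters: the virtual angiography differences adjacent frames.
#'
#' @slot frames numeric array, \code{M x N x T}, finite and nonnegative.
#' @slot pixelSizeMm isotropic pixel size in mm (\code{NA} when unknown).
#' @slot frameRateHz acquisition frame rate (\code{NA} when unknown).
#' @export
setClass("CineLoop",
  representation(frames = "array", pixelSizeMm = "numeric",
                 frameRateHz = "numeric"),
  prototype(pixelSizeMm = NA_real_, frameRateHz = NA_real_))

setValidity("CineLoop", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L)
    return("'frames' must be an M x N x T array")
  if (d[3] < 2L)
    return("differencing requires T >= 2")
  if (!all(is.finite(object@frames)))
    return("frame intensities must be finite")
  if (min(object@frames) < 0)
    return("frame intensities must be nonnegative")
  TRUE
})

#' CineLoop constructor
#'
#' @param frames an \code{M x N x T} numeric array, or a list of equally
#'   sized matrices (stacked in list order).
#' @param pixelSizeMm,frameRateHz optional acquisition metadata.
#' @return a validated \linkS4class{CineLoop}.
#' @examples
#' cl <- CineLoop(array(runif(16 * 16 * 4), c(16, 16, 4)))
#' dim(frames(cl))
#' @export
CineLoop <- function(frames, pixelSizeMm = NA_real_, frameRateHz = NA_real_) {
  if (is.list(frames)) {
    shp <- lapply(frames, dim)
    if (length(frames) >= 2L &&
        !all(vapply(shp, identical, logical(1), shp[[1]])))
      stop("all frames must share an identical (M, N) shape")
    frames <- array(unlist(frames),
                    c(dim(frames[[1]]), length(frames)))
  }
  new("CineLoop", frames = frames,
      pixelSizeMm = as.numeric(pixelSizeMm),
      frameRateHz = as.numeric(frameRateHz))
}

#' RoiMask: a rough binary annotation mask
#'
#' @slot mask logical matrix, \code{TRUE} inside the rough annotation.
#' @slot label free-text label, conventionally \code{"cam_vessel"} or
#'   \code{"microvessel"}; downstream commands route on it.
#' @export
setClass("RoiMask",
  representation(mask = "matrix", label = "character"),
  prototype(label = "cam_vessel"))

setValidity("RoiMask", function(object) {
  if (!is.logical(object@mask))
    return("'mask' must be a logical matrix")
  if (!any(object@mask))
    return("mask must contain at least one TRUE pixel")
  TRUE
})

#' RoiMask constructor
#' @param mask logical (or 0/1 numeric) matrix.
#' @param label annotation label.
#' @export
RoiMask <- function(mask, label = "cam_vessel") {
  storage.mode(mask) <- "logical"
  new("RoiMask", mask = mask, label = as.character(label))
}

#' PointAnnotation: ordered click points seeding an interpolated curve
#'
#' Closed annotations (vessel boundaries) need at least 3 points, open
#' ones (microvessel curves) at least 2. Coordinates are continuous
#' 1-based (row, col) pairs.
#'
#' @slot points numeric \code{K x 2} matrix of (row, col) coordinates.
#' @slot closed \code{TRUE} for a closed boundary.
#' @slot label free-text label.
#' @export
setClass("PointAnnotation",
  representation(points = "matrix", closed = "logical", label = "character"),
  prototype(closed = FALSE, label = ""))

setValidity("PointAnnotation", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 2L)
    return("'points' must be a numeric K x 2 matrix of (row, col)")
  if (!all(is.finite(p)))
    return("annotation points must be finite")
  k <- nrow(p)
  if (isTRUE(object@closed) && k < 3L)
    return("a closed boundary needs >= 3 points")
  if (!isTRUE(object@closed) && k < 2L)
    return("an open curve needs >= 2 points")
  TRUE
})

#' PointAnnotation constructor
#' @param points numeric \code{K x 2} matrix (row, col).
#' @param closed logical; closed boundary vs open curve.
#' @param label annotation label.
#' @export
PointAnnotation <- function(points, closed = FALSE, label = "") {
  points <- as.matrix(points)
  dimnames(points) <- NULL
  new("PointAnnotation", points = points, closed = isTRUE(closed),
      label = as.character(label))
}

#' DifferenceStack: the absolute temporal finite differences of a loop
#'
#' Element \code{t} of the stack is \code{|I[t+1] - I[t]|}; a loop of
#' \code{T} frames yields exactly \code{T - 1} difference images.
#'
#' @slot diffs numeric array \code{M x N x (T-1)}, nonnegative.
#' @export
setClass("DifferenceStack", representation(diffs = "array"))

setValidity("DifferenceStack", function(object) {
  if (length(dim(object@diffs)) != 3L)
    return("'diffs' must be an M x N x (T-1) array")
  if (min(object@diffs) < 0)
    return("absolute differences must be nonnegative")
  TRUE
})

#' Angiogram: accumulated blood-flow evidence
#'
#' The virtual angiogram is the element-wise mean of the absolute temporal
#' finite differences of a cine loop. Static pixels contribute exactly
#' zero, so the map highlights moving speckle (blood) against the frozen
#' background.
#'
#' @slot image nonnegative numeric matrix \code{M x N}.
#' @slot tUsed number of difference images accumulated so far.
#' @slot displayRange numeric(2), the (lo, hi) used by the last display
#'   rendering (\code{NA} until \code{\link{enhanceForDisplay}} runs).
#' @export
setClass("Angiogram",
  representation(image = "matrix", tUsed = "integer",
                 displayRange = "numeric"),
  prototype(tUsed = 0L, displayRange = c(NA_real_, NA_real_)))

setValidity("Angiogram", function(object) {
  if (!is.numeric(object@image))
    return("'image' must be a numeric matrix")
  if (object@tUsed < 0L)
    return("'tUsed' must be >= 0")
  if (object@tUsed > 0L && min(object@image) < 0)
    return("angiogram values must be nonnegative")
  TRUE
})

#' Angiogram constructor
#' @param image nonnegative numeric matrix.
#' @param tUsed count of accumulated differences.
#' @param displayRange optional numeric(2) display range.
#' @export
Angiogram <- function(image, tUsed = 0L,
                      displayRange = c(NA_real_, NA_real_)) {
  new("Angiogram", image = image, tUsed = as.integer(tUsed),
      displayRange = as.numeric(displayRange))
}

#' VesselBoundary: closed smooth boundary of a large CAM vessel
#'
#' @slot curve numeric \code{K x 2} matrix of (row, col) points tracing the
#'   closed boundary (first point not repeated at the end).
#' @slot source \code{"manual"} (interpolated from clicks) or
#'   \code{"snake"} (active contour).
#' @slot converged for snake output, whether the evolution met the
#'   displacement tolerance before the iteration cap.
#' @export
setClass("VesselBoundary",
  representation(curve = "matrix", source = "character",
                 converged = "logical"),
  prototype(source = "manual", converged = TRUE))

setValidity("VesselBoundary", function(object) {
  if (!is.numeric(object@curve) || ncol(object@curve) != 2L)
    return("'curve' must be a numeric K x 2 matrix")
  if (nrow(object@curve) < 8L)
    return("boundary must have >= 8 points after resampling")
  if (!object@source %in% c("manual", "snake"))
    return("source must be 'manual' or 'snake'")
  TRUE
})

#' CenterlineSet: open polyline microvessel centerlines
#'
#' @slot curves list of numeric \code{K x 2} matrices, each an ordered open
#'   polyline of (row, col) points.
#' @slot source \code{"manual"} or \code{"skeleton"}.
#' @slot junctions numeric \code{J x 2} matrix of junction-node (row, col)
#'   positions (merged adjacent junction pixels); empty for manual curves.
#' @export
setClass("CenterlineSet",
  representation(curves = "list", source = "character",
                 junctions = "matrix"),
  prototype(curves = list(), source = "manual",
            junctions = matrix(numeric(0), 0, 2)))

setValidity("CenterlineSet", function(object) {
  for (cv in object@curves) {
    if (!is.matrix(cv) || ncol(cv) != 2L || nrow(cv) < 2L)
      return("each centerline must be a K x 2 matrix with K >= 2")
  }
  if (!object@source %in% c("manual", "skeleton"))
    return("source must be 'manual' or 'skeleton'")
  TRUE
})

#' CenterlineSet constructor
#' @param curves list of \code{K x 2} (row, col) matrices.
#' @param source \code{"manual"} or \code{"skeleton"}.
#' @param junctions optional \code{J x 2} matrix of junction nodes.
#' @export
CenterlineSet <- function(curves, source = "manual",
                          junctions = matrix(numeric(0), 0, 2)) {
  curves <- lapply(curves, function(cv) {
    cv <- as.matrix(cv); dimnames(cv) <- NULL; cv
  })
  junctions <- as.matrix(junctions)
  new("CenterlineSet", curves = curves, source = source,
      junctions = junctions)
}

#' SnakeParams: active-contour tuning parameters
#'
#' Defaults were calibrated on the bright-disk phantom and are fully
#' exposed: \code{nPoints} contour samples, elasticity \code{alpha},
#' rigidity \code{beta}, Gaussian pre-smoothing \code{sigma} (px),
#' implicit-Euler step \code{gamma}, iteration cap \code{maxIter} and
#' convergence tolerance \code{tol} (mean point displacement per
#' iteration, px).
#'
#' @slot nPoints,alpha,beta,sigma,gamma,maxIter,tol numeric scalars.
#' @export
setClass("SnakeParams",
  representation(nPoints = "integer", alpha = "numeric", beta = "numeric",
                 sigma = "numeric", gamma = "numeric", maxIter = "integer",
                 tol = "numeric"))

setValidity("SnakeParams", function(object) {
  if (object@nPoints < 8L) return("nPoints must be >= 8")
  if (object@alpha < 0 || object@beta < 0)
    return("alpha and beta must be nonnegative")
  if (object@gamma <= 0) return("gamma must be > 0")
  if (object@maxIter < 1L) return("maxIter must be >= 1")
  if (object@tol <= 0) return("tol must be > 0")
  TRUE
})

#' SnakeParams constructor
#' @param nPoints number of contour samples.
#' @param alpha elasticity (tension) weight.
#' @param beta rigidity (bending) weight.
#' @param sigma Gaussian smoothing of the display image, in px.
#' @param gamma implicit-Euler time step.
#' @param maxIter iteration cap.
#' @param tol convergence tolerance: mean displacement per iteration, px.
#' @export
SnakeParams <- function(nPoints = 200L, alpha = 0.015, beta = 10,
                        sigma = 2, gamma = 0.001, maxIter = 2500L,
                        tol = 0.1) {
  new("SnakeParams", nPoints = as.integer(nPoints), alpha = alpha,
      beta = beta, sigma = sigma, gamma = gamma,
      maxIter = as.integer(maxIter), tol = tol)
}

#' SynthScene: parametric ground-truth description for the simulator
#'
#' Describes a synthetic B-mode scene: a frozen speckled background plus
#' vessel tubes carrying bright scatterers that advect along the
#' centerline, emulating moving erythrocytes. The same scene doubles as
#' analytic ground truth for recovery tests.
#'
#' @slot shape integer(2), (M, N).
#' @slot vessels list of vessel descriptions; each has \code{centerline}
#'   (\code{K x 2} polyline), \code{half_width_px}, \code{flow_px_per_frame}
#'   and \code{scatterer_density} (scatterers per 100 px^2).
#' @slot speckle list with \code{mean}, \code{rayleigh_sigma},
#'   \code{blur_sigma_px}.
#' @slot backgroundJitterSd sd of per-frame additive Gaussian jitter.
#' @slot nFrames number of frames to render (>= 2).
#' @slot seed RNG seed; identical seeds give bit-identical loops.
#' @export
setClass("SynthScene",
  representation(shape = "integer", vessels = "list", speckle = "list",
                 backgroundJitterSd = "numeric", nFrames = "integer",
                 seed = "integer"))

setValidity("SynthScene", function(object) {
  if (length(object@shape) != 2L || any(object@shape < 8L))
    return("'shape' must be (M, N) with both >= 8")
  if (object@nFrames < 2L)
    return("nFrames must be >= 2")
  for (v in object@vessels) {
    need <- c("centerline", "half_width_px", "flow_px_per_frame",
              "scatterer_density")
    if (!all(need %in% names(v)))
      return(paste("each vessel needs fields:", paste(need, collapse = ", ")))
    if (v$half_width_px <= 0) return("half_width_px must be > 0")
    if (v$flow_px_per_frame < 0) return("flow_px_per_frame must be >= 0")
    cl <- v$centerline
    w <- v$half_width_px
    if (min(cl[, 1]) - w < 1 || max(cl[, 1]) + w > object@shape[1] ||
        min(cl[, 2]) - w < 1 || max(cl[, 2]) + w > object@shape[2])
      return("vessel tube extends outside the frame")
  }
  sp <- object@speckle
  if (!all(c("mean", "rayleigh_sigma", "blur_sigma_px") %in% names(sp)))
    return("speckle needs fields mean, rayleigh_sigma, blur_sigma_px")
  if (sp$mean <= 0 || sp$mean >= 1) return("speckle mean must be in (0,1)")
  if (object@backgroundJitterSd < 0)
    return("backgroundJitterSd must be >= 0")
  TRUE
})

#' SynthScene constructor
#' @param shape (M, N) frame size.
#' @param vessels list of vessel descriptions (see class docs).
#' @param speckle list(mean, rayleigh_sigma, blur_sigma_px).
#' @param backgroundJitterSd per-frame Gaussian jitter sd.
#' @param nFrames number of frames.
#' @param seed RNG seed.
#' @export
SynthScene <- function(shape, vessels = list(),
                       speckle = list(mean = 0.25, rayleigh_sigma = 0.06,
                                      blur_sigma_px = 1),
                       backgroundJitterSd = 0, nFrames = 64L, seed = 1L) {
  vessels <- lapply(vessels, function(v) {
    v$centerline <- as.matrix(v$centerline)
    dimnames(v$centerline) <- NULL
    v
  })
  new("SynthScene", shape = as.integer(shape), vessels = vessels,
      speckle = speckle, backgroundJitterSd = backgroundJitterSd,
      nFrames = as.integer(nFrames), seed = as.integer(seed))
}
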