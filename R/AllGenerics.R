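#' Accessors for camangio containers
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x a camangio object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "CineLoop", function(x) x@frames)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "CineLoop", function(x) dim(x@frames)[3])

#' @rdname accessors
#' @export
setGeneric("frameShape", function(x) standardGeneric("frameShape"))
#' @rdname accessors
#' @export
setMethod("frameShape", "CineLoop", function(x) dim(x@frames)[1:2])
#' @rdname accessors
#' @export
setMethod("frameShape", "RoiMask", function(x) dim(x@mask))
#' @rdname accessors
#' @export
setMethod("frameShape", "Angiogram", function(x) dim(x@image))

#' @rdname accessors
#' @export
setGeneric("pixelSizeMm", function(x) standardGeneric("pixelSizeMm"))
#' @rdname accessors
#' @export
setMethod("pixelSizeMm", "CineLoop", function(x) x@pixelSizeMm)

#' @rdname accessors
#' @export
setGeneric("maskImage", function(x) standardGeneric("maskImage"))
#' @rdname accessors
#' @export
setMethod("maskImage", "RoiMask", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("annotationPoints", function(x) standardGeneric("annotationPoints"))
#' @rdname accessors
#' @export
setMethod("annotationPoints", "PointAnnotation", function(x) x@points)

#' @rdname accessors
#' @export
setGeneric("isClosed", function(x) standardGeneric("isClosed"))
#' @rdname accessors
#' @export
setMethod("isClosed", "PointAnnotation", function(x) x@closed)

#' @rdname accessors
#' @export
setGeneric("annotationLabel", function(x) standardGeneric("annotationLabel"))
#' @rdname accessors
#' @export
setMethod("annotationLabel", "PointAnnotation", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("annotationLabel", "RoiMask", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("diffImages", function(x) standardGeneric("diffImages"))
#' @rdname accessors
#' @export
setMethod("diffImages", "DifferenceStack", function(x) x@diffs)

#' @rdname accessors
#' @export
setGeneric("nDiffs", function(x) standardGeneric("nDiffs"))
#' @rdname accessors
#' @export
setMethod("nDiffs", "DifferenceStack", function(x) dim(x@diffs)[3])

#' @rdname accessors
#' @export
setGeneric("angioImage", function(x) standardGeneric("angioImage"))
#' @rdname accessors
#' @export
setMethod("angioImage", "Angiogram", function(x) x@image)

#' @rdname accessors
#' @export
setGeneric("tUsed", function(x) standardGeneric("tUsed"))
#' @rdname accessors
#' @export
setMethod("tUsed", "Angiogram", function(x) x@tUsed)

#' @rdname accessors
#' @export
setGeneric("displayRange", function(x) standardGeneric("displayRange"))
#' @rdname accessors
#' @export
setMethod("displayRange", "Angiogram", function(x) x@displayRange)

#' @rdname accessors
#' @export
setGeneric("boundaryCurve", function(x) standardGeneric("boundaryCurve"))
#' @rdname accessors
#' @export
setMethod("boundaryCurve", "VesselBoundary", function(x) x@curve)

#' @rdname accessors
#' @export
setGeneric("curveSource", function(x) standardGeneric("curveSource"))
#' @rdname accessors
#' @export
setMethod("curveSource", "VesselBoundary", function(x) x@source)
#' @rdname accessors
#' @export
setMethod("curveSource", "CenterlineSet", function(x) x@source)

#' @rdname accessors
#' @export
setGeneric("hasConverged", function(x) standardGeneric("hasConverged"))
#' @rdname accessors
#' @export
setMethod("hasConverged", "VesselBoundary", function(x) x@converged)

#' @rdname accessors
#' @export
setGeneric("centerlines", function(x) standardGeneric("centerlines"))
#' @rdname accessors
#' @export
setMethod("centerlines", "CenterlineSet", function(x) x@curves)

#' @rdname accessors
#' @export
setGeneric("sceneShape", function(x) standardGeneric("sceneShape"))
#' @rdname accessors
#' @export
setMethod("sceneShape", "SynthScene", function(x) x@shape)

#' @rdname accessors
#' @export
setGeneric("sceneVessels", function(x) standardGeneric("sceneVessels"))
#' @rdname accessors
#' @export
setMethod("sceneVessels", "SynthScene", function(x) x@vessels)

setMethod("show", "CineLoop", function(object) {
  d <- dim(object@frames)
  cat(sprintf("CineLoop: %d frames of %d x %d, range [%.4g, %.4g]\n",
              d[3], d[1], d[2], min(object@frames), max(object@frames)))
  if (!is.na(object@pixelSizeMm))
    cat(sprintf("  pixel size: %.4g mm\n", object@pixelSizeMm))
  if (!is.na(object@frameRateHz))
    cat(sprintf("  frame rate: %.4g Hz\n", object@frameRateHz))
})

setMethod("show", "Angiogram", function(object) {
  d <- dim(object@image)
  cat(sprintf(
    "Angiogram: %d x %d, %d difference(s) accumulated, max %.4g\n",
    d[1], d[2], object@tUsed, max(object@image)))
})

setMethod("show", "RoiMask", function(object) {
  cat(sprintf("RoiMask '%s': %d x %d, %d TRUE pixel(s)\n",
              object@label, nrow(object@mask), ncol(object@mask),
              sum(object@mask)))
})

setMethod("show", "PointAnnotation", function(object) {
  cat(sprintf("PointAnnotation '%s': %d point(s), %s\n", object@label,
              nrow(object@points),
              if (object@closed) "closed" else "open"))
})

setMethod("show", "VesselBoundary", function(object) {
  cat(sprintf("VesselBoundary (%s): %d points, area %.1f px^2%s\n",
              object@source, nrow(object@curve), polygonArea(object@curve),
              if (object@source == "snake" && !object@converged)
                ", NOT converged" else ""))
})

setMethod("show", "CenterlineSet", function(object) {
  cat(sprintf("CenterlineSet (%s): %d curve(s), total length %.1f px\n",
              object@source, length(object@curves),
              sum(vapply(object@curves, polylineLength, numeric(1)))))
})

setMethod("show", "SynthScene", function(object) {
  cat(sprintf(
    "SynthScene: %d x %d, %d frame(s), %d vessel(s), jitter sd %.3g, seed %d\n",
    object@shape[1], object@shape[2], object@nFrames,
    length(object@vessels), object@backgroundJitterSd, object@seed))
})
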