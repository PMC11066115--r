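## Vascular network quantification: per-curve and total centerline
## length (Euclidean polyline length, so diagonal steps count sqrt(2)),
## branch-point count (merged skeleton junction nodes), and local
## diameter from the Euclidean distance transform of the vessel mask.

#' Euclidean length of a polyline
#' @param curve numeric \code{K x 2} matrix of (row, col) points.
#' @return total length in px.
#' @export
polylineLength <- function(curve) {
  if (nrow(curve) < 2L) return(0)
  sum(sqrt(rowSums(diff(curve)^2)))
}

#' Signed-area magnitude of a closed polygon (shoelace)
#' @param curve numeric \code{K x 2} matrix tracing the polygon (first
#'   point not repeated).
#' @return enclosed area in px^2.
#' @export
polygonArea <- function(curve) {
  r <- curve[, 1]; c <- curve[, 2]
  r2 <- c(r[-1], r[1]); c2 <- c(c[-1], c[1])
  abs(sum(c * r2 - c2 * r)) / 2
}

#' VesselMetrics: summary quantities of an annotated vascular network
#'
#' @slot totalLengthPx sum of per-curve Euclidean lengths.
#' @slot nBranchPoints number of merged skeleton junction nodes.
#' @slot nCurves number of centerline curves.
#' @slot meanDiameterPx mean local diameter over all curves (0 without a
#'   mask).
#' @slot perCurve data.frame with \code{length_px} and
#'   \code{mean_diameter_px} per curve (plus \code{_mm} twins when a
#'   pixel size is known).
#' @slot pixelSizeMm pixel size used for mm mirroring (\code{NA} if none).
#' @slot hasMask whether diameters were measurable.
#' @export
setClass("VesselMetrics",
  representation(totalLengthPx = "numeric", nBranchPoints = "integer",
                 nCurves = "integer", meanDiameterPx = "numeric",
                 perCurve = "data.frame", pixelSizeMm = "numeric",
                 hasMask = "logical"))

setValidity("VesselMetrics", function(object) {
  if (object@totalLengthPx < 0 || object@meanDiameterPx < 0 ||
      object@nBranchPoints < 0L || object@nCurves < 0L)
    return("all metrics must be nonnegative")
  if (nrow(object@perCurve) &&
      abs(sum(object@perCurve$length_px) - object@totalLengthPx) > 1e-9)
    return("totalLengthPx must equal the sum of per-curve lengths")
  TRUE
})

#' @rdname VesselMetrics-class
#' @param x,name slot access by name (list-style convenience).
#' @export
setMethod("$", "VesselMetrics", function(x, name) slot(x, name))

setMethod("show", "VesselMetrics", function(object) {
  cat(sprintf(
    "VesselMetrics: %d curve(s), total length %.1f px, %d branch point(s)",
    object@nCurves, object@totalLengthPx, object@nBranchPoints))
  if (object@hasMask)
    cat(sprintf(", mean diameter %.2f px", object@meanDiameterPx))
  cat("\n")
})

#' Quantify an annotated vascular network
#'
#' Curve length is the Euclidean polyline length. Branch points are the
#' merged junction nodes carried by a skeleton-derived
#' \linkS4class{CenterlineSet}. Local diameter at a centerline point is
#' twice the Euclidean distance-transform value of the vessel mask at
#' that point; per-curve diameters average along the curve. Without a
#' mask, diameters are reported as 0 and \code{hasMask} is \code{FALSE}.
#'
#' @param centerlines a \linkS4class{CenterlineSet}.
#' @param mask optional \linkS4class{RoiMask} (or logical matrix) of the
#'   vessel lumen, for diameter estimation.
#' @param pixelSizeMm optional pixel size; mm fields are mirrored when
#'   given.
#' @return a \linkS4class{VesselMetrics}.
#' @export
measureVessels <- function(centerlines, mask = NULL, pixelSizeMm = NULL) {
  stopifnot(is(centerlines, "CenterlineSet"))
  curves <- centerlines(centerlines)
  hasMask <- !is.null(mask)
  dm <- NULL
  if (hasMask) {
    m <- if (is(mask, "RoiMask")) maskImage(mask) else mask != 0
    dm <- EBImage::distmap(matrix(as.numeric(m), nrow(m), ncol(m)))
  }
  perCurve <- data.frame(length_px = numeric(0),
                         mean_diameter_px = numeric(0))
  for (cv in curves) {
    len <- polylineLength(cv)
    dia <- 0
    if (hasMask && nrow(cv)) {
      ri <- pmin(pmax(round(cv[, 1]), 1), nrow(dm))
      ci <- pmin(pmax(round(cv[, 2]), 1), ncol(dm))
      dia <- mean(2 * dm[cbind(ri, ci)])
    }
    perCurve <- rbind(perCurve,
                      data.frame(length_px = len, mean_diameter_px = dia))
  }
  total <- sum(perCurve$length_px)
  meanDia <- if (hasMask && nrow(perCurve))
    mean(perCurve$mean_diameter_px) else 0
  px <- if (is.null(pixelSizeMm)) NA_real_ else as.numeric(pixelSizeMm)
  if (!is.na(px) && nrow(perCurve)) {
    perCurve$length_mm <- perCurve$length_px * px
    perCurve$mean_diameter_mm <- perCurve$mean_diameter_px * px
  }
  new("VesselMetrics", totalLengthPx = total,
      nBranchPoints = nrow(centerlines@junctions),
      nCurves = length(curves), meanDiameterPx = meanDia,
      perCurve = perCurve, pixelSizeMm = px, hasMask = hasMask)
}

#' Export metrics as a table (one row per curve plus a summary row)
#'
#' @param metrics a \linkS4class{VesselMetrics}.
#' @return data.frame ready for \code{write.csv}.
#' @export
metricsTable <- function(metrics) {
  pc <- metrics@perCurve
  if (!nrow(pc))
    pc <- data.frame(length_px = numeric(0), mean_diameter_px = numeric(0))
  pc <- cbind(curve = seq_len(nrow(pc)), pc)
  summ <- data.frame(curve = NA_integer_,
                     length_px = metrics@totalLengthPx,
                     mean_diameter_px = metrics@meanDiameterPx)
  if ("length_mm" %in% names(pc)) {
    summ$length_mm <- metrics@totalLengthPx * metrics@pixelSizeMm
    summ$mean_diameter_mm <- metrics@meanDiameterPx * metrics@pixelSizeMm
  }
  out <- rbind(pc, summ[names(pc)])
  out$kind <- c(rep("curve", nrow(pc)), "summary")
  out$n_branch_points <- c(rep(NA_integer_, nrow(pc)),
                           metrics@nBranchPoints)
  out
}
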