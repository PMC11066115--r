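## Publication-style overlays: grayscale display base with large CAM
## vessels stroked in red and microvessel centerlines in cyan, plus an
## optional 1 mm scale bar when the pixel size is known.

## rasterize a polyline into a logical stroke mask of given width
.strokeMask <- function(shape, curve, widthPx = 2, closed = FALSE) {
  M <- shape[1]; N <- shape[2]
  out <- matrix(FALSE, M, N)
  cv <- if (closed) rbind(curve, curve[1, , drop = FALSE]) else curve
  if (nrow(cv) < 2) return(out)
  ## dense sampling along segments
  pts <- list()
  for (i in seq_len(nrow(cv) - 1)) {
    a <- cv[i, ]; b <- cv[i + 1, ]
    n <- max(2L, ceiling(4 * sqrt(sum((b - a)^2))))
    t <- seq(0, 1, length.out = n)
    pts[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  pts <- do.call(rbind, pts)
  rad <- widthPx / 2
  off <- expand.grid(dr = -ceiling(rad):ceiling(rad),
                     dc = -ceiling(rad):ceiling(rad))
  off <- off[off$dr^2 + off$dc^2 <= rad^2 + 1e-9, ]
  for (i in seq_len(nrow(off))) {
    rr <- round(pts[, 1]) + off$dr[i]
    cc <- round(pts[, 2]) + off$dc[i]
    ok <- rr >= 1 & rr <= M & cc >= 1 & cc <= N
    out[cbind(rr[ok], cc[ok])] <- TRUE
  }
  out
}

#' Render an RGB overlay of annotations on the display image
#'
#' CAM-vessel boundaries are stroked in red, microvessel centerlines in
#' cyan (2 px by default). With a known pixel size a white 1 mm scale
#' bar is drawn bottom-right. Without annotations the result is the
#' grayscale base promoted to RGB.
#'
#' @param display grayscale matrix in [0, 1].
#' @param boundaries list of \linkS4class{VesselBoundary} objects.
#' @param centerlineSets list of \linkS4class{CenterlineSet} objects.
#' @param strokePx stroke width in px.
#' @param pixelSizeMm optional pixel size for the scale bar.
#' @return \code{M x N x 3} RGB array in [0, 1].
#' @export
renderOverlay <- function(display, boundaries = list(),
                          centerlineSets = list(), strokePx = 2,
                          pixelSizeMm = NA_real_) {
  M <- nrow(display); N <- ncol(display)
  rgb <- array(display, c(M, N, 3))
  red <- matrix(FALSE, M, N)
  for (b in boundaries)
    red <- red | .strokeMask(c(M, N), boundaryCurve(b), strokePx,
                             closed = TRUE)
  cyan <- matrix(FALSE, M, N)
  for (cs in centerlineSets)
    for (cv in centerlines(cs))
      cyan <- cyan | .strokeMask(c(M, N), cv, strokePx, closed = FALSE)
  r <- rgb[, , 1]; g <- rgb[, , 2]; b2 <- rgb[, , 3]
  r[red] <- 1; g[red] <- 0; b2[red] <- 0
  r[cyan] <- 0; g[cyan] <- 1; b2[cyan] <- 1
  if (!is.na(pixelSizeMm) && pixelSizeMm > 0) {
    barLen <- min(round(1 / pixelSizeMm), N - 10L)
    rows <- (M - 12L):(M - 10L)
    cols <- (N - 8L - barLen + 1L):(N - 8L)
    r[rows, cols] <- 1; g[rows, cols] <- 1; b2[rows, cols] <- 1
  }
  rgb[, , 1] <- r; rgb[, , 2] <- g; rgb[, , 3] <- b2
  rgb
}
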