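## Cine, image and annotation I/O. Lossless multi-frame TIFF is the
## interchange format; everything downstream works on floating point in
## [0, 1]. Matrices are M rows x N cols with row 1 at the top.

.dtypeMax <- function(bits) 2^bits - 1

## round half away from zero (values here are nonnegative)
.roundHalfUp <- function(x) floor(x + 0.5)

.toGray <- function(fr) {
  if (length(dim(fr)) == 3L) {
    ## color plane stack -> channel average
    fr <- apply(fr, c(1, 2), mean)
  }
  fr
}

#' Read a cine loop from a multi-frame TIFF
#'
#' Frames are returned in file order (acquisition order). Color frames are
#' converted to grayscale by channel averaging. With \code{normalize =
#' TRUE}, integer samples are divided by the dtype maximum (255 for 8-bit,
#' 65535 for 16-bit) -- never by a per-file min/max -- so normalization is
#' idempotent and preserves relative intensity across files.
#'
#' @param path a multi-frame TIFF file with at least two frames.
#' @param normalize rescale integer samples to [0, 1] by the dtype maximum.
#' @param pixelSizeMm,frameRateHz optional metadata attached to the loop.
#' @return a \linkS4class{CineLoop}.
#' @export
readCine <- function(path, normalize = TRUE,
                     pixelSizeMm = NA_real_, frameRateHz = NA_real_) {
  if (!file.exists(path))
    stop("cannot read cine file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "avi")
    stop("AVI decoding is not supported; convert '", path,
         "' to a lossless multi-frame TIFF first")
  frs <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                  error = function(e)
                    stop("cannot read cine file: ", path, " (",
                         conditionMessage(e), ")"))
  if (!is.list(frs)) frs <- list(frs)
  if (length(frs) < 2L)
    stop("differencing requires T >= 2 (file has ", length(frs),
         " frame(s)): ", path)
  ## readTIFF always rescales integer samples to [0,1] by the dtype
  ## maximum -- exactly the normalization contract; undo it on request
  mats <- lapply(frs, function(fr) {
    bits <- attr(fr, "bits.per.sample")
    fmt <- attr(fr, "sample.format")
    fr <- .toGray(unclass(fr))
    if (!normalize) {
      isFloat <- !is.null(fmt) && identical(fmt, "float")
      if (!isFloat && !is.null(bits)) fr <- fr * .dtypeMax(bits)
    }
    fr
  })
  shp <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), shp), logical(1))))
    stop("inconsistent frame shapes in cine file: ", path)
  CineLoop(mats, pixelSizeMm = pixelSizeMm, frameRateHz = frameRateHz)
}

#' Write a cine loop to a lossless multi-frame TIFF
#'
#' Intensities must already lie in [0, 1]; they are quantized to the
#' requested bit depth with round-half-away-from-zero, so a write/read
#' round trip through \code{\link{readCine}} is bit-exact at the quantized
#' values.
#'
#' @param loop a \linkS4class{CineLoop} with intensities in [0, 1].
#' @param path destination TIFF path.
#' @param bitDepth 8 or 16.
#' @export
writeCine <- function(loop, path, bitDepth = 16L) {
  stopifnot(is(loop, "CineLoop"))
  fr <- frames(loop)
  if (max(fr) > 1)
    stop("cine intensities must be in [0, 1]; normalize before writing")
  mx <- .dtypeMax(bitDepth)
  mats <- lapply(seq_len(dim(fr)[3]),
                 function(t) .roundHalfUp(fr[, , t] * mx) / mx)
  tiff::writeTIFF(mats, path, bits.per.sample = as.integer(bitDepth),
                  compression = "none")
  invisible(path)
}

#' Write a single grayscale image (PNG or TIFF)
#'
#' Real values in [0, 1] are mapped linearly to the integer range with
#' round-half-away-from-zero (0.5 at 8 bit becomes 128). PNG output is
#' 8-bit; use TIFF for 16-bit.
#'
#' @param image numeric matrix (or M x N x 3 RGB array, PNG/TIFF) in [0, 1].
#' @param path destination; extension selects the format.
#' @param bitDepth 8 or 16.
#' @export
writeImage <- function(image, path, bitDepth = 8L) {
  if (!all(is.finite(image)))
    stop("image values must be finite")
  if (min(image) < 0 || max(image) > 1)
    stop("image values outside [0, 1]; normalize first ",
         "(e.g. with enhanceForDisplay)")
  if (!bitDepth %in% c(8L, 16L))
    stop("bitDepth must be 8 or 16")
  mx <- .dtypeMax(bitDepth)
  q <- .roundHalfUp(image * mx) / mx
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bitDepth != 8L)
      stop("PNG output is 8-bit here; use TIFF for 16-bit")
    png::writePNG(q, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(q, path, bits.per.sample = as.integer(bitDepth),
                    compression = "none")
  } else {
    stop("unsupported image extension '", ext, "' (use png/tif/tiff)")
  }
  invisible(path)
}

#' Read a grayscale image written by \code{\link{writeImage}}
#'
#' @param path PNG or TIFF path.
#' @return numeric matrix in [0, 1] (RGB inputs are channel-averaged).
#' @export
readImageGray <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  .toGray(img)
}

## ---- annotation JSON persistence --------------------------------------

## Run-length encoding of a logical matrix, scanned row-major (row 1 left
## to right first), alternating run counts starting with FALSE.
.maskToRle <- function(mask) {
  v <- as.vector(t(mask))
  r <- rle(v)
  if (r$values[1]) c(0L, r$lengths) else r$lengths
}

.rleToMask <- function(lens, shape) {
  lens <- as.integer(unlist(lens))
  vals <- rep(c(FALSE, TRUE), length.out = length(lens))
  v <- rep(vals, lens)
  if (length(v) != prod(shape))
    stop("RLE length ", length(v), " does not match shape ",
         shape[1], " x ", shape[2])
  matrix(v, nrow = shape[1], byrow = TRUE)
}

.annItem <- function(x) {
  if (is(x, "PointAnnotation")) {
    list(type = "points", closed = isClosed(x),
         points = unname(annotationPoints(x)),
         label = annotationLabel(x))
  } else if (is(x, "RoiMask")) {
    m <- maskImage(x)
    list(type = "mask", shape = dim(m), rle = .maskToRle(m),
         label = annotationLabel(x))
  } else if (is(x, "VesselBoundary")) {
    list(type = "points", closed = TRUE, points = unname(boundaryCurve(x)),
         label = paste0("boundary:", curveSource(x)),
         converged = hasConverged(x))
  } else if (is(x, "CenterlineSet")) {
    ## expanded by the caller; kept for completeness
    stop("write CenterlineSet curves as individual open PointAnnotations")
  } else stop("cannot serialize object of class ", class(x))
}

#' Write annotations to JSON
#'
#' Persists rough masks (run-length encoded), point annotations and
#' derived curves (boundaries as closed point items, centerline sets as
#' one open item per curve) losslessly: points keep full float precision.
#'
#' @param items list of \linkS4class{RoiMask}, \linkS4class{PointAnnotation},
#'   \linkS4class{VesselBoundary} or \linkS4class{CenterlineSet} objects.
#' @param path destination JSON path.
#' @export
writeAnnotations <- function(items, path) {
  flat <- list()
  for (x in items) {
    if (is(x, "CenterlineSet")) {
      src <- curveSource(x)
      for (cv in centerlines(x))
        flat[[length(flat) + 1L]] <-
          list(type = "points", closed = FALSE, points = unname(cv),
               label = paste0("centerline:", src))
    } else flat[[length(flat) + 1L]] <- .annItem(x)
  }
  jsonlite::write_json(list(items = flat), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.jsonFail <- function(where, why) stop("invalid annotation JSON at ",
                                       where, ": ", why)

#' Read annotations from JSON
#'
#' @param path JSON file written by \code{\link{writeAnnotations}} (or
#'   conforming to its schema).
#' @return list of \linkS4class{RoiMask} and \linkS4class{PointAnnotation}
#'   objects, in file order.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("cannot read annotations: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$items)) .jsonFail("items", "missing")
  out <- vector("list", length(doc$items))
  for (i in seq_along(doc$items)) {
    it <- doc$items[[i]]
    where <- sprintf("items[%d]", i)
    if (is.null(it$type)) .jsonFail(paste0(where, ".type"), "missing")
    lab <- if (is.null(it$label)) "" else it$label
    if (it$type == "points") {
      if (is.null(it$points) || !length(it$points))
        .jsonFail(paste0(where, ".points"), "missing or empty")
      pts <- do.call(rbind, lapply(it$points, function(p) {
        p <- unlist(p)
        if (length(p) != 2L || !is.numeric(p))
          .jsonFail(paste0(where, ".points"), "each point must be [row, col]")
        p
      }))
      if (any(pts < 1))
        .jsonFail(paste0(where, ".points"),
                  "coordinates must be >= 1 (inside the frame extent)")
      closed <- isTRUE(it$closed)
      out[[i]] <- PointAnnotation(pts, closed = closed, label = lab)
    } else if (it$type == "mask") {
      if (is.null(it$shape) || length(unlist(it$shape)) != 2L)
        .jsonFail(paste0(where, ".shape"), "must be [M, N]")
      if (is.null(it$rle)) .jsonFail(paste0(where, ".rle"), "missing")
      m <- .rleToMask(it$rle, as.integer(unlist(it$shape)))
      out[[i]] <- RoiMask(m, label = if (nzchar(lab)) lab else "cam_vessel")
    } else .jsonFail(paste0(where, ".type"), paste0("unknown type '",
                                                    it$type, "'"))
  }
  out
}

#' Check that an annotation lies within a frame extent
#'
#' @param ann a \linkS4class{PointAnnotation} or \linkS4class{RoiMask}.
#' @param shape integer(2), (M, N) of the frames it annotates.
#' @return invisibly \code{TRUE}; errors otherwise.
#' @export
checkAnnotationExtent <- function(ann, shape) {
  if (is(ann, "RoiMask")) {
    if (!identical(dim(maskImage(ann)), as.integer(shape)))
      stop("mask shape ", paste(dim(maskImage(ann)), collapse = "x"),
           " does not match frame shape ", paste(shape, collapse = "x"))
  } else {
    p <- annotationPoints(ann)
    if (any(p[, 1] < 1 | p[, 1] > shape[1] |
            p[, 2] < 1 | p[, 2] > shape[2]))
      stop("annotation points fall outside the ", shape[1], " x ",
           shape[2], " frame extent")
  }
  invisible(TRUE)
}
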