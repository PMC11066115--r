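## Virtual angiography: vessel enhancement by accumulating absolute
## temporal finite differences. The model assumes co-registered frames
## with a static background, so any pixel whose temporal trace is constant
## accumulates exactly zero while moving speckle (flowing blood) lights up.
## All accumulation is in double precision.

#' Absolute temporal finite differences of a cine loop
#'
#' For a loop of \code{T} frames, returns the stack of \code{T - 1}
#' images \code{|I[t+1] - I[t]|}. Order-sensitive by construction.
#'
#' @param loop a \linkS4class{CineLoop} (\code{T >= 2}).
#' @return a \linkS4class{DifferenceStack}.
#' @examples
#' fr <- array(0, c(4, 4, 3)); fr[2, 2, ] <- c(0.1, 0.5, 0.2)
#' d <- finiteDifferences(CineLoop(fr))
#' diffImages(d)[2, 2, ]  # 0.4, 0.3
#' @export
finiteDifferences <- function(loop) {
  stopifnot(is(loop, "CineLoop"))
  fr <- frames(loop)
  storage.mode(fr) <- "double"
  tt <- dim(fr)[3]
  d <- abs(fr[, , 2:tt, drop = FALSE] - fr[, , 1:(tt - 1), drop = FALSE])
  new("DifferenceStack", diffs = d)
}

#' Batch virtual angiogram
#'
#' The angiogram is the element-wise mean of the absolute finite
#' differences: \code{I_VA = sum(|dI_t|) / (T - 1)}. A static loop maps to
#' an exactly-zero angiogram; adding a constant to every frame leaves the
#' result unchanged, and scaling all intensities by \code{a >= 0} scales
#' it by exactly \code{a}.
#'
#' @param loop a \linkS4class{CineLoop}.
#' @return an \linkS4class{Angiogram} with \code{tUsed = T - 1}.
#' @examples
#' fr <- array(0.3, c(8, 8, 5))        # static loop
#' max(angioImage(angiogramBatch(CineLoop(fr))))  # exactly 0
#' @export
angiogramBatch <- function(loop) {
  d <- diffImages(finiteDifferences(loop))
  n <- dim(d)[3]
  img <- rowSums(d, dims = 2) / n
  Angiogram(img, tUsed = n)
}

#' Zero angiogram to seed streaming accumulation
#'
#' @param shape integer(2), (M, N).
#' @return an \linkS4class{Angiogram} with \code{tUsed = 0}.
#' @export
emptyAngiogram <- function(shape) {
  Angiogram(matrix(0, shape[1], shape[2]), tUsed = 0L)
}

#' Online (streaming) angiogram update
#'
#' Running-mean update \code{I_VA,t = ((t - 1) I_VA,t-1 + |dI_t|) / t},
#' where \code{t} counts the differences consumed so far. Feeding all
#' \code{T - 1} differences of a loop reproduces \code{\link{angiogramBatch}}
#' to within 1e-9 per pixel.
#'
#' @param prev the \linkS4class{Angiogram} after \code{t - 1} updates
#'   (use \code{\link{emptyAngiogram}} to start).
#' @param nextDiff the next absolute-difference image, nonnegative, same
#'   shape as \code{prev}.
#' @return the updated \linkS4class{Angiogram} with \code{tUsed = t}.
#' @export
angiogramOnlineUpdate <- function(prev, nextDiff) {
  stopifnot(is(prev, "Angiogram"))
  img <- angioImage(prev)
  if (!identical(dim(img), dim(nextDiff)))
    stop("difference image shape ", paste(dim(nextDiff), collapse = "x"),
         " does not match angiogram shape ",
         paste(dim(img), collapse = "x"))
  if (min(nextDiff) < 0)
    stop("difference images must be nonnegative")
  t <- tUsed(prev) + 1L
  Angiogram(((t - 1) * img + nextDiff) / t, tUsed = t)
}

#' Stream a whole loop through the online update
#'
#' Convenience wrapper equivalent to folding
#' \code{\link{angiogramOnlineUpdate}} over the difference stack.
#'
#' @param loop a \linkS4class{CineLoop}.
#' @return the final \linkS4class{Angiogram}.
#' @export
angiogramOnline <- function(loop) {
  d <- diffImages(finiteDifferences(loop))
  acc <- emptyAngiogram(dim(d)[1:2])
  for (t in seq_len(dim(d)[3]))
    acc <- angiogramOnlineUpdate(acc, d[, , t])
  acc
}

#' Contrast-enhance an angiogram for display and annotation
#'
#' Clips at the given upper percentile, then rescales linearly to [0, 1].
#' Monotone below the clip; an all-zero angiogram maps to an all-zero
#' image. The (lo, hi) actually used is recorded on the returned
#' angiogram's \code{displayRange}.
#'
#' @param angio an \linkS4class{Angiogram}.
#' @param clipPercentile upper clip percentile in (50, 100].
#' @return list with \code{display} (matrix in [0, 1]) and \code{angio}
#'   (input with \code{displayRange} filled in).
#' @export
enhanceForDisplay <- function(angio, clipPercentile = 99.5) {
  stopifnot(is(angio, "Angiogram"))
  if (clipPercentile <= 50 || clipPercentile > 100)
    stop("clipPercentile must be in (50, 100]")
  img <- angioImage(angio)
  hi <- as.numeric(quantile(img, clipPercentile / 100, names = FALSE,
                            type = 7))
  lo <- 0
  if (hi <= lo) {
    disp <- matrix(0, nrow(img), ncol(img))
    hi <- lo
  } else {
    disp <- pmin(pmax((img - lo) / (hi - lo), 0), 1)
  }
  angio@displayRange <- c(lo, hi)
  validObject(angio)
  list(display = disp, angio = angio)
}

#' Persist an angiogram as 16-bit TIFF plus JSON sidecar
#'
#' The image is stored scaled by its maximum (recorded in the sidecar
#' together with \code{tUsed} and \code{displayRange}) so the float values
#' can be recovered to quantization precision.
#'
#' @param angio an \linkS4class{Angiogram}.
#' @param path TIFF destination; the sidecar is \code{<path>.json}.
#' @export
writeAngiogram <- function(angio, path) {
  img <- angioImage(angio)
  mx <- max(img)
  scaled <- if (mx > 0) img / mx else img
  writeImage(scaled, path, bitDepth = 16L)
  meta <- list(t_used = tUsed(angio), scale_max = mx,
               display_range = displayRange(angio))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an angiogram written by \code{\link{writeAngiogram}}
#' @param path TIFF path with \code{<path>.json} sidecar.
#' @return an \linkS4class{Angiogram}.
#' @export
readAngiogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- readImageGray(path) * meta$scale_max
  Angiogram(img, tUsed = meta$t_used,
            displayRange = if (length(meta$display_range))
              as.numeric(meta$display_range) else c(NA_real_, NA_real_))
}
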