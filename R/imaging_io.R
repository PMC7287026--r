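#' @importFrom EBImage readImage writeImage resize Image imageData colorMode
NULL

# Internal pixel convention: numeric arrays indexed [row, col(, channel)],
# row increasing downward, intensities in [0, 1]. EBImage stores images
# x-major, so IO converts with aperm().

.asRGBArray <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("expected a height x width (x 3) numeric array", call. = FALSE)
  if (length(d) == 2L) x <- array(rep(x, 3L), c(d, 3L))
  if (dim(x)[3] != 3L)
    stop("expected exactly 3 channels", call. = FALSE)
  x
}

.checkIntensities <- function(x, what = "image") {
  if (!all(is.finite(x)))
    stop(what, " contains non-finite intensities", call. = FALSE)
  if (min(x) < -1e-8 || max(x) > 1 + 1e-8)
    stop(what, " intensities must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

#' Read a bright-field eye photograph
#'
#' Reads a TIFF or PNG raster into the package's canonical representation:
#' a `height x width x 3` numeric array with intensities in `[0, 1]`
#' (integer sources are divided by their bit-depth maximum by the
#' underlying reader). Single-channel images are replicated across the
#' three channels; an alpha channel, if present, is dropped.
#'
#' @param path path to a TIFF or PNG file.
#' @return Numeric array `height x width x 3` in `[0, 1]`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' saveImage(array(runif(24 * 32 * 3), c(24, 32, 3)), f)
#' img <- loadImage(f)
#' dim(img)
loadImage <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read image: file not found: ", path, call. = FALSE)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot read image '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  a <- EBImage::imageData(img)
  d <- dim(a)
  if (length(d) == 2L) {
    a <- t(a)                                    # x,y -> row,col
    a <- array(rep(a, 3L), c(dim(a), 3L))
  } else if (length(d) == 3L) {
    if (d[3] > 4L)
      stop("unsupported image layout in '", path, "': ", d[3], " channels",
           call. = FALSE)
    if (d[3] == 2L) a <- a[, , 1L, drop = FALSE]  # gray + alpha
    if (d[3] == 4L) a <- a[, , 1:3, drop = FALSE] # drop alpha
    a <- aperm(a, c(2L, 1L, 3L))
    if (dim(a)[3] == 1L) a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
  } else stop("unsupported image layout in '", path, "'", call. = FALSE)
  a <- pmin(pmax(a, 0), 1)
  .checkIntensities(a, path)
  a
}

#' Write an image to PNG (or TIFF)
#'
#' @param img `height x width (x 3)` numeric array in `[0, 1]`.
#' @param path output path; format follows the file extension.
#' @return Invisibly, `path`.
#' @export
saveImage <- function(img, path) {
  img <- .asRGBArray(img)
  .checkIntensities(img)
  EBImage::writeImage(EBImage::Image(aperm(img, c(2L, 1L, 3L)),
                                     colormode = "Color"), path)
  invisible(path)
}

#' Downscale an image by an integer factor
#'
#' Bilinear downscaling (with antialias smoothing) to
#' `round(height/factor) x round(width/factor)`. Eye photographs are
#' reduced to one-fourth of their acquisition resolution before
#' segmentation.
#'
#' @param img `height x width (x 3)` numeric array in `[0, 1]`.
#' @param factor positive integer scale divisor (default 4).
#' @return Array of the reduced size, same number of channels.
#' @export
#' @examples
#' x <- array(0.3, c(64, 48, 3))
#' dim(downscaleImage(x, 4))
downscaleImage <- function(img, factor = 4L) {
  if (length(factor) != 1L || !is.finite(factor) || factor < 1 ||
      abs(factor - round(factor)) > 1e-8)
    stop("factor must be a positive integer", call. = FALSE)
  factor <- as.integer(round(factor))
  d <- dim(img)
  if (factor > min(d[1:2]))
    stop("factor exceeds the image dimensions", call. = FALSE)
  if (factor == 1L) return(img)
  resizeImage(img, round(d[1] / factor), round(d[2] / factor),
              antialias = TRUE)
}

#' Resize an image to exact dimensions
#'
#' Bilinear interpolation to the requested `outHeight x outWidth`.
#' Constant images stay constant and intensities remain in `[0, 1]`.
#'
#' @param img `height x width (x 3)` numeric array.
#' @param outHeight,outWidth target dimensions in pixels (>= 1).
#' @param antialias apply a smoothing filter before subsampling (used
#'   when downscaling to avoid moire on the ommatidial lattice).
#' @return Resized array of the same kind (gray matrix in, gray matrix
#'   out).
#' @export
resizeImage <- function(img, outHeight, outWidth, antialias = FALSE) {
  if (outHeight < 1 || outWidth < 1)
    stop("target dimensions must be positive", call. = FALSE)
  d <- dim(img)
  gray <- length(d) == 2L
  out <- EBImage::resize(img, w = as.integer(outHeight),
                         h = as.integer(outWidth),
                         filter = "bilinear", antialias = antialias)
  out <- pmin(pmax(out, 0), 1)
  if (gray) out <- matrix(out, as.integer(outHeight), as.integer(outWidth))
  out
}

#' Convert an RGB image to grayscale luminance
#'
#' Per-pixel luminance `0.2126 R + 0.7152 G + 0.0722 B` (Rec. 709
#' coefficients; the weight vector is configurable). The weighted mean of
#' equal channels is the channel value, so grayscale inputs replicated to
#' RGB round-trip exactly.
#'
#' @param img `height x width x 3` numeric array in `[0, 1]`.
#' @param weights numeric(3) non-negative channel weights summing to 1.
#' @return `height x width` numeric matrix in `[0, 1]`.
#' @export
#' @examples
#' rgbToGray(array(c(1, 0, 0), c(1, 1, 3)))  # pure red -> 0.2126
rgbToGray <- function(img, weights = c(0.2126, 0.7152, 0.0722)) {
  img <- .asRGBArray(img)
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("weights must be three non-negative values summing to 1",
         call. = FALSE)
  img[, , 1] * weights[1] + img[, , 2] * weights[2] + img[, , 3] * weights[3]
}
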