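#' @importFrom EBImage opening
#' @importFrom stats quantile cov qchisq median
NULL

#' Segmentation parameter set
#'
#' Bundles the tunable parameters of the eye-ROI detector with their
#' defaults: quarter resizing, white top-hat with a disc kernel of
#' diameter 9, bright-pixel selection above the 0.99 intensity quantile,
#' discarding of pixels beyond the 0.8 quantile of distance to the
#' L1-median centroid, and a 0.90 confidence ellipse.
#'
#' @param resizeFactor integer >= 1, downscaling divisor applied first.
#' @param kernelSize odd integer, disc kernel diameter in pixels.
#' @param intensityQuantile quantile in (0,1) for bright-pixel selection.
#' @param distanceQuantile quantile in (0,1) for centroid-distance
#'   outlier rejection.
#' @param ellipseLevel confidence level in (0,1) of the ROI ellipse.
#' @return Named list of validated parameters.
#' @export
segmentationParams <- function(resizeFactor = 4L, kernelSize = 9L,
                               intensityQuantile = 0.99,
                               distanceQuantile = 0.8,
                               ellipseLevel = 0.90) {
  stopifnot(resizeFactor >= 1, kernelSize >= 1, kernelSize %% 2 == 1)
  for (q in c(intensityQuantile, distanceQuantile, ellipseLevel))
    if (q <= 0 || q >= 1)
      stop("quantiles and confidence level must lie strictly in (0, 1)",
           call. = FALSE)
  list(resizeFactor = as.integer(resizeFactor),
       kernelSize = as.integer(kernelSize),
       intensityQuantile = intensityQuantile,
       distanceQuantile = distanceQuantile,
       ellipseLevel = ellipseLevel)
}

#' Disc-shaped structuring element
#'
#' Binary `size x size` mask with cell (i, j) set iff
#' `(i - c)^2 + (j - c)^2 <= r^2`, where `c = r = (size - 1) / 2` (size
#' read as the disc diameter). For size 9 the disc holds 49 pixels.
#'
#' @param size odd positive integer, the disc diameter in pixels.
#' @return Integer 0/1 matrix of dimension `size x size`.
#' @export
#' @examples
#' sum(discKernel(9))  # 49
discKernel <- function(size = 9L) {
  if (length(size) != 1L || !is.finite(size) || size < 1 || size %% 2 != 1)
    stop("size must be a positive odd integer", call. = FALSE)
  size <- as.integer(size)
  r <- (size - 1) / 2
  idx <- seq_len(size) - 1 - r
  d2 <- outer(idx^2, idx^2, `+`)
  matrix(as.integer(d2 <= r^2 + 1e-9), size, size)
}

#' White top-hat transform
#'
#' `input - opening(input)` with the given binary structuring element
#' (opening = dilation of the erosion), enhancing bright structures
#' smaller than the kernel — here the in-focus ommatidial facets of the
#' convex eye surface. RGB images are transformed per channel.
#'
#' @param img `height x width (x 3)` numeric array in `[0, 1]`.
#' @param kernel binary structuring matrix, e.g. [discKernel()].
#' @return Array of the input's shape, intensities in `[0, 1]`.
#' @export
whiteTophat <- function(img, kernel = discKernel(9L)) {
  d <- dim(img)
  if (any(dim(kernel) > d[1:2]))
    stop("structuring kernel larger than the image", call. = FALSE)
  th <- function(m) pmin(pmax(m - EBImage::opening(m, kernel), 0), 1)
  if (length(d) == 2L) return(th(img))
  out <- img
  for (ch in seq_len(d[3])) out[, , ch] <- th(img[, , ch])
  out
}

#' Select pixels above an intensity quantile
#'
#' Returns the pixels whose intensity strictly exceeds the `q` quantile
#' of all pixel intensities (type-7 linearly interpolated order
#' statistics, the \R default).
#'
#' @param gray `height x width` numeric matrix in `[0, 1]`.
#' @param q quantile in (0,1); default 0.99.
#' @return List with `coords` (n x 2 integer matrix of `(row, col)`),
#'   `intensity` (numeric n), and `threshold` (the quantile used).
#' @export
selectBrightPixels <- function(gray, q = 0.99) {
  if (!is.matrix(gray) || length(gray) == 0L)
    stop("gray must be a non-empty matrix", call. = FALSE)
  thr <- stats::quantile(gray, q, names = FALSE, type = 7)
  keep <- which(gray > thr)
  if (length(keep) == 0L)
    stop("degenerate input: no pixel strictly exceeds the ", q,
         " intensity quantile; lower intensityQuantile or check the image",
         call. = FALSE)
  coords <- arrayInd(keep, dim(gray))
  colnames(coords) <- c("row", "col")
  list(coords = coords, intensity = gray[keep], threshold = thr)
}

#' Geometric (L1) median of a 2-D point set
#'
#' The point minimising the sum of Euclidean distances to all points,
#' computed by Weiszfeld's iteratively reweighted scheme: initialisation
#' at the coordinate-wise median; convergence when successive iterates
#' move less than `tol`; if an iterate coincides with a data point the
#' Vardi-Zhang adjusted step is taken to avoid division by zero.
#'
#' @param points n x 2 numeric matrix of `(row, col)` coordinates.
#' @param tol convergence tolerance on the iterate displacement.
#' @param maxIter iteration cap.
#' @return Numeric(2), the `(row, col)` L1-median.
#' @references Weiszfeld (1937); Vardi & Zhang (2000), PNAS 97:1423.
#' @export
l1Median <- function(points, tol = 1e-6, maxIter = 1000L) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty point set", call. = FALSE)
  if (nrow(points) == 1L) return(as.numeric(points[1, ]))
  x <- apply(points, 2, stats::median)
  for (iter in seq_len(maxIter)) {
    d <- sqrt(rowSums(sweep(points, 2, x)^2))
    at <- d < 1e-9
    if (any(at)) {
      # Vardi-Zhang: treat the coincident data point's multiplicity
      # separately and damp the Weiszfeld step accordingly
      if (sum(!at) == 0L) return(as.numeric(x))
      w <- 1 / d[!at]
      tshift <- colSums(points[!at, , drop = FALSE] * w) / sum(w) - x
      rnorm_ <- sqrt(sum((colSums(sweep(points[!at, , drop = FALSE], 2, x) /
                                    d[!at]))^2))
      eta <- sum(at)
      step <- max(0, 1 - eta / max(rnorm_, 1e-12))
      xnew <- x + step * tshift
    } else {
      w <- 1 / d
      xnew <- colSums(points * w) / sum(w)
    }
    if (sqrt(sum((xnew - x)^2)) < tol) {
      x <- xnew
      break
    }
    x <- xnew
  }
  as.numeric(x)
}

#' Discard pixels far from the centroid
#'
#' Computes each point's Euclidean distance to `center` and removes the
#' points whose distance strictly exceeds the `q` quantile of the
#' distance distribution (type-7 estimator, matching
#' [selectBrightPixels()]).
#'
#' @param points n x 2 numeric matrix of `(row, col)` coordinates.
#' @param center numeric(2) centroid.
#' @param q quantile in (0,1); default 0.8.
#' @return List with `coords` (kept points), `kept` (logical index into
#'   the input), and `threshold`.
#' @export
filterByDistance <- function(points, center, q = 0.8) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty point set", call. = FALSE)
  d <- sqrt((points[, 1] - center[1])^2 + (points[, 2] - center[2])^2)
  thr <- stats::quantile(d, q, names = FALSE, type = 7)
  kept <- d <= thr
  list(coords = points[kept, , drop = FALSE], kept = kept, threshold = thr)
}

#' Fit a Gaussian confidence ellipse to a point set
#'
#' Centre = coordinate mean; covariance = sample covariance (n - 1
#' denominator); boundary at the chi-square(2 df) quantile of the
#' requested level, so that for Gaussian scatter the ellipse covers
#' approximately `level` of the points.
#'
#' @param points n x 2 numeric matrix (n >= 3, non-collinear).
#' @param level confidence level in (0,1); default 0.90
#'   (chi-square scale 2 log 10 = 4.60517).
#' @return An [EllipseROI-class].
#' @export
fitConfidenceEllipse <- function(points, level = 0.90) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    stop("degenerate geometry: need at least 3 points", call. = FALSE)
  ctr <- colMeans(points)
  S <- stats::cov(points)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(!is.finite(ev)) || min(ev) <= 1e-10 * max(ev, 1))
    stop("degenerate geometry: collinear points give a singular covariance",
         call. = FALSE)
  new("EllipseROI", center = as.numeric(ctr), covariance = S,
      scale = stats::qchisq(level, df = 2), level = level)
}

#' Test ellipse membership
#'
#' @param ellipse an [EllipseROI-class].
#' @param points n x 2 numeric matrix of `(row, col)` coordinates.
#' @return Logical vector: Mahalanobis distance squared `<= scale`.
#' @export
insideEllipse <- function(ellipse, points) {
  points <- as.matrix(points)
  ci <- solve(ellipse@covariance)
  dx <- sweep(points, 2, ellipse@center)
  q <- rowSums((dx %*% ci) * dx)
  q <= ellipse@scale
}

#' Crop the elliptical ROI out of an image
#'
#' Takes the ellipse's bounding box intersected with the image, rasterises
#' ellipse membership into a binary mask and zeroes the pixels outside the
#' mask, so downstream featurization sees a rectangular grid supported
#' only on the eye.
#'
#' @param img `height x width x 3` numeric array (the resized source).
#' @param ellipse an [EllipseROI-class] in `img` coordinates.
#' @param source provenance string stored on the result.
#' @return An [EyeROI-class].
#' @export
cropROI <- function(img, ellipse, source = NA_character_) {
  img <- .asRGBArray(img)
  d <- dim(img)
  ctr <- ellipse@center
  if (ctr[1] < 1 || ctr[1] > d[1] || ctr[2] < 1 || ctr[2] > d[2])
    stop("ellipse center lies outside the image", call. = FALSE)
  half <- sqrt(ellipse@scale * diag(ellipse@covariance))
  r0 <- max(1L, floor(ctr[1] - half[1]))
  r1 <- min(d[1], ceiling(ctr[1] + half[1]))
  c0 <- max(1L, floor(ctr[2] - half[2]))
  c1 <- min(d[2], ceiling(ctr[2] + half[2]))
  if (r1 < r0 || c1 < c0)
    stop("ellipse lies entirely outside the image", call. = FALSE)
  rows <- r0:r1; cols <- c0:c1
  grid <- cbind(rep(rows, times = length(cols)),
                rep(cols, each = length(rows)))
  mask <- matrix(as.integer(insideEllipse(ellipse, grid)),
                 length(rows), length(cols))
  if (sum(mask) == 0L)
    stop("ellipse rasterises to an empty mask", call. = FALSE)
  crop <- sweep(img[rows, cols, , drop = FALSE], c(1, 2), mask, `*`)
  new("EyeROI", image = crop, mask = mask, ellipse = ellipse,
      offset = c(r0, c0),
      source = if (is.na(source)) "" else source)
}

#' Segment the eye region of interest
#'
#' The full five-stage detector: downscale, white top-hat with a disc
#' kernel (per RGB channel), grayscale conversion, selection of pixels
#' above the intensity quantile, Weiszfeld L1-median centroid,
#' centroid-distance outlier rejection, confidence-ellipse fit, and crop
#' of the ellipse from the downscaled original image. The detector is
#' invariant to where the eye sits in the frame.
#'
#' @param img `height x width x 3` numeric array in `[0, 1]`, or a file
#'   path readable by [loadImage()].
#' @param params parameter list from [segmentationParams()].
#' @param source provenance string (defaults to the path when `img` is
#'   one).
#' @return An [EyeROI-class]; its ellipse is expressed in the coordinates
#'   of the downscaled image.
#' @export
segmentEye <- function(img, params = segmentationParams(),
                       source = NA_character_) {
  if (is.character(img)) {
    if (is.na(source)) source <- img
    img <- loadImage(img)
  }
  img <- .asRGBArray(img)
  .checkIntensities(img)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("segmentation failed at stage [", name, "]: ",
           conditionMessage(e), call. = FALSE))
  }
  small <- stage("downscale", downscaleImage(img, params$resizeFactor))
  enhanced <- stage("tophat",
                    whiteTophat(small, discKernel(params$kernelSize)))
  gray <- stage("grayscale", rgbToGray(enhanced))
  bright <- stage("threshold",
                  selectBrightPixels(gray, params$intensityQuantile))
  ctr <- stage("centroid", l1Median(bright$coords))
  kept <- stage("distance-filter",
                filterByDistance(bright$coords, ctr,
                                 params$distanceQuantile))
  ell <- stage("ellipse",
               fitConfidenceEllipse(kept$coords, params$ellipseLevel))
  stage("crop", cropROI(small, ell, source = source))
}
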