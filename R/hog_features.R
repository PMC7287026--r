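#' HOG parameter set
#'
#' Parameters of the oriented-gradient descriptor: a `cells x cells`
#' grid of contiguous cells and `nOrientations` unsigned orientation
#' bins covering 0-180 degrees. The defaults (5 x 5 cells, 5 bins)
#' yield the 125-dimensional descriptor used for classification.
#'
#' @param cells cells per image side (>= 1).
#' @param nOrientations orientation bins over 0-180 degrees (>= 1).
#' @param normalize L2-normalise each cell histogram (epsilon 1e-6);
#'   disabling it exposes the raw gradient-magnitude histogram.
#' @param interpolateBins share each pixel's vote linearly between the
#'   two nearest orientation bins instead of hard assignment.
#' @return Named parameter list.
#' @export
hogParams <- function(cells = 5L, nOrientations = 5L, normalize = TRUE,
                      interpolateBins = FALSE) {
  stopifnot(cells >= 1, nOrientations >= 1)
  list(cells = as.integer(cells), nOrientations = as.integer(nOrientations),
       normalize = isTRUE(normalize),
       interpolateBins = isTRUE(interpolateBins))
}

#' Image gradient field
#'
#' Centred finite differences with replicated borders:
#' `gx = (I[r, c+1] - I[r, c-1]) / 2` along columns and
#' `gy = (I[r+1, c] - I[r-1, c]) / 2` along rows. Magnitude is the
#' Euclidean norm and orientation `atan2(gy, gx)` in degrees folded into
#' `[0, 180)` (unsigned gradients).
#'
#' @param gray `height x width` numeric matrix, at least 3 x 3.
#' @return List with matrices `magnitude` (>= 0) and `orientation`
#'   (degrees in `[0, 180)`).
#' @export
computeGradient <- function(gray) {
  if (!is.matrix(gray) || nrow(gray) < 3L || ncol(gray) < 3L)
    stop("image must be at least 3 x 3", call. = FALSE)
  h <- nrow(gray); w <- ncol(gray)
  right <- gray[, c(2:w, w)]; left <- gray[, c(1, 1:(w - 1))]
  down <- gray[c(2:h, h), ]; up <- gray[c(1, 1:(h - 1)), ]
  gx <- (right - left) / 2
  gy <- (down - up) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180
  ang[ang >= 180] <- 0          # guard against 180 from fp rounding
  list(magnitude = mag, orientation = ang)
}

# near-equal contiguous index bands for cell partition
.bands <- function(n, k) {
  cuts <- round(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(i) (cuts[i] + 1L):cuts[i + 1L])
}

#' Histogram-of-oriented-gradients descriptor
#'
#' Partitions the image into a `cells x cells` grid of contiguous cells
#' (band sizes differing by at most one pixel when the image dimension is
#' not divisible), accumulates each pixel's gradient magnitude into the
#' orientation bin containing its unsigned gradient direction, and
#' L2-normalises each cell's histogram (epsilon 1e-6). Blocks are
#' concatenated cell-major: cells in row-major order, orientation bins
#' fastest. With the defaults the result has length 125. The per-cell
#' normalisation makes the descriptor invariant to global intensity
#' scaling and shifts.
#'
#' @param gray `height x width` numeric matrix.
#' @param params parameter list from [hogParams()].
#' @return Numeric vector of length `cells^2 * nOrientations`.
#' @export
#' @examples
#' length(hogDescriptor(matrix(runif(200 * 200), 200), hogParams()))  # 125
hogDescriptor <- function(gray, params = hogParams()) {
  if (!is.matrix(gray) || nrow(gray) < params$cells ||
      ncol(gray) < params$cells)
    stop("image smaller than the cell grid", call. = FALSE)
  g <- computeGradient(gray)
  nb <- params$nOrientations
  binw <- 180 / nb
  rb <- .bands(nrow(gray), params$cells)
  cb <- .bands(ncol(gray), params$cells)
  out <- numeric(params$cells^2 * nb)
  pos <- 0L
  for (i in seq_len(params$cells)) {
    for (j in seq_len(params$cells)) {
      m <- g$magnitude[rb[[i]], cb[[j]]]
      a <- g$orientation[rb[[i]], cb[[j]]]
      if (params$interpolateBins) {
        x <- a / binw - 0.5
        lo <- floor(x)
        fr <- x - lo
        b0 <- (lo %% nb) + 1L
        b1 <- ((lo + 1) %% nb) + 1L
        hist <- as.numeric(
          tapply(c(m * (1 - fr), m * fr), factor(c(b0, b1), levels = 1:nb),
                 sum, default = 0))
      } else {
        b <- pmin(floor(a / binw), nb - 1L) + 1L
        hist <- as.numeric(tapply(as.numeric(m), factor(b, levels = 1:nb),
                                  sum, default = 0))
      }
      if (params$normalize)
        hist <- hist / sqrt(sum(hist^2) + 1e-6^2)
      out[pos + 1:nb] <- hist
      pos <- pos + nb
    }
  }
  out
}

#' Featurize a set of eye ROIs
#'
#' Converts each [EyeROI-class] (or raw RGB array) to grayscale luminance
#' and computes its HOG descriptor, assembling the labelled feature
#' matrix fed to the classifiers.
#'
#' @param patches list of [EyeROI-class] objects or RGB arrays.
#' @param labels phenotype label per patch (factor or character), or
#'   `NULL` for unlabelled data.
#' @param params parameter list from [hogParams()].
#' @return An [EyeFeatures-class] with one row per patch.
#' @export
featurizeDataset <- function(patches, labels = NULL, params = hogParams()) {
  n <- length(patches)
  if (!is.null(labels) && length(labels) != n)
    stop("patches and labels must be aligned", call. = FALSE)
  p <- params$cells^2 * params$nOrientations
  feats <- matrix(0, n, p)
  src <- character(n)
  for (i in seq_len(n)) {
    obj <- patches[[i]]
    if (is(obj, "EyeROI")) {
      img <- obj@image
      src[i] <- obj@source
    } else img <- .asRGBArray(obj)
    feats[i, ] <- hogDescriptor(rgbToGray(img), params)
  }
  if (n > 0) colnames(feats) <- sprintf("f%03d", seq_len(p))
  lab <- if (is.null(labels)) factor(rep(NA_character_, n))
         else if (is.factor(labels)) labels
         else factor(labels, levels = unique(labels))
  new("EyeFeatures", features = feats, labels = lab, source = src)
}
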