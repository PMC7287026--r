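#' Accessors for ommaQuant S4 objects
#'
#' Small accessor generics: `featureMatrix()` and `eyeLabels()` read the
#' descriptor matrix and label factor out of an [EyeFeatures-class];
#' `roiImage()`, `roiMask()` and `roiEllipse()` read the crop, the binary
#' ellipse mask and the fitted [EllipseROI-class] out of an
#' [EyeROI-class]; `ellipseCenter()` and `ellipseAxes()` report an
#' ellipse's centre and semi-axis lengths (major, minor; the semi-axes of
#' the boundary at the stored chi-square scale).
#'
#' @param x the object.
#' @return The corresponding slot contents (see Details of each class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("eyeLabels", function(x) standardGeneric("eyeLabels"))
#' @rdname accessors
#' @export
setGeneric("roiImage", function(x) standardGeneric("roiImage"))
#' @rdname accessors
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))
#' @rdname accessors
#' @export
setGeneric("roiEllipse", function(x) standardGeneric("roiEllipse"))
#' @rdname accessors
#' @export
setGeneric("ellipseCenter", function(x) standardGeneric("ellipseCenter"))
#' @rdname accessors
#' @export
setGeneric("ellipseAxes", function(x) standardGeneric("ellipseAxes"))

#' @rdname accessors
setMethod("featureMatrix", "EyeFeatures", function(x) x@features)
#' @rdname accessors
setMethod("eyeLabels", "EyeFeatures", function(x) x@labels)
#' @rdname accessors
setMethod("roiImage", "EyeROI", function(x) x@image)
#' @rdname accessors
setMethod("roiMask", "EyeROI", function(x) x@mask)
#' @rdname accessors
setMethod("roiEllipse", "EyeROI", function(x) x@ellipse)
#' @rdname accessors
setMethod("ellipseCenter", "EllipseROI", function(x) x@center)
#' @rdname accessors
setMethod("ellipseCenter", "EyeROI", function(x) x@ellipse@center)
#' @rdname accessors
setMethod("ellipseAxes", "EllipseROI", function(x) {
  ev <- eigen(x@covariance, symmetric = TRUE, only.values = TRUE)$values
  sqrt(x@scale * sort(ev, decreasing = TRUE))
})

setMethod("show", "EllipseROI", function(object) {
  ax <- ellipseAxes(object)
  cat(sprintf(
    "EllipseROI: center (row=%.1f, col=%.1f), semi-axes %.1f x %.1f px, %.0f%% level\n",
    object@center[1], object@center[2], ax[1], ax[2], 100 * object@level))
})

setMethod("show", "EyeROI", function(object) {
  d <- dim(object@image)
  cat(sprintf("EyeROI: %d x %d crop, %d mask pixels, source '%s'\n",
              d[1], d[2], sum(object@mask != 0), object@source))
  show(object@ellipse)
})

setMethod("show", "EyeFeatures", function(object) {
  cat(sprintf("EyeFeatures: %d images x %d features\n",
              nrow(object@features), ncol(object@features)))
  if (length(object@labels))
    print(table(object@labels))
})

setMethod("show", "EyeClassifier", function(object) {
  hp <- paste(names(object@hyper), unlist(object@hyper),
              sep = "=", collapse = ", ")
  cat(sprintf("EyeClassifier <%s> on %d features (%s); classes: %s\n",
              object@kind, object@featureDim, hp,
              paste(object@classOrder, collapse = ", ")))
})

setMethod("show", "EyeEvalReport", function(object) {
  cat(sprintf(
    "EyeEvalReport: accuracy %.3f (%.3f-%.3f), kappa %.3f, multiclass AUC %.3f\n",
    object@accuracy, object@accuracyCI[1], object@accuracyCI[2],
    object@kappa, object@mAUC))
  cat("Confusion matrix (rows = predicted, cols = reference):\n")
  print(object@confusion)
})

setMethod("show", "EyeSpec", function(object) {
  cat(sprintf(
    "EyeSpec: %dx%d px, axes (%g, %g), spacing %g, jitter %g, fusion %g, depig %g, bristles %g, %s\n",
    object@imageSize[1], object@imageSize[2], object@eyeAxes[1],
    object@eyeAxes[2], object@latticeSpacing, object@jitterSd,
    object@fusionProb, object@depigProb, object@bristleDensity,
    object@illumination))
})

setMethod("show", "LabeledEyeImage", function(object) {
  cat(sprintf("LabeledEyeImage: %dx%d px, label '%s', disorder %.2f, %d facets\n",
              dim(object@image)[1], dim(object@image)[2], object@label,
              object@disorderLevel, nrow(object@truth$facets)))
})
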