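#' @import methods
NULL

#' Canonical phenotype class order
#'
#' The five phenotype classes of the rough-eye model, ordered as used
#' throughout the package: healthy wild type, the full SCA1 degeneration
#' phenotype, and three genetic modifiers of intermediate severity.
#' Severity increases WT < mod1 < mod2 < mod3 < SCA1.
#'
#' @return Character vector of length 5:
#'   `c("WT", "SCA1", "mod1", "mod2", "mod3")`.
#' @export
#' @examples
#' eyeClasses()
eyeClasses <- function() c("WT", "SCA1", "mod1", "mod2", "mod3")

#' @title EllipseROI: a confidence ellipse in image coordinates
#'
#' @description Gaussian confidence ellipse fitted to candidate eye
#' pixels. A point `x` (as `(row, col)`) lies inside the ellipse iff
#' `t(x - center) %*% solve(covariance) %*% (x - center) <= scale`,
#' where `scale` is the chi-square(2 df) quantile at the confidence
#' level.
#'
#' @slot center numeric(2), `(row, col)` of the ellipse centre.
#' @slot covariance 2x2 symmetric positive-definite matrix.
#' @slot scale positive scalar, chi-square(2) quantile at `level`.
#' @slot level confidence level in (0, 1).
#' @exportClass EllipseROI
setClass("EllipseROI",
  representation(center = "numeric", covariance = "matrix",
                 scale = "numeric", level = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@center) != 2L || !all(is.finite(object@center)))
      msg <- c(msg, "center must be a finite (row, col) pair")
    if (!all(dim(object@covariance) == c(2L, 2L)))
      msg <- c(msg, "covariance must be 2x2")
    else {
      if (max(abs(object@covariance - t(object@covariance))) > 1e-8)
        msg <- c(msg, "covariance must be symmetric")
      ev <- eigen(object@covariance, symmetric = TRUE,
                  only.values = TRUE)$values
      if (any(ev <= 0)) msg <- c(msg, "covariance must be positive definite")
    }
    if (length(object@scale) != 1L || object@scale <= 0)
      msg <- c(msg, "scale must be a positive scalar")
    if (object@level <= 0 || object@level >= 1)
      msg <- c(msg, "level must lie strictly inside (0, 1)")
    if (is.null(msg)) TRUE else msg
  })

#' @title EyeROI: an extracted eye region of interest
#'
#' @description Rectangular crop of the (resized) source image around the
#' fitted confidence ellipse, together with the binary ellipse-membership
#' mask (pixels outside the ellipse are zeroed in the crop) and the
#' ellipse itself in source-image coordinates.
#'
#' @slot image numeric array `height x width x 3`, intensities in [0,1],
#'   zeroed outside the mask.
#' @slot mask integer/logical matrix aligned to `image` (1 = inside).
#' @slot ellipse the [EllipseROI-class] in the coordinates of the resized
#'   source image.
#' @slot offset numeric(2): `(row, col)` of the crop's top-left pixel in
#'   the resized source image (1-based).
#' @slot source character(1) provenance string (file path or label).
#' @exportClass EyeROI
setClass("EyeROI",
  representation(image = "array", mask = "matrix", ellipse = "EllipseROI",
                 offset = "numeric", source = "character"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@image)
    if (length(d) != 3L || d[3] != 3L)
      msg <- c(msg, "image must be height x width x 3")
    if (!all(dim(object@mask) == d[1:2]))
      msg <- c(msg, "mask must align with image")
    if (sum(object@mask) < 1)
      msg <- c(msg, "mask must contain at least one positive pixel")
    if (is.null(msg)) TRUE else msg
  })

#' @title EyeFeatures: a labelled HOG feature matrix
#'
#' @description One row per eye image: the oriented-gradient descriptor,
#' with aligned phenotype labels and provenance. The container fed to the
#' classifiers.
#'
#' @slot features numeric matrix, rows = images, columns = descriptor
#'   dimensions (125 with default parameters).
#' @slot labels factor of phenotype labels aligned to rows (levels follow
#'   [eyeClasses()] when the data come from the five-class design).
#' @slot source character vector of per-row provenance strings.
#' @exportClass EyeFeatures
setClass("EyeFeatures",
  representation(features = "matrix", labels = "factor",
                 source = "character"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@features) != length(object@labels))
      msg <- c(msg, "label count must equal feature row count")
    if (length(object@source) != nrow(object@features))
      msg <- c(msg, "source count must equal feature row count")
    if (nrow(object@features) > 0 && any(!is.finite(object@features)))
      msg <- c(msg, "features must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' @title EyeClassifier: a trained phenotype classifier
#'
#' @description Wraps a fitted learner (RBF-kernel SVM, decision tree,
#' AdaBoost decision tree or random forest) together with the fixed
#' class order its probability output follows and the feature
#' dimensionality it expects.
#'
#' @slot kind one of `"svm_rbf"`, `"dt"`, `"adaboost_dt"`, `"rf"`.
#' @slot fit the underlying fitted model object.
#' @slot classOrder character vector, the fixed probability column order.
#' @slot featureDim integer, expected descriptor length.
#' @slot hyper named list of hyperparameters used.
#' @slot seed integer seed the fit was performed under.
#' @exportClass EyeClassifier
setClass("EyeClassifier",
  representation(kind = "character", fit = "ANY", classOrder = "character",
                 featureDim = "integer", hyper = "list", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("svm_rbf", "dt", "adaboost_dt", "rf"))
      msg <- c(msg, "unknown classifier kind")
    if (length(object@classOrder) < 2L)
      msg <- c(msg, "classOrder must name at least two classes")
    if (is.null(msg)) TRUE else msg
  })

#' @title EyeEvalReport: test-set evaluation of a classifier
#'
#' @description Confusion matrix (rows = predicted, columns = reference)
#' and the derived metrics: global accuracy with exact binomial
#' (Clopper-Pearson) confidence interval, Cohen's kappa, and the
#' multiclass pairwise AUC of Hand and Till with its per-pair table.
#'
#' @slot confusion K x K integer matrix, predicted x reference.
#' @slot accuracy numeric(1).
#' @slot accuracyCI numeric(2), lower and upper 95% bounds.
#' @slot kappa numeric(1).
#' @slot mAUC numeric(1), Hand-Till multiclass AUC.
#' @slot pairwiseAUC K x K symmetric matrix of pairwise AUCs (NA diagonal).
#' @exportClass EyeEvalReport
setClass("EyeEvalReport",
  representation(confusion = "matrix", accuracy = "numeric",
                 accuracyCI = "numeric", kappa = "numeric", mAUC = "numeric",
                 pairwiseAUC = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@confusion) != ncol(object@confusion))
      msg <- c(msg, "confusion matrix must be square")
    if (any(object@confusion < 0))
      msg <- c(msg, "confusion counts must be non-negative")
    tot <- sum(object@confusion)
    if (tot > 0 &&
        abs(object@accuracy - sum(diag(object@confusion)) / tot) > 1e-8)
      msg <- c(msg, "accuracy must equal trace/total of the confusion matrix")
    if (length(object@accuracyCI) == 2L && length(object@accuracy) == 1L &&
        (object@accuracy < object@accuracyCI[1] - 1e-8 ||
         object@accuracy > object@accuracyCI[2] + 1e-8))
      msg <- c(msg, "accuracy must lie inside its confidence interval")
    if (is.null(msg)) TRUE else msg
  })

#' @title EyeSpec: appearance parameters for one synthetic eye image
#'
#' @description Parameterises the synthetic compound-eye renderer: a
#' convex elliptical eye of hexagonally packed ommatidial facets on a
#' plain background, with graded disorder (positional jitter, facet
#' fusion, depigmentation, interommatidial bristle loss) and two
#' illumination modes (`"diffuse"` smooth shading, `"bright_spot"`
#' specular highlight per facet).
#'
#' Construct with [eyeSpec()], which fills defaults and randomises the
#' eye position when none is given.
#'
#' @slot imageSize integer(2) `(height, width)` in pixels.
#' @slot eyeCenter numeric(2) `(row, col)`; `NA` = randomise at render.
#' @slot eyeAxes numeric(2) semi-axes `(b_row, a_col)` in pixels.
#' @slot latticeSpacing numeric(1), centre-to-centre facet spacing (px).
#' @slot jitterSd numeric(1), sd of isotropic Gaussian jitter of facet
#'   centres (px).
#' @slot fusionProb numeric(1) in [0,1], per-facet neighbour-fusion
#'   probability.
#' @slot depigProb numeric(1) in [0,1], per-facet probability of seeding
#'   a depigmented (red-attenuated) patch.
#' @slot bristleDensity numeric(1) in [0,1], fraction of facets carrying
#'   an interommatidial bristle hair.
#' @slot necrosisProb numeric(1) in [0,1], per-facet probability of a
#'   dark necrotic patch.
#' @slot facetContrast numeric(1) in [0,1], contrast of the facet colour
#'   against the interommatidial base (1 = crisp lattice, 0 = facets
#'   indistinguishable from the base tissue).
#' @slot glintProb numeric(1) in [0,1], probability that a facet focuses
#'   light into a small specular glint.
#' @slot illumination `"diffuse"` or `"bright_spot"`.
#' @slot backgroundLevel numeric(1) in [0,1].
#' @slot noiseSd numeric(1), sd of additive Gaussian pixel noise.
#' @exportClass EyeSpec
setClass("EyeSpec",
  representation(imageSize = "integer", eyeCenter = "numeric",
                 eyeAxes = "numeric", latticeSpacing = "numeric",
                 jitterSd = "numeric", fusionProb = "numeric",
                 depigProb = "numeric", bristleDensity = "numeric",
                 necrosisProb = "numeric", facetContrast = "numeric",
                 glintProb = "numeric",
                 illumination = "character", backgroundLevel = "numeric",
                 noiseSd = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@imageSize < 8L)) msg <- c(msg, "image too small")
    if (object@latticeSpacing < 2) msg <- c(msg, "latticeSpacing must be >= 2")
    for (p in c("fusionProb", "depigProb", "bristleDensity",
                "necrosisProb", "facetContrast", "glintProb")) {
      v <- slot(object, p)
      if (v < 0 || v > 1) msg <- c(msg, paste(p, "must lie in [0,1]"))
    }
    if (!object@illumination %in% c("diffuse", "bright_spot"))
      msg <- c(msg, "illumination must be 'diffuse' or 'bright_spot'")
    if (object@jitterSd < 0) msg <- c(msg, "jitterSd must be >= 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@backgroundLevel < 0 || object@backgroundLevel > 1)
      msg <- c(msg, "backgroundLevel must lie in [0,1]")
    # a fixed eye must fit inside the frame
    if (!anyNA(object@eyeCenter)) {
      h <- object@imageSize[1]; w <- object@imageSize[2]
      b <- object@eyeAxes[1]; a <- object@eyeAxes[2]
      if (object@eyeCenter[1] - b < 1 || object@eyeCenter[1] + b > h ||
          object@eyeCenter[2] - a < 1 || object@eyeCenter[2] + a > w)
        msg <- c(msg, "eye ellipse must fit inside the image")
    }
    if (is.null(msg)) TRUE else msg
  })

#' @title LabeledEyeImage: a rendered synthetic eye with ground truth
#'
#' @description Output of [renderEye()]: the RGB image plus the phenotype
#' label, the scalar disorder level that generated it, and the true
#' geometry (eye centre, semi-axes, jittered facet centres) for oracle
#' tests.
#'
#' @slot image numeric array `height x width x 3` in [0,1].
#' @slot label character(1), one of [eyeClasses()] (or `""` for
#'   off-grid disorder levels).
#' @slot disorderLevel numeric(1) in [0,1].
#' @slot truth list with `center`, `axes`, `facets` (n x 2 matrix of
#'   `(row, col)` facet centres).
#' @exportClass LabeledEyeImage
setClass("LabeledEyeImage",
  representation(image = "array", label = "character",
                 disorderLevel = "numeric", truth = "list"))
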