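#' IREG severity weights
#'
#' The default weight vector of the regularity index over
#' [eyeClasses()] order `(WT, SCA1, mod1, mod2, mod3)`:
#' `(4, 0, 3, 2, 1) / 4`. Severity increases
#' WT < mod1 < mod2 < mod3 < SCA1, so a pure-class probability vector
#' scores 1, 0.75, 0.5, 0.25 and 0 respectively.
#'
#' @return Named numeric(5) of weights in `[0, 1]`.
#' @export
iregWeights <- function() {
  w <- c(WT = 4, SCA1 = 0, mod1 = 3, mod2 = 2, mod3 = 1) / 4
  w
}

#' Eye regularity index (IREG)
#'
#' Scalar regularity score derived from the posterior class
#' probabilities of one eye:
#' `IREG = (4 P(WT) + 3 P(mod1) + 2 P(mod2) + 1 P(mod3) + 0 P(SCA1)) / 4`,
#' ranging from 0 (total degeneration) to 1 (healthy eye) and linear in
#' the probability vector. Malformed inputs are rejected, not silently
#' renormalised.
#'
#' @param p probability vector (or matrix, one row per eye) over the
#'   five classes; names/colnames must identify the classes when the
#'   order differs from [eyeClasses()].
#' @param weights severity weights over [eyeClasses()] order; default
#'   [iregWeights()].
#' @return Numeric score(s) in `[0, 1]`.
#' @export
#' @examples
#' iregScore(c(WT = 1, SCA1 = 0, mod1 = 0, mod2 = 0, mod3 = 0))  # 1
#' iregScore(c(WT = 0, SCA1 = 0, mod1 = 0, mod2 = 1, mod3 = 0))  # 0.5
iregScore <- function(p, weights = iregWeights()) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1,
                                   dimnames = list(NULL, names(p)))
  if (ncol(p) != length(weights))
    stop("probability vector length must match the weight vector",
         call. = FALSE)
  if (!is.null(colnames(p))) {
    if (!setequal(colnames(p), names(weights)))
      stop("probability names do not match the weighted classes",
           call. = FALSE)
    p <- p[, names(weights), drop = FALSE]
  }
  if (any(p < -1e-12))
    stop("probabilities must be non-negative", call. = FALSE)
  if (any(abs(rowSums(p) - 1) > 1e-6))
    stop("probabilities must sum to 1 (no silent renormalization)",
         call. = FALSE)
  as.numeric(p %*% weights)
}

#' Batch IREG scoring with per-genotype summaries
#'
#' Featurizes a set of eye ROIs, predicts class probabilities with the
#' given classifier, scores each eye with [iregScore()] and summarises
#' the scores per genotype with boxplot statistics (median, quartiles,
#' whiskers at 1.5 IQR, min, max).
#'
#' @param model an [EyeClassifier-class] trained over the five classes.
#' @param patches list of [EyeROI-class] objects (or RGB arrays).
#' @param genotypes grouping label per patch.
#' @param hog HOG parameters, see [hogParams()].
#' @return List with `scores` (data.frame: genotype, probabilities,
#'   ireg) and `summary` (data.frame of per-genotype boxplot
#'   statistics). Empty genotype groups are dropped with a warning.
#' @export
iregBatch <- function(model, patches, genotypes, hog = hogParams()) {
  if (length(patches) != length(genotypes))
    stop("patches and genotypes must be aligned", call. = FALSE)
  feats <- featurizeDataset(patches, labels = genotypes, params = hog)
  probs <- predictProbabilities(model, feats)
  scores <- iregScore(probs)
  gen <- as.factor(genotypes)
  empty <- setdiff(levels(gen), unique(as.character(gen)))
  if (length(empty)) {
    warning("empty genotype group(s) omitted: ",
            paste(empty, collapse = ", "))
    gen <- droplevels(gen)
  }
  summ <- do.call(rbind, lapply(levels(gen), function(g) {
    s <- scores[gen == g]
    qs <- stats::quantile(s, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- qs[3] - qs[1]
    data.frame(genotype = g, n = length(s), min = min(s), q1 = qs[1],
               median = qs[2], q3 = qs[3], max = max(s),
               whiskerLow = min(s[s >= qs[1] - 1.5 * iqr]),
               whiskerHigh = max(s[s <= qs[3] + 1.5 * iqr]))
  }))
  list(scores = data.frame(genotype = gen, probs, ireg = scores),
       summary = summ)
}
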