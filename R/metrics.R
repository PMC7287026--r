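#' @importFrom stats qbeta
#' @importFrom utils read.delim
NULL

#' Confusion matrix (predicted x reference)
#'
#' `counts[i, j]` = number of items predicted as class `i` whose
#' reference label is class `j`.
#'
#' @param pred predicted labels.
#' @param truth reference labels.
#' @param classes class order for rows/columns; defaults to the union of
#'   levels present.
#' @return K x K integer matrix with dimnames
#'   `list(predicted, reference)`.
#' @export
confusionCounts <- function(pred, truth, classes = NULL) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length", call. = FALSE)
  if (is.null(classes))
    classes <- union(levels(as.factor(truth)), levels(as.factor(pred)))
  pred <- as.character(pred); truth <- as.character(truth)
  bad <- setdiff(unique(c(pred, truth)), classes)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  m <- table(factor(pred, levels = classes), factor(truth, levels = classes))
  m <- matrix(as.integer(m), length(classes), length(classes),
              dimnames = list(predicted = classes, reference = classes))
  m
}

#' Accuracy with exact binomial confidence interval
#'
#' Global accuracy `trace/total` of a confusion matrix with the
#' Clopper-Pearson interval:
#' `lower = qbeta(alpha/2, s, n - s + 1)`,
#' `upper = qbeta(1 - alpha/2, s + 1, n - s)`, with the conventional
#' endpoints 0 at `s = 0` and 1 at `s = n`.
#'
#' @param cm square confusion matrix of counts.
#' @param level confidence level (default 0.95).
#' @return Named numeric: `accuracy`, `lower`, `upper`.
#' @export
accuracyCI <- function(cm, level = 0.95) {
  n <- sum(cm)
  if (n < 1) stop("empty confusion matrix", call. = FALSE)
  s <- sum(diag(cm))
  alpha <- 1 - level
  lower <- if (s == 0) 0 else stats::qbeta(alpha / 2, s, n - s + 1)
  upper <- if (s == n) 1 else stats::qbeta(1 - alpha / 2, s + 1, n - s)
  c(accuracy = s / n, lower = lower, upper = upper)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` with observed
#' agreement `po = trace/total` and expected agreement
#' `pe = sum_i row_i * col_i / total^2`.
#'
#' @param cm square confusion matrix of counts.
#' @return Numeric kappa in `[-1, 1]`.
#' @export
cohenKappa <- function(cm) {
  n <- sum(cm)
  if (n < 1) stop("empty confusion matrix", call. = FALSE)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12)
    stop("kappa undefined: expected agreement equals 1 ",
         "(all mass in a single cell)", call. = FALSE)
  (po - pe) / (1 - pe)
}

# rank-based (Mann-Whitney) AUC of scores separating positives from
# negatives; ties count one half
.rankAUC <- function(scoresPos, scoresNeg) {
  nPos <- length(scoresPos); nNeg <- length(scoresNeg)
  r <- rank(c(scoresPos, scoresNeg), ties.method = "average")
  (sum(r[seq_len(nPos)]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Hand-Till multiclass AUC
#'
#' The average over unordered class pairs of the symmetrised two-class
#' rank AUC: for a pair (i, j), `A(i, j) = (A(i|j) + A(j|i)) / 2`, where
#' `A(i|j)` ranks the probability-of-class-i scores of class-i items
#' against class-j items (ties half). The multiclass AUC is
#' `2 / (K (K - 1)) * sum over pairs`, over the pairs with both classes
#' present.
#'
#' @param probs matrix of class probabilities, columns named by class.
#' @param truth reference labels aligned to the rows.
#' @return Numeric multiclass AUC in `[0, 1]`.
#' @references Hand & Till (2001) Mach. Learn. 45:171.
#' @export
handTillAUC <- function(probs, truth) {
  truth <- as.character(truth)
  cls <- colnames(probs)
  present <- cls[cls %in% truth]
  if (length(present) < 2L)
    stop("need at least two classes present in truth", call. = FALSE)
  pairs <- utils::combn(present, 2, simplify = FALSE)
  vals <- vapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    ii <- truth == i; jj <- truth == j
    aij <- .rankAUC(probs[ii, i], probs[jj, i])
    aji <- .rankAUC(probs[jj, j], probs[ii, j])
    (aij + aji) / 2
  }, numeric(1))
  mean(vals)
}

#' Pairwise ROC curve
#'
#' ROC of the probability-of-first-class score restricted to items of the
#' two classes, sweeping all thresholds. The trapezoidal area under the
#' returned curve equals the rank AUC `A(i|j)` used by [handTillAUC()].
#'
#' @param probs matrix of class probabilities, columns named by class.
#' @param truth reference labels aligned to the rows.
#' @param pair character(2): the (positive, negative) class pair.
#' @return data.frame with columns `fpr` and `tpr`, monotone from (0,0)
#'   to (1,1), plus an `auc` attribute.
#' @export
pairwiseROC <- function(probs, truth, pair) {
  truth <- as.character(truth)
  i <- pair[1]; j <- pair[2]
  ii <- truth == i; jj <- truth == j
  if (!any(ii) || !any(jj))
    stop("both classes of the pair must be present", call. = FALSE)
  sc <- c(probs[ii, i], probs[jj, i])
  lab <- c(rep(TRUE, sum(ii)), rep(FALSE, sum(jj)))
  ord <- order(sc, decreasing = TRUE)
  sc <- sc[ord]; lab <- lab[ord]
  # group tied scores into single threshold steps
  steps <- c(which(diff(sc) != 0), length(sc))
  tp <- cumsum(lab)[steps]; fp <- cumsum(!lab)[steps]
  tpr <- c(0, tp / sum(lab)); fpr <- c(0, fp / sum(!lab))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a trained classifier on labelled features
#'
#' Composes probability prediction, argmax labelling, the confusion
#' matrix, accuracy with its exact binomial interval, Cohen's kappa, the
#' Hand-Till multiclass AUC and the full pairwise AUC table.
#'
#' @param model an [EyeClassifier-class].
#' @param features a labelled [EyeFeatures-class] test set.
#' @param level confidence level of the accuracy interval.
#' @return An [EyeEvalReport-class].
#' @export
evaluateClassifier <- function(model, features, level = 0.95) {
  stopifnot(is(features, "EyeFeatures"))
  probs <- predictProbabilities(model, features)
  pred <- colnames(probs)[max.col(probs, ties.method = "first")]
  truth <- as.character(features@labels)
  cm <- confusionCounts(pred, truth, classes = model@classOrder)
  acc <- accuracyCI(cm, level)
  K <- length(model@classOrder)
  pw <- matrix(NA_real_, K, K,
               dimnames = list(model@classOrder, model@classOrder))
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    ca <- model@classOrder[a]; cb <- model@classOrder[b]
    if (any(truth == ca) && any(truth == cb)) {
      aij <- .rankAUC(probs[truth == ca, ca], probs[truth == cb, ca])
      aji <- .rankAUC(probs[truth == cb, cb], probs[truth == ca, cb])
      pw[a, b] <- pw[b, a] <- (aij + aji) / 2
    }
  }
  new("EyeEvalReport", confusion = cm, accuracy = unname(acc["accuracy"]),
      accuracyCI = unname(acc[c("lower", "upper")]), kappa = cohenKappa(cm),
      mAUC = handTillAUC(probs, truth), pairwiseAUC = pw)
}

#' Published benchmark confusion matrices
#'
#' The test-set confusion matrices of the four classical classifiers
#' (RBF-kernel SVM, decision tree, AdaBoost decision tree, 1000-tree
#' random forest) on the five-phenotype rough-eye benchmark (75 test
#' images; reference counts 20 WT, 11 SCA1, 13 mod1, 15 mod2, 16 mod3),
#' shipped as plain text under `inst/extdata`. Useful for exercising the
#' evaluation metrics without any image data.
#'
#' @return Named list of four 5 x 5 integer matrices
#'   (`svm_rbf`, `dt`, `adaboost_dt`, `rf`), rows = predicted,
#'   columns = reference, classes in [eyeClasses()] order.
#' @export
referenceConfusionMatrices <- function() {
  path <- system.file("extdata", "benchmark_confusion_counts.tsv",
                      package = "ommaQuant", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  cls <- eyeClasses()
  out <- lapply(c("svm_rbf", "dt", "adaboost_dt", "rf"), function(k) {
    m <- matrix(0L, 5, 5, dimnames = list(predicted = cls, reference = cls))
    m[cbind(match(tab$predicted, cls), match(tab$reference, cls))] <-
      as.integer(tab[[k]])
    m
  })
  names(out) <- c("svm_rbf", "dt", "adaboost_dt", "rf")
  out
}
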