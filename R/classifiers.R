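#' @importFrom e1071 svm
#' @importFrom rpart rpart rpart.control
#' @importFrom randomForest randomForest
#' @importFrom stats predict
NULL

#' Stratified train/test split
#'
#' Splits row indices so that every class keeps the target training
#' fraction: per class with `n_c` members, `ceil(trainFrac * n_c)` rows
#' go to training and the rest to test, drawn uniformly at random under
#' the seed. With the study's class sizes (82, 44, 55, 62, 65) and the
#' default 0.75 this yields test counts (20, 11, 13, 15, 16).
#'
#' @param labels class label per row (factor or character).
#' @param trainFrac training fraction in (0,1); default 0.75.
#' @param seed integer seed; the split is reproducible given
#'   `(labels, trainFrac, seed)`.
#' @return List with integer vectors `train` and `test` and the `seed`.
#' @export
stratifiedSplit <- function(labels, trainFrac = 0.75, seed) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (any(tab < 2L))
    stop("stratification error: every class needs at least 2 members",
         call. = FALSE)
  set.seed(as.integer(seed))
  train <- integer(0)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    nTrain <- ceiling(trainFrac * length(idx))
    train <- c(train, sort(sample(idx, nTrain)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train),
       seed = as.integer(seed))
}

# stratified k-fold assignment (1..k per row), deterministic under seed
.stratifiedFolds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  if (min(table(labels)) < k)
    stop("k exceeds the smallest class count; cannot stratify folds",
         call. = FALSE)
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.defaultGrids <- list(
  svm_rbf = expand.grid(sigma = c(0.0005, 0.001, 0.005, 0.01, 0.05),
                        C = c(0.25, 0.5, 1, 2, 4)),
  dt = expand.grid(maxdepth = c(2, 4, 8, 16, 30)),
  adaboost_dt = expand.grid(nRounds = c(10, 25, 50), maxdepth = c(1, 2, 4)),
  rf = expand.grid(mtry = c(5, 11, 22), nTrees = 1000)
)

# complexity ordering for tie-breaks: smaller C, then smaller sigma;
# smaller depth/rounds/mtry elsewhere
.gridComplexityOrder <- function(kind, grid) {
  switch(kind,
    svm_rbf = order(grid$C, grid$sigma),
    dt = order(grid$maxdepth),
    adaboost_dt = order(grid$nRounds, grid$maxdepth),
    rf = order(grid$mtry),
    seq_len(nrow(grid)))
}

#' Grid search by stratified k-fold cross-validation
#'
#' Evaluates every hyperparameter combination by mean held-out accuracy
#' over a stratified k-fold partition of the training data, and returns
#' the maximiser; ties are broken toward the lowest-complexity
#' parameters (for the SVM: smaller cost, then smaller sigma).
#'
#' @param features an [EyeFeatures-class] (the training portion).
#' @param kind classifier kind, see [trainClassifier()].
#' @param grid data.frame of hyperparameter combinations; `NULL` uses a
#'   built-in default grid (the SVM grid contains cost 1, sigma 0.005).
#' @param k folds (default 10); must not exceed the smallest class count.
#' @param seed integer seed controlling fold assignment and fits.
#' @return List with `best` (named hyperparameter list), `accuracy` (its
#'   mean CV accuracy) and `table` (the grid with a `cvAccuracy` column).
#' @export
cvGridSearch <- function(features, kind, grid = NULL, k = 10L, seed = 1L) {
  stopifnot(is(features, "EyeFeatures"))
  if (is.null(grid)) grid <- .defaultGrids[[kind]]
  if (is.null(grid)) stop("unknown classifier kind: ", kind, call. = FALSE)
  labels <- droplevels(features@labels)
  fold <- .stratifiedFolds(labels, k, seed)
  X <- features@features
  acc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    hyper <- as.list(grid[gi, , drop = FALSE])
    hits <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      fitFeat <- new("EyeFeatures", features = X[tr, , drop = FALSE],
                     labels = droplevels(labels[tr]),
                     source = features@source[tr])
      model <- trainClassifier(fitFeat, kind, hyper = hyper,
                               seed = seed + f)
      pr <- predictProbabilities(model, X[!tr, , drop = FALSE])
      pred <- colnames(pr)[max.col(pr, ties.method = "first")]
      hits <- hits + sum(pred == as.character(labels[!tr]))
    }
    acc[gi] <- hits / length(labels)
  }
  ord <- .gridComplexityOrder(kind, grid)
  bestPos <- ord[which.max(acc[ord])]
  out <- grid
  out$cvAccuracy <- acc
  list(best = as.list(grid[bestPos, , drop = FALSE]),
       accuracy = acc[bestPos], table = out)
}

#' Train a phenotype classifier on HOG features
#'
#' Fits one of the four classical learners on a labelled feature matrix:
#' \describe{
#'   \item{`svm_rbf`}{support vector machine with Gaussian radial basis
#'     kernel `exp(-sigma * ||u - v||^2)` (so `sigma` is the kernel
#'     width parameter; defaults `C = 1`, `sigma = 0.005`), with
#'     probability estimates enabled.}
#'   \item{`dt`}{a single CART decision tree.}
#'   \item{`adaboost_dt`}{boosted decision trees (multiclass AdaBoost,
#'     SAMME) over CART base learners.}
#'   \item{`rf`}{random forest, 1000 trees by default.}
#' }
#'
#' @param features an [EyeFeatures-class] with at least two classes.
#' @param kind `"svm_rbf"`, `"dt"`, `"adaboost_dt"` or `"rf"`.
#' @param hyper named list of hyperparameters overriding the defaults
#'   (`C`, `sigma`; `maxdepth`; `nRounds`, `maxdepth`; `nTrees`, `mtry`).
#' @param seed integer seed; identical data and seed give identical fits.
#' @return An [EyeClassifier-class].
#' @export
trainClassifier <- function(features, kind, hyper = list(), seed = 1L) {
  stopifnot(is(features, "EyeFeatures"))
  X <- features@features
  y <- droplevels(features@labels)
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  if (nlevels(y) < 2L)
    stop("training set must contain at least two classes", call. = FALSE)
  if (nrow(X) < nlevels(y))
    stop("fewer rows than classes", call. = FALSE)
  colnames(X) <- paste0("V", seq_len(ncol(X)))  # canonical names for
  seed <- as.integer(seed)                      # formula-based learners
  set.seed(seed)
  fit <- switch(kind,
    svm_rbf = {
      C <- hyper$C %||% 1
      sigma <- hyper$sigma %||% 0.005
      hyper <- list(C = C, sigma = sigma)
      e1071::svm(X, y, type = "C-classification", kernel = "radial",
                 gamma = sigma, cost = C, probability = TRUE, scale = FALSE)
    },
    dt = {
      maxdepth <- hyper$maxdepth %||% 30
      hyper <- list(maxdepth = maxdepth)
      df <- data.frame(y = y, X)
      rpart::rpart(y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxdepth = maxdepth,
                                                  xval = 0))
    },
    adaboost_dt = {
      nRounds <- hyper$nRounds %||% 50
      maxdepth <- hyper$maxdepth %||% 2
      hyper <- list(nRounds = nRounds, maxdepth = maxdepth)
      .fitSAMME(X, y, nRounds = nRounds, maxdepth = maxdepth)
    },
    rf = {
      nTrees <- hyper$nTrees %||% 1000
      mtry <- hyper$mtry %||% max(1L, floor(sqrt(ncol(X))))
      hyper <- list(nTrees = nTrees, mtry = mtry)
      randomForest::randomForest(X, y, ntree = nTrees, mtry = mtry)
    },
    stop("unknown classifier kind: ", kind, call. = FALSE))
  new("EyeClassifier", kind = kind, fit = fit, classOrder = levels(y),
      featureDim = ncol(X), hyper = hyper, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior class probabilities
#'
#' Predicts the per-class probability for each feature row, with columns
#' in the classifier's fixed class order; rows sum to 1.
#'
#' @param model an [EyeClassifier-class].
#' @param features an [EyeFeatures-class] or bare numeric matrix with
#'   `featureDim` columns.
#' @return Numeric matrix, one row per input row, one column per class.
#' @export
predictProbabilities <- function(model, features) {
  X <- if (is(features, "EyeFeatures")) features@features else features
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != model@featureDim)
    stop("feature dimension mismatch: expected ", model@featureDim,
         " columns", call. = FALSE)
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  cls <- model@classOrder
  p <- switch(model@kind,
    svm_rbf = {
      pr <- stats::predict(model@fit, X, probability = TRUE)
      attr(pr, "probabilities")
    },
    dt = stats::predict(model@fit, data.frame(X), type = "prob"),
    adaboost_dt = .predictSAMME(model@fit, X),
    rf = stats::predict(model@fit, X, type = "prob"))
  p <- p[, cls, drop = FALSE]
  p <- p / rowSums(p)
  rownames(p) <- NULL
  p
}

#' Hard class predictions
#'
#' Argmax of [predictProbabilities()] (first class wins exact ties).
#'
#' @inheritParams predictProbabilities
#' @return Factor of predicted classes with levels = the class order.
#' @export
predictClasses <- function(model, features) {
  p <- predictProbabilities(model, features)
  factor(colnames(p)[max.col(p, ties.method = "first")],
         levels = model@classOrder)
}
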