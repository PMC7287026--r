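test_that("stratified split follows the per-class ceiling rule", {
  sizes <- c(WT = 82, SCA1 = 44, mod1 = 55, mod2 = 62, mod3 = 65)
  labels <- factor(rep(names(sizes), sizes), levels = names(sizes))
  sp <- stratifiedSplit(labels, 0.75, seed = 123)
  testCounts <- table(labels[sp$test])
  expect_equal(as.integer(testCounts), c(20L, 11L, 13L, 15L, 16L))
  expect_length(sp$test, 75L)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0L)
  # 4 items at 0.75 -> 3 train / 1 test
  sp4 <- stratifiedSplit(rep("x", 4), 0.75, seed = 1)
  expect_length(sp4$train, 3L)
  # determinism
  spA <- stratifiedSplit(labels, 0.75, seed = 99)
  spB <- stratifiedSplit(labels, 0.75, seed = 99)
  expect_identical(spA, spB)
  expect_error(stratifiedSplit(c("a", "a", "b"), 0.75, seed = 1),
               "at least 2")
})

test_that("grid search returns the CV-best, lowest-complexity point", {
  feats <- blobFeatures(12, classes = c("a", "b"), seed = 2)
  one <- cvGridSearch(feats, "svm_rbf",
                      grid = data.frame(sigma = 0.005, C = 1),
                      k = 4, seed = 5)
  expect_equal(one$best$C, 1)
  expect_equal(one$best$sigma, 0.005)
  # separable toy data: an adequate grid point reaches CV accuracy 1
  res <- cvGridSearch(feats, "svm_rbf",
                      grid = expand.grid(sigma = c(0.005, 0.1),
                                         C = c(1, 4)),
                      k = 4, seed = 5)
  expect_equal(res$accuracy, 1)
  expect_error(cvGridSearch(feats, "svm_rbf", k = 50, seed = 1),
               "smallest class")
})

test_that("classifiers fit, predict probabilities and are reproducible", {
  feats <- blobFeatures(15, classes = c("a", "b", "c"), d = 6, seed = 3)
  test <- blobFeatures(5, classes = c("a", "b", "c"), d = 6, seed = 4)
  for (kind in c("svm_rbf", "dt", "adaboost_dt", "rf")) {
    hyper <- if (kind == "rf") list(nTrees = 100) else list()
    m <- trainClassifier(feats, kind, hyper = hyper, seed = 11)
    p <- predictProbabilities(m, test)
    expect_identical(colnames(p), m@classOrder)
    expect_true(all(abs(rowSums(p) - 1) < 1e-9))
    expect_true(all(p >= 0))
    acc <- mean(as.character(predictClasses(m, test)) ==
                  as.character(eyeLabels(test)))
    expect_gte(acc, 0.95)       # blobs are trivially separable
    # determinism under the seed
    m2 <- trainClassifier(feats, kind, hyper = hyper, seed = 11)
    expect_equal(predictProbabilities(m2, test), p, tolerance = 1e-12)
  }
  oneClass <- makeFeatures(matrix(rnorm(20), 10, 2), rep("a", 10))
  expect_error(trainClassifier(oneClass, "svm_rbf"), "two classes")
  expect_error(trainClassifier(feats, "nonsense"), "unknown")
})

test_that("probability prediction validates dimensions and order", {
  feats <- blobFeatures(10, seed = 6)
  m <- trainClassifier(feats, "svm_rbf", seed = 1)
  expect_error(predictProbabilities(m, matrix(0, 2, 99)), "mismatch")
  X <- featureMatrix(blobFeatures(4, seed = 7))
  p <- predictProbabilities(m, X)
  perm <- c(3, 1, 4, 2, 5:8)
  expect_equal(predictProbabilities(m, X[perm, ]), p[perm, ],
               tolerance = 1e-12)
})

test_that("the RBF kernel uses the exp(-sigma d^2) parameterisation", {
  # one support-vector-ish check: with huge sigma the kernel collapses and
  # test points far from training data get near-uniform probabilities
  feats <- blobFeatures(10, classes = c("a", "b"), d = 2, sepScale = 3,
                        seed = 8)
  m <- trainClassifier(feats, "svm_rbf", hyper = list(C = 1, sigma = 1e6),
                       seed = 1)
  far <- matrix(c(100, 100), 1, 2)
  p <- predictProbabilities(m, far)
  expect_lt(abs(p[1, 1] - p[1, 2]), 0.2)
})
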