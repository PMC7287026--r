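test_that("confusion matrix counts predicted x reference", {
  cls <- letters[1:3]
  pred <- c("a", "a", "b", "c", "c", "c")
  cm <- confusionCounts(pred, pred, classes = cls)
  expect_equal(sum(diag(cm)), 6L)
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  truth <- rep(eyeClasses(), each = 5)
  allWT <- confusionCounts(rep("WT", 25), truth, classes = eyeClasses())
  expect_equal(unname(allWT["WT", ]), rep(5L, 5))
  expect_equal(sum(allWT[-1, ]), 0L)
  expect_error(confusionCounts(c("a", "zz"), c("a", "a"), classes = cls),
               "unknown")
  expect_error(confusionCounts("a", c("a", "b")), "equal length")
})

test_that("benchmark confusion matrices load with the published layout", {
  cms <- referenceConfusionMatrices()
  expect_named(cms, c("svm_rbf", "dt", "adaboost_dt", "rf"))
  for (cm in cms) {
    expect_equal(unname(colSums(cm)), c(20L, 11L, 13L, 15L, 16L))
    expect_equal(sum(cm), 75L)
  }
  expect_equal(unname(diag(cms$svm_rbf)), c(20L, 11L, 12L, 14L, 16L))
})

test_that("exact binomial interval matches closed forms and binom.test", {
  cms <- referenceConfusionMatrices()
  acc <- accuracyCI(cms$svm_rbf)
  expect_equal(unname(round(acc, 3)), c(0.973, 0.907, 0.997))
  ten <- accuracyCI(diag(c(5, 5)))
  expect_equal(unname(ten), c(1, 0.025^(1 / 10), 1), tolerance = 1e-10)
  none <- accuracyCI(matrix(c(0, 5, 0, 0), 2, 2))
  expect_equal(unname(none), c(0, 0, 1 - 0.025^(1 / 5)), tolerance = 1e-10)
  expect_equal(unname(round(none, 4))[3], 0.5218)
  bt <- binom.test(73, 75)$conf.int
  expect_equal(unname(accuracyCI(cms$svm_rbf)[2:3]), as.numeric(bt),
               tolerance = 1e-10)
  expect_error(accuracyCI(matrix(0, 2, 2)), "empty")
})

test_that("Cohen's kappa from the formula, including edge cases", {
  cms <- referenceConfusionMatrices()
  expect_equal(round(vapply(cms, cohenKappa, numeric(1)), 3),
               c(svm_rbf = 0.966, dt = 0.560, adaboost_dt = 0.711,
                 rf = 0.847))
  expect_equal(cohenKappa(diag(c(3, 7))), 1)
  # single predicted class over uniform truth: chance-level agreement
  uni <- matrix(0, 4, 4); uni[1, ] <- 6
  expect_equal(cohenKappa(uni), 0)
  expect_error(cohenKappa(matrix(c(9, 0, 0, 0), 2, 2)), "undefined")
})

test_that("published accuracies are recovered from the count tables", {
  cms <- referenceConfusionMatrices()
  expect_equal(round(vapply(cms, function(m) accuracyCI(m)[["accuracy"]],
                            numeric(1)), 3),
               c(svm_rbf = 0.973, dt = 0.653, adaboost_dt = 0.773,
                 rf = 0.880))
})

test_that("Hand-Till mAUC: perfection, chance, and the 2-class oracle", {
  cls <- c("x", "y", "z")
  truth <- rep(cls, each = 4)
  perfect <- do.call(rbind, lapply(truth, function(t) {
    p <- c(x = 0.01, y = 0.01, z = 0.01); p[t] <- 0.98; p
  }))
  expect_equal(handTillAUC(perfect, truth), 1)
  # label-independent scores average 0.5 over permutations
  set.seed(10)
  probs <- matrix(runif(60), 20, 3, dimnames = list(NULL, cls))
  probs <- probs / rowSums(probs)
  m <- replicate(1000, handTillAUC(probs, sample(rep(cls, c(8, 6, 6)))))
  expect_lt(abs(mean(m) - 0.5), 0.02)
  # K = 2 equals brute-force pair counting (ties counted half)
  set.seed(11)
  sc <- round(runif(30), 1)
  lab <- sample(c("p", "n"), 30, replace = TRUE, prob = c(0.4, 0.6))
  P <- cbind(p = sc, n = 1 - sc)
  pos <- sc[lab == "p"]; neg <- sc[lab == "n"]
  brute <- mean(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(handTillAUC(P, lab), brute, tolerance = 1e-12)
  # invariant under strictly monotone transforms of the scores
  P2 <- cbind(p = exp(3 * sc), n = exp(3 * (1 - sc)))
  expect_equal(handTillAUC(P2, lab), handTillAUC(P, lab))
  expect_error(handTillAUC(P, rep("p", 30)), "two classes")
})

test_that("pairwise ROC is monotone and its area matches the rank AUC", {
  set.seed(12)
  cls <- c("u", "v")
  truth <- sample(cls, 40, replace = TRUE)
  sc <- ifelse(truth == "u", runif(40, 0.3, 1), runif(40, 0, 0.7))
  P <- cbind(u = sc, v = 1 - sc)
  roc <- pairwiseROC(P, truth, c("u", "v"))
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[nrow(roc)], 1)
  pos <- sc[truth == "u"]; neg <- sc[truth == "v"]
  brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(attr(roc, "auc"), brute, tolerance = 1e-9)
  expect_equal(as.numeric(suppressMessages(
    pROC::auc(truth == "u", sc, direction = "<"))), attr(roc, "auc"),
    tolerance = 1e-9)
  # degenerate: identical scores give the chance diagonal
  flat <- pairwiseROC(cbind(u = rep(0.5, 40), v = 0.5), truth, c("u", "v"))
  expect_equal(attr(flat, "auc"), 0.5)
  # perfect separation passes through (0, 1)
  sep <- cbind(u = ifelse(truth == "u", 0.9, 0.1), v = 0)
  rocSep <- pairwiseROC(sep, truth, c("u", "v"))
  expect_true(any(rocSep$fpr == 0 & rocSep$tpr == 1))
  expect_error(pairwiseROC(P, rep("u", 40), c("u", "v")), "present")
})

test_that("Clopper-Pearson interval keeps nominal coverage", {
  set.seed(13)
  n <- 75; p <- 0.97
  s <- rbinom(10000, n, p)
  lower <- ifelse(s == 0, 0, qbeta(0.025, s, n - s + 1))
  upper <- ifelse(s == n, 1, qbeta(0.975, s + 1, n - s))
  expect_gte(mean(lower <= p & p <= upper), 0.95)
})

test_that("evaluateClassifier composes the metrics consistently", {
  feats <- blobFeatures(12, classes = c("a", "b", "c"), seed = 14)
  m <- trainClassifier(feats, "svm_rbf", hyper = list(sigma = 0.2), seed = 2)
  ev <- evaluateClassifier(m, feats)     # evaluate on training data
  expect_equal(ev@accuracy, sum(diag(ev@confusion)) / sum(ev@confusion))
  expect_equal(ev@accuracy, 1)
  expect_equal(ev@kappa, 1)
  expect_equal(ev@mAUC, 1)
  expect_true(isSymmetric(unname(ev@pairwiseAUC)))
  # shuffled labels: agreement indistinguishable from chance
  set.seed(15)
  shuffled <- makeFeatures(featureMatrix(feats),
                           sample(eyeLabels(feats)))
  m0 <- trainClassifier(shuffled, "dt", seed = 2)
  ev0 <- evaluateClassifier(m0, blobFeatures(12, classes = c("a", "b", "c"),
                                             seed = 16))
  expect_lt(abs(ev0@kappa), 0.35)
  expect_lt(abs(ev0@mAUC - 0.5), 0.25)
})
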