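# Multiclass AdaBoost (SAMME; Zhu et al. 2009) over CART base learners.
# Written in-package because no boosting provider ships with the
# dependency stack; the algorithm is the standard stagewise additive
# model with the multiclass (K - 1)-shifted learner weight.

.fitSAMME <- function(X, y, nRounds = 50L, maxdepth = 2L) {
  n <- nrow(X)
  K <- nlevels(y)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  df <- data.frame(y = y, X)
  for (m in seq_len(nRounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = maxdepth,
                                                       xval = 0, cp = -1,
                                                       minsplit = 4,
                                                       minbucket = 2))
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / K) break          # worse than chance: stop boosting
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    learners[[length(learners) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err < 1e-10) break               # perfect learner: nothing to reweight
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  if (length(learners) == 0L) {          # fall back to the plain tree
    learners <- list(rpart::rpart(y ~ ., data = df, method = "class",
                                  control = rpart::rpart.control(
                                    maxdepth = maxdepth, xval = 0)))
    alphas <- 1
  }
  structure(list(learners = learners, alphas = alphas, classes = levels(y)),
            class = "sammeBoost")
}

.predictSAMME <- function(fit, X) {
  df <- data.frame(X)
  K <- length(fit$classes)
  score <- matrix(0, nrow(df), K, dimnames = list(NULL, fit$classes))
  for (m in seq_along(fit$learners)) {
    pred <- stats::predict(fit$learners[[m]], df, type = "class")
    score[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      score[cbind(seq_len(nrow(df)), as.integer(pred))] + fit$alphas[m]
  }
  # weighted-vote scores -> probabilities (softmax-free normalisation)
  p <- score / pmax(rowSums(score), 1e-12)
  p
}
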