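# shared helpers: tiny constructors used across test files

makeFeatures <- function(X, y) {
  new("EyeFeatures", features = X,
      labels = if (is.factor(y)) y else factor(y),
      source = rep("", nrow(X)))
}

subsetFeatures <- function(feats, idx) {
  new("EyeFeatures", features = featureMatrix(feats)[idx, , drop = FALSE],
      labels = droplevels(eyeLabels(feats)[idx]),
      source = rep("", length(idx)))
}

# two well-separated Gaussian blobs per class in d dimensions
blobFeatures <- function(nPerClass, classes = c("a", "b"), d = 5,
                         sepScale = 10, seed = 1) {
  set.seed(seed)
  X <- NULL; y <- character(0)
  for (k in seq_along(classes)) {
    mu <- rep(0, d); mu[k] <- sepScale
    X <- rbind(X, matrix(rnorm(nPerClass * d, 0, 0.5), nPerClass, d) +
                 matrix(mu, nPerClass, d, byrow = TRUE))
    y <- c(y, rep(classes[k], nPerClass))
  }
  makeFeatures(X, factor(y))
}

# independent grid-refinement minimiser of the distance-sum objective;
# shrinks the search window around the best grid point down to a
# resolution below `res`
gridL1Median <- function(points, res = 0.01) {
  obj <- function(r, c) {
    colSums(sqrt(outer(points[, 1], r, `-`)^2 +
                 outer(points[, 2], c, `-`)^2))
  }
  lo <- apply(points, 2, min); hi <- apply(points, 2, max)
  span <- max(hi - lo, 1)
  repeat {
    rs <- seq(lo[1], hi[1], length.out = 41)
    cs <- seq(lo[2], hi[2], length.out = 41)
    vals <- outer(rs, cs, function(r, c)
      vapply(seq_along(r), function(i)
        sum(sqrt((points[, 1] - r[i])^2 + (points[, 2] - c[i])^2)),
        numeric(1)))
    best <- arrayInd(which.min(vals), dim(vals))
    ctr <- c(rs[best[1]], cs[best[2]])
    step <- max(rs[2] - rs[1], cs[2] - cs[1])
    if (step < res) return(ctr)
    lo <- ctr - 2 * step; hi <- ctr + 2 * step
  }
}
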