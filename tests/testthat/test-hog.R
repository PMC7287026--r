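test_that("gradient field follows centred differences with folding", {
  g <- computeGradient(matrix(0.4, 12, 12))
  expect_true(all(g$magnitude == 0))
  # vertical step edge: response only in the straddling columns, at 0 deg
  x <- matrix(0, 10, 10); x[, 6:10] <- 1
  g <- computeGradient(x)
  hot <- g$magnitude > 0
  expect_true(all(which(colSums(hot) > 0) %in% 5:6))
  expect_true(all(g$orientation[hot] == 0))
  # magnitudes are linear in intensity
  set.seed(3)
  y <- matrix(runif(64, 0, 0.5), 8, 8)
  g1 <- computeGradient(y); g2 <- computeGradient(2 * y)
  expect_equal(g2$magnitude, 2 * g1$magnitude, tolerance = 1e-12)
  expect_true(all(g1$orientation >= 0 & g1$orientation < 180))
  expect_error(computeGradient(matrix(0, 2, 5)), "3 x 3")
})

test_that("descriptor length equals cells^2 * orientations", {
  set.seed(4)
  img <- matrix(runif(200 * 200), 200, 200)
  expect_length(hogDescriptor(img), 125)
  expect_length(hogDescriptor(img, hogParams(cells = 3, nOrientations = 7)),
                63)
  expect_length(hogDescriptor(img, hogParams(cells = 1, nOrientations = 1)),
                1)
  expect_error(hogDescriptor(matrix(0, 3, 3), hogParams(cells = 5)),
               "smaller")
})

test_that("constant images give the all-zero descriptor", {
  expect_true(all(hogDescriptor(matrix(0.7, 50, 50)) == 0))
})

test_that("a horizontal grating concentrates mass in the 90-degree bin", {
  r <- matrix(seq_len(60), 60, 60)
  grating <- 0.5 + 0.4 * sin(2 * pi * r / 8)   # varies along rows only
  d <- hogDescriptor(grating)
  cells <- matrix(d, nrow = 25, byrow = TRUE)  # cell x bin
  # bin containing 90 deg is the third of five (72-108)
  interior <- as.vector(outer(2:4, 2:4, function(i, j) (i - 1) * 5 + j))
  for (cell in interior)
    expect_gte(cells[cell, 3] / sum(cells[cell, ]), 0.95)
})

test_that("descriptor is invariant to intensity scale and shift", {
  set.seed(5)
  img <- matrix(runif(80 * 80, 0.2, 0.6), 80, 80)
  expect_equal(hogDescriptor(img), hogDescriptor(img * 0.5),
               tolerance = 1e-6)
  expect_equal(hogDescriptor(img), hogDescriptor(img + 0.3),
               tolerance = 1e-6)
})

test_that("quarter rotation permutes orientation bins on gratings", {
  r <- matrix(seq_len(60), 60, 60)
  horiz <- 0.5 + 0.4 * sin(2 * pi * r / 8)     # gradient at 90 deg
  vert <- t(horiz)                             # gradient at 0 deg
  binShare <- function(img) {
    cells <- matrix(hogDescriptor(img), nrow = 25, byrow = TRUE)
    colSums(cells) / sum(cells)
  }
  sH <- binShare(horiz); sV <- binShare(vert)
  expect_gt(sH[3], 0.9)     # 90 deg lives in bin 3
  expect_gt(sV[1], 0.9)     # 0 deg lives in bin 1
})

test_that("raw histogram mass is conserved without normalisation", {
  set.seed(6)
  img <- matrix(runif(45 * 55), 45, 55)
  d <- hogDescriptor(img, hogParams(normalize = FALSE))
  g <- computeGradient(img)
  expect_equal(sum(d), sum(g$magnitude), tolerance = 1e-9)
  # per-cell norm is bounded by 1 once normalised
  dn <- matrix(hogDescriptor(img), nrow = 25, byrow = TRUE)
  expect_true(all(sqrt(rowSums(dn^2)) <= 1 + 1e-9))
})

test_that("featurizeDataset assembles aligned labelled rows", {
  empty <- featurizeDataset(list())
  expect_equal(nrow(featureMatrix(empty)), 0L)
  set.seed(8)
  patches <- replicate(4, array(runif(30 * 30 * 3), c(30, 30, 3)),
                       simplify = FALSE)
  patches[[4]] <- patches[[1]]
  fm <- featurizeDataset(patches, labels = c("a", "b", "a", "b"))
  expect_identical(dim(featureMatrix(fm)), c(4L, 125L))
  expect_equal(featureMatrix(fm)[1, ], featureMatrix(fm)[4, ])
  expect_error(featurizeDataset(patches, labels = c("a", "b")), "aligned")
})
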