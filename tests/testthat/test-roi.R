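test_that("disc kernel matches brute-force membership counts", {
  expect_identical(discKernel(1), matrix(1L, 1, 1))
  k3 <- discKernel(3)
  expect_equal(sum(k3), 5)                       # plus shape
  expect_equal(k3[2, ], c(1L, 1L, 1L))
  expect_equal(diag(k3), c(0L, 1L, 0L))
  for (size in c(5L, 7L, 9L, 13L)) {
    r <- (size - 1) / 2
    brute <- 0L
    for (i in seq_len(size)) for (j in seq_len(size))
      if ((i - 1 - r)^2 + (j - 1 - r)^2 <= r^2) brute <- brute + 1L
    expect_equal(sum(discKernel(size)), brute)
  }
  expect_equal(sum(discKernel(9)), 49)
  expect_error(discKernel(4), "odd")
  expect_error(discKernel(-3), "odd")
})

test_that("white top-hat removes large structures and keeps small ones", {
  k <- discKernel(9)
  expect_true(all(whiteTophat(matrix(0.6, 40, 40), k) == 0))
  # isolated bright pixel is smaller than the kernel: it survives intact
  x <- matrix(0, 30, 30); x[15, 12] <- 1
  wt <- whiteTophat(x, k)
  expect_equal(wt[15, 12], 1)
  # wide plateau: interior flattened to zero (oracle: erosion + dilation)
  y <- matrix(0, 80, 80); y[16:65, 16:65] <- 0.8
  opened <- EBImage::dilate(EBImage::erode(y, k), k)
  expect_equal(whiteTophat(y, k), pmin(pmax(y - opened, 0), 1),
               tolerance = 1e-12)
  expect_equal(whiteTophat(y, k)[40, 40], 0)
  # per-channel on RGB
  rgb <- array(0.6, c(40, 40, 3))
  expect_true(all(whiteTophat(rgb, k) == 0))
  expect_error(whiteTophat(matrix(0, 5, 5), k), "larger")
})

test_that("bright-pixel selection applies a strict type-7 quantile", {
  expect_error(selectBrightPixels(matrix(0.5, 10, 10)), "degenerate")
  x <- matrix(0, 100, 100); x[40, 60] <- 1
  sel <- selectBrightPixels(x, 0.99)
  expect_equal(nrow(sel$coords), 1L)
  expect_equal(unname(sel$coords[1, ]), c(40, 60))
  # equally spaced distinct ramp: exactly the strictly-above pixels
  v <- seq(0, 1, length.out = 10000)
  ramp <- matrix(v, 100, 100)
  sel <- selectBrightPixels(ramp, 0.99)
  thr <- quantile(v, 0.99, type = 7)
  # brute-force oracle: exactly the strictly-above pixels (here 100: the
  # interpolated threshold falls between the 9900th and 9901st value)
  expect_equal(nrow(sel$coords), sum(v > thr))
  expect_equal(nrow(sel$coords), 100L)
  expect_true(all(sel$intensity > thr))
})

test_that("lowering the intensity quantile never loses pixels", {
  img <- renderEye(eyeSpec(eyeCenter = c(120, 160)), seed = 5)
  g <- rgbToGray(whiteTophat(img@image, discKernel(9)))
  counts <- vapply(c(0.995, 0.99, 0.97, 0.9, 0.8),
                   function(q) nrow(selectBrightPixels(g, q)$coords),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("Weiszfeld L1-median matches closed forms and brute force", {
  expect_equal(l1Median(cbind(3, 7)), c(3, 7))
  expect_equal(l1Median(cbind(c(0, 1, 10), 4)), c(1, 4), tolerance = 1e-4)
  sq <- rbind(c(0, 0), c(0, 2), c(2, 0), c(2, 2))
  expect_equal(l1Median(sq), c(1, 1), tolerance = 1e-6)
  # a data point may itself be the median (Vardi-Zhang branch)
  star <- rbind(c(5, 5), c(5, 9), c(5, 1), c(1, 5), c(9, 5))
  expect_equal(l1Median(star), c(5, 5), tolerance = 1e-6)
  set.seed(42)
  for (rep in 1:20) {
    pts <- matrix(runif(2 * sample(3:20, 1), 0, 100), ncol = 2)
    est <- l1Median(pts)
    ref <- gridL1Median(pts, res = 0.005)
    obj <- function(p) sum(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2))
    expect_lt(abs(obj(est) - obj(ref)), 0.05)
    # within the convex hull (bounding box is a necessary condition)
    expect_true(all(est >= apply(pts, 2, min) - 1e-6))
    expect_true(all(est <= apply(pts, 2, max) + 1e-6))
  }
  expect_error(l1Median(matrix(numeric(0), 0, 2)), "empty")
})

test_that("distance filtering discards strictly beyond the quantile", {
  ctr <- c(0, 0)
  # exactly representable points, all at distance 5 from the origin
  ring <- rbind(c(3, 4), c(4, 3), c(-3, 4), c(-4, 3), c(3, -4), c(4, -3),
                c(-3, -4), c(-4, -3), c(5, 0), c(-5, 0), c(0, 5), c(0, -5))
  keep <- filterByDistance(ring, ctr, 0.8)
  expect_equal(nrow(keep$coords), nrow(ring))   # all equidistant: all kept
  pts <- cbind(1:10, 0)
  res <- filterByDistance(pts, ctr, 0.8)
  expect_equal(res$threshold, quantile(1:10, 0.8, names = FALSE))  # 8.2
  expect_equal(unname(res$coords[, 1]), 1:8)
  single <- filterByDistance(cbind(4, 2), c(0, 0), 0.8)
  expect_equal(nrow(single$coords), 1L)
})

test_that("confidence ellipse has chi-square coverage and axes", {
  set.seed(7)
  pts <- matrix(rnorm(2 * 10000), ncol = 2)
  ell <- fitConfidenceEllipse(pts, level = 0.90)
  expect_equal(ell@scale, qchisq(0.90, 2))
  expect_equal(ell@scale, 2 * log(10), tolerance = 1e-10)
  cover <- mean(insideEllipse(ell, pts))
  expect_lt(abs(cover - 0.90), 0.01)
  ax <- ellipseAxes(ell)
  expect_equal(unname(ax), rep(sqrt(2 * log(10)), 2), tolerance = 0.05)
  expect_error(fitConfidenceEllipse(cbind(1:3, 2 * (1:3))), "degenerate")
  expect_error(fitConfidenceEllipse(rbind(c(0, 0), c(1, 1))), "degenerate")
})

test_that("ROI cropping rasterises the ellipse onto the image", {
  img <- array(0.8, c(60, 60, 3))
  circ <- new("EllipseROI", center = c(30, 30), covariance = diag(2),
              scale = 15^2, level = 0.9)          # disc of radius 15
  roi <- cropROI(img, circ)
  area <- sum(roiMask(roi))
  expect_lt(abs(area - pi * 15^2) / (pi * 15^2), 0.02)
  expect_true(all(roiImage(roi)[roiMask(roi) == 0] == 0))
  expect_true(all(roiImage(roi)[, , 1][roiMask(roi) == 1] == 0.8))
  # ellipse overhanging the edge is clipped but non-empty
  over <- new("EllipseROI", center = c(30, 58), covariance = diag(2),
              scale = 100, level = 0.9)
  roiOver <- cropROI(img, over)
  expect_lte(dim(roiImage(roiOver))[2], 60)
  expect_gt(sum(roiMask(roiOver)), 0)
  # huge ellipse covers the whole image
  big <- new("EllipseROI", center = c(30, 30), covariance = diag(2),
             scale = 1e6, level = 0.9)
  expect_identical(dim(roiImage(cropROI(img, big)))[1:2], c(60L, 60L))
  outside <- new("EllipseROI", center = c(-5, 30), covariance = diag(2),
                 scale = 1, level = 0.9)
  expect_error(cropROI(img, outside), "outside")
})

test_that("segmentEye finds the eye and is translation-equivariant", {
  par1 <- segmentationParams(resizeFactor = 1L)
  img <- renderEye(eyeSpec(eyeCenter = c(118, 150)), seed = 9)
  roi <- segmentEye(img@image, par1)
  off <- (ellipseCenter(roi) - img@truth$center) / img@truth$axes
  expect_lte(sum(off^2), 1)        # centre inside the true eye ellipse
  # translating the eye translates the detected ellipse
  spec0 <- eyeSpec(imageSize = c(300L, 420L), eyeCenter = c(130, 200))
  spec1 <- eyeSpec(imageSize = c(300L, 420L), eyeCenter = c(190, 160))
  c0 <- ellipseCenter(segmentEye(renderEye(spec0, seed = 3)@image, par1))
  c1 <- ellipseCenter(segmentEye(renderEye(spec1, seed = 3)@image, par1))
  expect_lt(max(abs((c1 - c0) - c(60, -40))), 5)
  # bright-spot illumination segments too
  bs <- renderEye(eyeSpec(eyeCenter = c(118, 150),
                          illumination = "bright_spot"), seed = 9)
  roiBs <- segmentEye(bs@image, par1)
  offBs <- (ellipseCenter(roiBs) - bs@truth$center) / bs@truth$axes
  expect_lte(sum(offBs^2), 1)
  # degenerate input fails at the thresholding stage, with a stage label
  expect_error(segmentEye(array(0, c(64, 64, 3)), par1), "threshold")
})
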