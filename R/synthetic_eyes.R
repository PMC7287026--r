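#' @importFrom stats rnorm runif
NULL

#' Construct an EyeSpec
#'
#' Builds a validated [EyeSpec-class]. The defaults describe a healthy
#' (wild-type-like) eye rendered at one-tenth of the acquisition
#' resolution of the bright-field setup the pipeline targets: a
#' 240 x 320 px frame holding an elliptical eye of semi-axes 72 x 96 px
#' packed with ommatidial facets at 11 px spacing. When no `eyeCenter`
#' is given the eye is placed uniformly at random (fully in frame) at
#' render time, so translation invariance of the segmentation is
#' exercised continuously.
#'
#' @param imageSize integer(2) `(height, width)`.
#' @param eyeCenter numeric(2) `(row, col)` or `NA` (randomise).
#' @param eyeAxes numeric(2) semi-axes `(rows, cols)`.
#' @param latticeSpacing facet centre spacing in px.
#' @param jitterSd sd (px) of facet-centre jitter.
#' @param fusionProb per-facet probability of fusing with a neighbour.
#' @param depigProb per-facet probability of seeding a depigmented patch.
#' @param bristleDensity fraction of facets carrying a bristle hair.
#' @param necrosisProb per-facet probability of a dark necrotic patch.
#' @param facetContrast facet-versus-base colour contrast in [0,1].
#' @param glintProb per-facet probability of a specular glint
#'   (diffuse mode).
#' @param illumination `"diffuse"` or `"bright_spot"`.
#' @param backgroundLevel background gray level.
#' @param noiseSd sd of additive Gaussian pixel noise.
#' @return An [EyeSpec-class].
#' @export
eyeSpec <- function(imageSize = c(240L, 320L), eyeCenter = c(NA, NA),
                    eyeAxes = c(72, 96), latticeSpacing = 11,
                    jitterSd = 0.15, fusionProb = 0.01, depigProb = 0,
                    bristleDensity = 1, necrosisProb = 0,
                    facetContrast = 1, glintProb = 0.95,
                    illumination = "diffuse",
                    backgroundLevel = 0.22, noiseSd = 0.005) {
  new("EyeSpec", imageSize = as.integer(imageSize),
      eyeCenter = as.numeric(eyeCenter), eyeAxes = as.numeric(eyeAxes),
      latticeSpacing = latticeSpacing, jitterSd = jitterSd,
      fusionProb = fusionProb, depigProb = depigProb,
      bristleDensity = bristleDensity, necrosisProb = necrosisProb,
      facetContrast = facetContrast, glintProb = glintProb,
      illumination = illumination,
      backgroundLevel = backgroundLevel, noiseSd = noiseSd)
}

# degeneration endpoints: (healthy, fully degenerated); chosen once to
# span the qualitative range from pristine hexagonal packing to heavy
# jitter, facet fusion, depigmentation and bristle loss
.degenEndpoints <- list(
  jitterSd = c(0.15, 2.6),
  fusionProb = c(0.01, 0.50),
  depigProb = c(0.00, 0.45),
  bristleDensity = c(1.00, 0.05),
  necrosisProb = c(0.00, 0.45),
  facetContrast = c(1.00, 0.20),
  glintProb = c(0.95, 0.05))

.levelLabels <- c(WT = 0, mod1 = 0.25, mod2 = 0.5, mod3 = 0.75, SCA1 = 1)

#' Map a disorder level onto an EyeSpec
#'
#' Linearly interpolates the degeneration parameters (jitter, fusion
#' probability, depigmentation probability, bristle loss
#' `1 - bristleDensity`, necrosis probability, facet-contrast decay and
#' glint loss) between the base spec (level 0, assumed calibrated to a
#' healthy eye) and a fully degenerated endpoint (level 1). The five phenotype classes map
#' to equally spaced levels: WT = 0, mod1 = 0.25, mod2 = 0.5,
#' mod3 = 0.75, SCA1 = 1.
#'
#' @param level disorder level in `[0, 1]`.
#' @param base template [EyeSpec-class]; its non-degeneration fields are
#'   kept.
#' @return An [EyeSpec-class] at the requested disorder level.
#' @export
degenerationSeries <- function(level, base = eyeSpec()) {
  if (length(level) != 1L || !is.finite(level) || level < 0 || level > 1)
    stop("level must lie in [0, 1]", call. = FALSE)
  e <- .degenEndpoints
  lerp <- function(from, ab) from + level * (ab[2] - from)
  initialize(base,
             jitterSd = lerp(base@jitterSd, e$jitterSd),
             fusionProb = lerp(base@fusionProb, e$fusionProb),
             depigProb = lerp(base@depigProb, e$depigProb),
             bristleDensity = lerp(base@bristleDensity, e$bristleDensity),
             necrosisProb = lerp(base@necrosisProb, e$necrosisProb),
             facetContrast = lerp(base@facetContrast, e$facetContrast),
             glintProb = lerp(base@glintProb, e$glintProb))
}

.levelLabel <- function(level) {
  hit <- which(abs(.levelLabels - level) < 1e-9)
  if (length(hit)) names(.levelLabels)[hit[1]] else ""
}

.disorderOfSpec <- function(spec) {
  e <- .degenEndpoints$jitterSd
  min(1, max(0, (spec@jitterSd - e[1]) / (e[2] - e[1])))
}

# soft-edged segment painter (capsule of the given half-width)
.paintSegment <- function(arr, p0, p1, halfWidth, col) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  rs <- max(1L, floor(min(p0[1], p1[1]) - halfWidth - 1)):
    min(h, ceiling(max(p0[1], p1[1]) + halfWidth + 1))
  cs <- max(1L, floor(min(p0[2], p1[2]) - halfWidth - 1)):
    min(w, ceiling(max(p0[2], p1[2]) + halfWidth + 1))
  v <- p1 - p0
  L2 <- sum(v^2)
  rr <- matrix(rs, length(rs), length(cs))
  cc <- matrix(cs, length(rs), length(cs), byrow = TRUE)
  t_ <- if (L2 > 0) pmin(pmax(((rr - p0[1]) * v[1] + (cc - p0[2]) * v[2]) /
                                L2, 0), 1) else 0
  d <- sqrt((rr - (p0[1] + t_ * v[1]))^2 + (cc - (p0[2] + t_ * v[2]))^2)
  alpha <- pmin(pmax(halfWidth + 0.5 - d, 0), 1)
  for (k in 1:3) {
    win <- arr[rs, cs, k]
    arr[rs, cs, k] <- win * (1 - alpha) + col[k] * alpha
  }
  arr
}

# soft-edged disc painter; modifies and returns the rgb array
.paintDisc <- function(arr, r0, c0, rad, col, channels = 1:3,
                       mode = c("blend", "multiply")) {
  mode <- match.arg(mode)
  h <- dim(arr)[1]; w <- dim(arr)[2]
  rs <- max(1L, floor(r0 - rad - 1)):min(h, ceiling(r0 + rad + 1))
  cs <- max(1L, floor(c0 - rad - 1)):min(w, ceiling(c0 + rad + 1))
  if (length(rs) == 0L || length(cs) == 0L) return(arr)
  d <- sqrt(outer((rs - r0)^2, (cs - c0)^2, `+`))
  alpha <- pmin(pmax(rad + 0.5 - d, 0), 1)
  for (k in seq_along(channels)) {
    ch <- channels[k]
    win <- arr[rs, cs, ch]
    arr[rs, cs, ch] <- if (mode == "blend")
      win * (1 - alpha) + col[k] * alpha
    else win * (1 - alpha * (1 - col[k]))
    }
  arr
}

#' Render one synthetic compound-eye image
#'
#' Draws a convex elliptical eye of hexagonally packed bright ommatidial
#' facets (with a thin dark honeycomb between them) on a plain
#' background. Degeneration is emulated by Gaussian jitter of the facet
#' centres, fusion of neighbouring facets into smooth blobs, depigmented
#' patches with attenuated red channel, dark necrotic patches, fading
#' facet contrast, and loss of the oriented interommatidial bristle
#' hairs and specular glints. Lesion and ornament counts are fixed at
#' `round(prob * n)` per image — a genotype's severity is reproducible;
#' randomness lies in where lesions fall. Illumination is either
#' `"diffuse"` (near-uniform shading with a specular crescent per facet)
#' or `"bright_spot"` (a bright highlight on every facet). Additive
#' Gaussian noise is applied last and intensities clipped to `[0, 1]`.
#' Rendering is fully deterministic given `(spec, seed)`.
#'
#' @param spec an [EyeSpec-class].
#' @param seed integer seed.
#' @return A [LabeledEyeImage-class] carrying the image, the phenotype
#'   label implied by the spec's disorder level (empty for off-grid
#'   levels) and the ground-truth geometry.
#' @export
renderEye <- function(spec, seed = 1L) {
  stopifnot(is(spec, "EyeSpec"))
  set.seed(as.integer(seed))
  h <- spec@imageSize[1]; w <- spec@imageSize[2]
  b <- spec@eyeAxes[1]; a <- spec@eyeAxes[2]
  ctr <- spec@eyeCenter
  if (anyNA(ctr)) {
    pad <- 3
    if (b + pad >= h / 2 || a + pad >= w / 2)
      ctr <- c(h / 2, w / 2)
    else
      ctr <- c(stats::runif(1, b + pad, h - b - pad),
               stats::runif(1, a + pad, w - a - pad))
  }
  arr <- array(spec@backgroundLevel, c(h, w, 3))
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ell2 <- ((rr - ctr[1]) / b)^2 + ((cc - ctr[2]) / a)^2
  eye <- ell2 <= 1
  shade <- if (spec@illumination == "diffuse") 1 - 0.06 * ell2
           else matrix(0.8, h, w)
  eyeCol <- c(0.50, 0.13, 0.10)
  for (ch in 1:3) {
    plane <- arr[, , ch]
    plane[eye] <- eyeCol[ch] * shade[eye]
    arr[, , ch] <- plane
  }

  # hexagonal facet lattice clipped to the eye, then jittered
  s <- spec@latticeSpacing
  rowStep <- s * sqrt(3) / 2
  kr <- ceiling(b / rowStep)
  kc <- ceiling(a / s) + 1
  centers <- NULL
  for (i in -kr:kr) {
    rPos <- ctr[1] + i * rowStep
    off <- if (i %% 2 == 0) 0 else s / 2
    cPos <- ctr[2] + off + (-kc:kc) * s
    centers <- rbind(centers, cbind(rPos, cPos))
  }
  margin <- (0.44 * s + 2) / min(a, b)
  inEll <- ((centers[, 1] - ctr[1]) / b)^2 +
    ((centers[, 2] - ctr[2]) / a)^2 <= (1 - margin)^2
  centers <- centers[inEll, , drop = FALSE]
  n <- nrow(centers)
  centers <- centers + matrix(stats::rnorm(2 * n, 0, spec@jitterSd), n, 2)

  # facets nearly touch, so the dark interstitial base shows through as a
  # thin honeycomb lattice along the three hexagonal directions
  facetR <- 0.44 * s
  # facet colour fades toward the base tissue as degeneration flattens
  # the lattice
  facetCol <- eyeCol + spec@facetContrast * (c(0.82, 0.38, 0.28) - eyeCol)
  shadeAt <- function(r0, c0) {
    if (spec@illumination != "diffuse") return(0.8)
    1 - 0.06 * (((r0 - ctr[1]) / b)^2 + ((c0 - ctr[2]) / a)^2)
  }
  # lesion and ornament COUNTS are fixed at round(prob * n): a genotype's
  # severity is reproducible between animals; randomness lies in where
  # lesions fall, not in how many there are
  pickK <- function(p) {
    k <- round(p * n)
    out <- logical(n)
    if (k > 0) out[sample.int(n, min(k, n))] <- TRUE
    out
  }
  glintOff <- c(-0.25, -0.25) * facetR   # fixed light direction (upper left)
  glint <- pickK(spec@glintProb)
  for (i in seq_len(n)) {
    sh <- shadeAt(centers[i, 1], centers[i, 2])
    arr <- .paintDisc(arr, centers[i, 1], centers[i, 2], facetR,
                      facetCol * sh)
    if (spec@illumination == "diffuse" && glint[i]) {
      # specular crescent: curved facets reflect the (fixed) light source
      # as a short horizontal streak, independent of pigmentation
      g0 <- centers[i, ] + glintOff
      arr <- .paintSegment(arr, g0 - c(0, 0.25 * s), g0 + c(0, 0.25 * s),
                           0.8, c(0.95, 0.88, 0.80) * sh)
    }
  }

  # fusion: bridge a facet to one of its six hexagonal neighbours
  fuse <- pickK(spec@fusionProb)
  dirs <- rbind(c(0, 1), c(0, -1), c(rowStep / s, 0.5),
                c(rowStep / s, -0.5), c(-rowStep / s, 0.5),
                c(-rowStep / s, -0.5))
  pick <- sample.int(6L, n, replace = TRUE)
  for (i in which(fuse)) {
    mid <- centers[i, ] + dirs[pick[i], ] * s / 2
    # a fused pair reads as one large smooth blob without the
    # interommatidial groove
    arr <- .paintDisc(arr, mid[1], mid[2], s,
                      facetCol * shadeAt(mid[1], mid[2]))
  }

  # depigmentation: attenuate the red channel in patches
  depig <- pickK(spec@depigProb)
  for (i in which(depig))
    arr <- .paintDisc(arr, centers[i, 1], centers[i, 2], 1.6 * s,
                      col = 0.45, channels = 1L, mode = "multiply")

  # necrotic tissue: dark patches that erase the facet lattice locally
  necro <- pickK(spec@necrosisProb)
  for (i in which(necro))
    arr <- .paintDisc(arr, centers[i, 1], centers[i, 2], 0.9 * s,
                      col = rep(0.35, 3), mode = "multiply")

  # interommatidial bristles: short dark oriented hairs anchored at a
  # lattice vertex; orientation is consistent across the eye (the hairs
  # follow the body axis), so their loss shifts the oriented-gradient
  # signature of degenerated eyes
  bristle <- pickK(spec@bristleDensity)
  hairDir <- c(-sin(40 * pi / 180), cos(40 * pi / 180))  # 40 deg hairs
  hairLen <- 0.7 * s
  for (i in which(bristle)) {
    p0 <- c(centers[i, 1] + 0.5 * rowStep, centers[i, 2] + 0.25 * s)
    arr <- .paintSegment(arr, p0, p0 + hairLen * hairDir, 1.0,
                         c(0.06, 0.04, 0.03))
  }

  if (spec@illumination == "bright_spot")
    for (i in seq_len(n))
      arr <- .paintDisc(arr, centers[i, 1], centers[i, 2], 1.4,
                        c(0.97, 0.95, 0.90))

  if (spec@noiseSd > 0)
    arr <- arr + stats::rnorm(length(arr), 0, spec@noiseSd)
  arr <- pmin(pmax(arr, 0), 1)

  lvl <- .disorderOfSpec(spec)
  new("LabeledEyeImage", image = arr, label = .levelLabel(lvl),
      disorderLevel = lvl,
      truth = list(center = ctr, axes = c(b, a), facets = centers))
}

#' Nearest-neighbour distances of a point set
#'
#' Distance from each point to its nearest other point. The variance of
#' these distances over the true facet centres is the blinded regularity
#' statistic used to verify that disorder increases monotonically.
#'
#' @param points n x 2 numeric matrix.
#' @return Numeric vector of length n.
#' @export
nearestNeighborDistances <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("need at least two points", call. = FALSE)
  d <- as.matrix(stats::dist(points))
  diag(d) <- Inf
  apply(d, 1, min)
}

#' Generate a labelled synthetic eye dataset
#'
#' Renders `nPerClass` images for each of the five phenotype classes at
#' their disorder levels (WT = 0, mod1 = 0.25, mod2 = 0.5, mod3 = 0.75,
#' SCA1 = 1), each with the eye at an independently randomised in-frame
#' position. Optionally writes lossless PNG files plus a manifest CSV.
#' Fully reproducible under `seed`.
#'
#' @param nPerClass images per class (>= 1).
#' @param base template [EyeSpec-class] (its `eyeCenter` should be `NA`
#'   so positions randomise).
#' @param seed integer seed.
#' @param outDir directory to write `eye_<class>_<i>.png` files and
#'   `manifest.csv` into, or `NULL` to keep images in memory only.
#' @return List with `images` (list of [LabeledEyeImage-class]) and
#'   `manifest` (data.frame: id, path, class, disorderLevel, centre and
#'   axes of the true eye, per-image seed).
#' @export
generateEyeDataset <- function(nPerClass, base = eyeSpec(), seed = 1L,
                               outDir = NULL) {
  stopifnot(nPerClass >= 1)
  set.seed(as.integer(seed))
  levels_ <- .levelLabels[eyeClasses()]
  total <- 5L * as.integer(nPerClass)
  seeds <- sample.int(.Machine$integer.max - 1L, total)
  if (!is.null(outDir) && !dir.exists(outDir))
    if (!dir.create(outDir, recursive = TRUE))
      stop("cannot create output directory: ", outDir, call. = FALSE)
  images <- vector("list", total)
  rows <- vector("list", total)
  k <- 0L
  for (cl in eyeClasses()) {
    spec <- degenerationSeries(levels_[[cl]], base)
    for (i in seq_len(nPerClass)) {
      k <- k + 1L
      img <- renderEye(spec, seed = seeds[k])
      images[[k]] <- img
      path <- NA_character_
      if (!is.null(outDir)) {
        path <- file.path(outDir, sprintf("eye_%s_%03d.png", cl, i))
        saveImage(img@image, path)
      }
      rows[[k]] <- data.frame(
        id = sprintf("%s_%03d", cl, i), path = path, class = cl,
        disorderLevel = img@disorderLevel,
        centerRow = img@truth$center[1], centerCol = img@truth$center[2],
        axisRow = img@truth$axes[1], axisCol = img@truth$axes[2],
        seed = seeds[k])
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(outDir))
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE)
  list(images = images, manifest = manifest)
}
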