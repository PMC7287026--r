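#' @importFrom yaml read_yaml
#' @importFrom jsonlite write_json
#' @importFrom rlang hash
NULL

.mergeConfig <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Default pipeline configuration
#'
#' @return Nested list of all pipeline settings with their defaults;
#'   any subset can be overridden via [runPipeline()]'s `config`.
#' @export
pipelineDefaults <- function() {
  list(
    seed = 1L,
    simulate = list(nPerClass = 10L, illumination = "diffuse"),
    input = list(manifest = NULL),   # CSV with path,class: use real images
    segmentation = list(resizeFactor = 1L, kernelSize = 9L,
                        intensityQuantile = 0.99, distanceQuantile = 0.8,
                        ellipseLevel = 0.90),
    hog = list(cells = 5L, nOrientations = 5L),
    classifier = list(kind = "svm_rbf", hyper = list(C = 1, sigma = 0.005)),
    split = list(trainFrac = 0.75),
    cv = list(enabled = FALSE, k = 10L),
    out = NULL)
}

#' Run the full quantification pipeline
#'
#' Ingest (or simulate) labelled eye images, segment every eye ROI,
#' featurize with HOG, stratified-split, optionally grid-search
#' hyperparameters by cross-validation, train the classifier, evaluate
#' it on the held-out test set and score every test eye with IREG.
#' Images failing segmentation are logged and skipped, not fatal. The
#' returned report carries the effective configuration, its hash and the
#' seed, so identical configurations reproduce identical reports.
#'
#' @param config nested list overriding [pipelineDefaults()], or the
#'   path of a YAML file holding such a list.
#' @return List: `config`, `configHash`, `seed`, `counts` (per-stage
#'   tallies), `failures` (per-image segmentation errors), `cv` (grid
#'   search result or NULL), `model` ([EyeClassifier-class]), `eval`
#'   ([EyeEvalReport-class]), `ireg` (per-genotype summary on the test
#'   set). If `config$out` is set, a JSON report and the IREG score
#'   table are written there.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(pipelineDefaults(), config)
  cfgHash <- rlang::hash(cfg)
  seed <- as.integer(cfg$seed)

  # ---- ingest ----------------------------------------------------------
  if (!is.null(cfg$input$manifest)) {
    man <- utils::read.csv(cfg$input$manifest, stringsAsFactors = FALSE)
    if (nrow(man) == 0L) stop("empty input manifest", call. = FALSE)
    paths <- man$path; labels <- man$class
    readOne <- function(i) loadImage(paths[i])
    ids <- paths
  } else {
    sim <- generateEyeDataset(cfg$simulate$nPerClass,
                              base = eyeSpec(illumination =
                                               cfg$simulate$illumination),
                              seed = seed)
    labels <- sim$manifest$class
    ids <- sim$manifest$id
    readOne <- function(i) sim$images[[i]]@image
  }
  n <- length(labels)
  if (n == 0L) stop("configuration error: empty input set", call. = FALSE)

  # ---- segment (skip-and-log) -----------------------------------------
  segPar <- do.call(segmentationParams, cfg$segmentation)
  rois <- vector("list", n)
  failures <- character(0)
  for (i in seq_len(n)) {
    rois[[i]] <- tryCatch(
      segmentEye(readOne(i), segPar, source = ids[i]),
      error = function(e) {
        failures <<- c(failures,
                       sprintf("%s: %s", ids[i], conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(rois, is.null, logical(1))
  if (!any(ok))
    stop("configuration error: no image survived segmentation",
         call. = FALSE)

  # ---- featurize / split / train / evaluate ---------------------------
  hogPar <- do.call(hogParams, cfg$hog)
  feats <- featurizeDataset(rois[ok], labels = factor(labels[ok]),
                            params = hogPar)
  split <- stratifiedSplit(feats@labels, cfg$split$trainFrac, seed = seed)
  trainFeat <- new("EyeFeatures",
                   features = feats@features[split$train, , drop = FALSE],
                   labels = droplevels(feats@labels[split$train]),
                   source = feats@source[split$train])
  testFeat <- new("EyeFeatures",
                  features = feats@features[split$test, , drop = FALSE],
                  labels = droplevels(feats@labels[split$test]),
                  source = feats@source[split$test])
  hyper <- cfg$classifier$hyper
  cvRes <- NULL
  if (isTRUE(cfg$cv$enabled)) {
    cvRes <- cvGridSearch(trainFeat, cfg$classifier$kind,
                          grid = cfg$cv$grid, k = cfg$cv$k, seed = seed)
    hyper <- cvRes$best
  }
  model <- trainClassifier(trainFeat, cfg$classifier$kind, hyper = hyper,
                           seed = seed)
  eval <- evaluateClassifier(model, testFeat)
  ireg <- iregBatch(model, rois[ok][split$test],
                    genotypes = feats@labels[split$test], hog = hogPar)

  report <- list(
    config = cfg, configHash = cfgHash, seed = seed,
    counts = list(input = n, segmented = sum(ok),
                  train = length(split$train), test = length(split$test)),
    failures = failures, cv = cvRes, model = model, eval = eval,
    ireg = ireg$summary, iregScores = ireg$scores)

  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(configHash = cfgHash, seed = seed, counts = report$counts,
           failures = failures,
           confusion = eval@confusion, accuracy = eval@accuracy,
           accuracyCI = eval@accuracyCI, kappa = eval@kappa,
           mAUC = eval@mAUC, ireg = ireg$summary),
      file.path(cfg$out, "report.json"), auto_unbox = TRUE, digits = NA,
      matrix = "rowmajor")
    utils::write.csv(ireg$scores, file.path(cfg$out, "ireg.csv"),
                     row.names = FALSE)
  }
  report
}
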