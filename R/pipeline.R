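#' @include io.R ensemble.R severity.R
NULL

#' Run the full detection pipeline
#'
#' Simulate (or load), split, train the random-subspace ensemble, predict,
#' grade severity from detected lesion counts, and evaluate.  Every stage
#' seed derives from `config$seed`; rerunning with the same configuration
#' reproduces the report exactly (timing fields aside).
#'
#' The classifier consumes the 5 input planes of [fundusPlanes()].  When
#' `preprocess = TRUE` the corruption-removal chain runs on each image
#' first (worthwhile when the simulated images carry noise/blur/
#' illumination artifacts).
#'
#' @param config nested configuration list (see [defaultConfig()]).
#' @param dataDir optional existing dataset directory ([loadDataset()]
#'   layout); when `NULL`, data are simulated per `config$simulate`.
#' @param preprocess run [preprocessFundus()] on every image first.
#' @param testFraction held-out fraction for evaluation.
#' @param outDir where to write `report.json` and `predictions.csv`
#'   (`NULL` skips writing).
#' @return list of class `"PipelineResult"`: `report` ([evaluatePredictions()]
#'   output), `severityReport`, `model`, `thresholds`, `predictions`
#'   (data.frame), `timings`.
#' @export
runPipeline <- function(config = defaultConfig(), dataDir = NULL,
                        preprocess = FALSE, testFraction = 0.25,
                        outDir = config$io$outDir) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    t0 <<- proc.time()[["elapsed"]]
  }

  # --- data ---------------------------------------------------------
  if (is.null(dataDir)) {
    sim <- config$simulate
    ds <- generateDataset(sim$nPerClass, baseSeed = sim$baseSeed,
                          outDir = NULL, height = sim$height,
                          width = sim$width, noiseDensity = sim$noiseDensity,
                          illuminationStrength = sim$illuminationStrength,
                          blurSigma = sim$blurSigma)
    records <- ds$manifest
    images <- lapply(ds$images, fundusImage)
  } else {
    ds <- loadDataset(dataDir)
    records <- ds$records
    images <- ds$images
  }
  tick("simulate")

  if (preprocess) {
    images <- lapply(images, preprocessFundus, config = config$preprocess)
    tick("preprocess")
  }

  classes <- VALID_CLASSES
  y <- match(records$class_label, classes)
  n <- length(images)
  testIdx <- withSeed(config$seed + 31L,
                      sample.int(n, max(1L, round(testFraction * n))))
  trainIdx <- setdiff(seq_len(n), testIdx)

  # --- classification ----------------------------------------------
  x <- stackPlanes(images)
  ens <- config$ensemble
  model <- trainEnsemble(x[, , , trainIdx, drop = FALSE], y[trainIdx],
    classNames = classes, L = ens$L, rFraction = ens$rFraction,
    scale = ens$scale, epochs = ens$epochs, batchSize = ens$batchSize,
    lr = ens$lr, weighting = ens$weighting, seed = config$seed)
  tick("train")
  pred <- predictEnsemble(model, x[, , , testIdx, drop = FALSE])
  report <- evaluatePredictions(records$class_label[testIdx], pred$class,
                                classes = classes)
  tick("predict")

  # --- severity grading from detected lesion counts ----------------
  seg <- config$segment
  fcfg <- config$features
  detCount <- function(img) {
    segm <- segmentVessels(img, MinPts = seg$MinPts, eps = seg$eps,
      extractionThreshold = seg$extractionThreshold,
      maxSamples = seg$maxSamples,
      vesselnessThreshold = seg$vesselnessThreshold)
    cand <- detectCandidates(img, segm, darkPercentile = fcfg$darkPercentile,
      darkAbs = fcfg$darkAbs, brightPercentile = fcfg$brightPercentile,
      brightAbs = fcfg$brightAbs, maSizeGate = fcfg$maSizeGate)
    nrow(cand$regions)
  }
  trainCounts <- vapply(images[trainIdx], detCount, numeric(1))
  sevTrain <- records$severity[trainIdx]
  hasSev <- sevTrain %in% SEVERITY_LEVELS
  thresholds <- NULL
  sevReport <- NULL
  if (sum(hasSev) >= 3L && length(unique(sevTrain[hasSev])) >= 2L) {
    thresholds <- fitSeverityThresholds(trainCounts[hasSev], sevTrain[hasSev])
    testCounts <- vapply(images[testIdx], detCount, numeric(1))
    sevPred <- gradeSeverity(testCounts, thresholds)
    sevTrue <- records$severity[testIdx]
    keep <- sevTrue %in% SEVERITY_LEVELS
    if (any(keep)) {
      sevReport <- evaluatePredictions(sevTrue[keep], sevPred[keep],
                                       classes = SEVERITY_LEVELS)
    }
  }
  tick("severity")

  predictions <- data.frame(filename = records$filename[testIdx],
    truth = records$class_label[testIdx], stringsAsFactors = FALSE)
  predictions <- cbind(predictions,
                       setNames(as.data.frame(pred$scores),
                                paste0("p_", classes)))
  predictions$class <- pred$class

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(predictions, file.path(outDir, "predictions.csv"),
              row.names = FALSE)
    rep <- list(accuracy = report$accuracy, errorRate = report$errorRate,
      macro = as.list(report$macro),
      perClass = report$perClass,
      confusion = as.data.frame.matrix(report$confusion),
      severityAccuracy = if (!is.null(sevReport)) sevReport$accuracy else NA,
      thresholds = if (!is.null(thresholds))
        list(t1 = thresholds@t1, t2 = thresholds@t2) else NULL,
      seeds = list(pipeline = config$seed, simulate = config$simulate$baseSeed),
      timings = as.list(timings))
    jsonlite::write_json(rep, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(report = report, severityReport = sevReport, model = model,
                 thresholds = thresholds, predictions = predictions,
                 timings = timings),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult\n==============\nClassification:\n")
  print(x$report)
  if (!is.null(x$severityReport)) {
    cat("\nSeverity grading:\n")
    print(x$severityReport)
  }
  invisible(x)
}

#' Scaled-down end-to-end classification benchmark
#'
#' The package's reference desk-scale experiment: generate
#' `nTrain` + `nTest` synthetic fundus images per class at `size` x `size`,
#' train the L-member random-subspace ensemble at the given width scale,
#' and evaluate fused and per-member accuracy on the held-out images.
#' Training and test sets use disjoint generation seeds derived from
#' `seed`.
#'
#' @param seed experiment seed (drives generation, subspaces, init,
#'   shuffling).
#' @param nTrain,nTest images per class.
#' @param size image side in pixels.
#' @param L,scale,epochs,batchSize,lr ensemble hyperparameters.
#' @param rFraction fraction of input planes per member.
#' @return list with `fusedAccuracy`, `memberAccuracies`, `weights`,
#'   `diversity`, `report` (an [evaluatePredictions()] report), `model`.
#' @export
runScaledBenchmark <- function(seed = 0L, nTrain = 150L, nTest = 50L,
                               size = 64L, L = 3L, scale = 0.125,
                               epochs = 15L, batchSize = 32L, lr = 1e-3,
                               rFraction = 0.8) {
  classes <- VALID_CLASSES
  base <- (as.integer(seed) %% 20000L) * 100000L   # derived seeds stay < 2^31
  tr <- generateDataset(nTrain, baseSeed = base, outDir = NULL,
                        height = size, width = size)
  te <- generateDataset(nTest, baseSeed = base + 50000L,
                        outDir = NULL, height = size, width = size)
  xtr <- stackPlanes(tr$images)
  xte <- stackPlanes(te$images)
  ytr <- match(tr$manifest$class_label, classes)
  yte <- match(te$manifest$class_label, classes)
  model <- trainEnsemble(xtr, ytr, classNames = classes, L = L,
                         rFraction = rFraction, scale = scale,
                         epochs = epochs, batchSize = batchSize, lr = lr,
                         seed = seed)
  pred <- predictEnsemble(model, xte)
  fused <- mean(pred$class == classes[yte])
  memberAcc <- vapply(pred$memberScores, function(s) {
    mean(max.col(s, ties.method = "first") == yte)
  }, numeric(1))
  report <- evaluatePredictions(classes[yte], pred$class, classes = classes)
  list(fusedAccuracy = fused, memberAccuracies = memberAcc,
       weights = fusionWeights(model),
       diversity = ensembleDiversity(model, xte),
       report = report, model = model)
}
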