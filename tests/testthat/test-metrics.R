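test_that("confusion-derived metrics match their closed forms", {
  cc <- list(T1 = 90, T2 = 5, F1 = 3, F2 = 2)
  expect_equal(accuracy(cc), 0.95)
  expect_equal(precisionScore(cc), 90 / 93)
  expect_equal(recallScore(cc), 90 / 92)
  expect_equal(fScore(0.9, 0.9), 0.9)
  expect_equal(fScore(1, 0), 0)
  expect_equal(fScore(0.8, 0.6), 2 * 0.8 * 0.6 / 1.4)
  expect_equal(errorRate(5, 100), 0.05)
  expect_equal(errorRate(0, 10), 0)
  expect_error(errorRate(1, 0), "nSamples")
  expect_error(accuracy(list(T1 = 0, T2 = 0, F1 = 0, F2 = 0)), "empty")
  expect_true(is.na(precisionScore(list(T1 = 0, T2 = 5, F1 = 0, F2 = 2))))
})

test_that("identities hold over random confusion tables", {
  set.seed(14)
  classes <- c("normal", "DR", "DME")
  for (i in 1:100) {
    n <- sample(10:60, 1)
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    rep <- evaluatePredictions(truth, pred, classes)
    expect_equal(rep$accuracy + rep$errorRate, 1)
    # macro metrics are plain means of the defined per-class values
    expect_equal(unname(rep$macro["precision"]),
                 mean(rep$perClass$precision, na.rm = TRUE))
    expect_equal(unname(rep$macro["recall"]),
                 mean(rep$perClass$recall, na.rm = TRUE))
    # F-score equals an independently recomputed harmonic mean
    for (k in seq_len(nrow(rep$perClass))) {
      p <- rep$perClass$precision[k]; r <- rep$perClass$recall[k]
      if (!is.na(p) && !is.na(r) && p + r > 0) {
        expect_equal(rep$perClass$fscore[k], 2 / (1 / p + 1 / r))
      }
    }
    # one-vs-rest counts always total n
    cc <- confusionCounts(truth, pred, "DR")
    expect_equal(cc$T1 + cc$T2 + cc$F1 + cc$F2, n)
  }
})

test_that("micro-pooled counts reproduce overall accuracy", {
  set.seed(15)
  classes <- c("a", "b", "c")
  truth <- sample(classes, 80, replace = TRUE)
  pred <- sample(classes, 80, replace = TRUE)
  pooled <- Reduce(function(acc, cl) {
    cc <- confusionCounts(truth, pred, cl)
    Map(`+`, acc, cc)
  }, classes, init = list(T1 = 0, T2 = 0, F1 = 0, F2 = 0))
  rep <- evaluatePredictions(truth, pred, classes)
  expect_equal(accuracy(pooled),
               (2 * rep$accuracy + 1) / 3)  # 3-class one-vs-rest pooling
})

test_that("datasets round-trip through disk with labels intact", {
  td <- withr::local_tempdir()
  ds <- generateDataset(2, baseSeed = 7, outDir = td, height = 64, width = 64,
                        writeMasks = FALSE)
  loaded <- loadDataset(td)
  expect_identical(nrow(loaded$records), 6L)
  expect_identical(loaded$records$class_label, ds$manifest$class_label)
  expect_identical(loaded$skipped, 0L)
  expect_equal(dim(loaded$images[[1]]), c(64, 64, 3))
  # a missing file is skipped with a warning, not fatal
  file.remove(file.path(td, ds$manifest$filename[1]))
  expect_warning(l2 <- loadDataset(td), "skipping")
  expect_identical(nrow(l2$records), 5L)
  expect_identical(l2$skipped, 1L)
  expect_error(loadDataset(file.path(td, "nope")), "manifest")
})

test_that("config files merge over profile defaults", {
  td <- withr::local_tempdir()
  cfg <- defaultConfig("desk")
  expect_identical(cfg$ensemble$epochs, 15L)
  expect_identical(defaultConfig("full")$ensemble$epochs, 235L)
  yaml::write_yaml(list(ensemble = list(epochs = 2), seed = 99),
                   file.path(td, "c.yaml"))
  merged <- readConfig(file.path(td, "c.yaml"))
  expect_equal(merged$ensemble$epochs, 2)
  expect_equal(merged$seed, 99)
  expect_identical(merged$ensemble$batchSize, 32L)  # untouched default
  expect_error(readConfig(file.path(td, "missing.yaml")), "not found")
})
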