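test_that("perfectly separable counts reach zero conditional entropy", {
  th <- fitSeverityThresholds(c(1, 2, 5, 6, 12, 15),
                              c("mild", "mild", "moderate", "moderate",
                                "severe", "severe"))
  expect_equal(th@fittedEntropy, 0)
  expect_true(th@t1 >= 2 && th@t1 < 5)
  expect_true(th@t2 >= 6 && th@t2 < 12)
})

test_that("labels independent of counts leave the full label entropy", {
  counts <- rep(1:6, times = 3)
  labels <- rep(c("mild", "moderate", "severe"), each = 6)
  th <- fitSeverityThresholds(counts, labels)
  expect_equal(th@fittedEntropy, log2(3), tolerance = 1e-9)
})

test_that("the fit matches an independent exhaustive oracle", {
  set.seed(10)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    counts <- sample(0:15, n, replace = TRUE)
    labels <- ifelse(counts + rnorm(n) <= 3, "mild",
                     ifelse(counts + rnorm(n) <= 9, "moderate", "severe"))
    if (length(unique(labels)) < 2 || length(unique(counts)) < 2) next
    th <- fitSeverityThresholds(counts, labels)
    ref <- bfSeverityFit(counts, labels)
    expect_equal(th@fittedEntropy, ref$H, tolerance = 1e-9)
    # fitted conditional entropy never exceeds the marginal label entropy
    p <- prop.table(table(labels))
    expect_lte(th@fittedEntropy, -sum(p * log2(p)) + 1e-9)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(fitSeverityThresholds(1:2, c("mild", "severe")), "3 samples")
  expect_error(fitSeverityThresholds(c(1, 5, 9), rep("mild", 3)),
               "degenerate")
})

test_that("grading follows the stated bin convention and is monotone", {
  th <- new("SeverityThresholds", t1 = 3, t2 = 9, fittedEntropy = 0,
            classNames = c("mild", "moderate", "severe"))
  expect_identical(gradeSeverity(0, th), "mild")
  expect_identical(gradeSeverity(3, th), "mild")
  expect_identical(gradeSeverity(9, th), "moderate")  # boundary -> moderate
  expect_identical(gradeSeverity(10, th), "severe")
  ord <- factor(gradeSeverity(0:20, th),
                levels = c("mild", "moderate", "severe"), ordered = TRUE)
  expect_true(all(diff(as.integer(ord)) >= 0))
  expect_error(gradeSeverity(-1, th), "count")
})

test_that("thresholds are recovered from noisy generator counts", {
  hits <- 0L
  for (trial in 1:15) {
    d <- simulateSeverityCounts(120, seed = 400 + trial, sigma = 1)
    th <- fitSeverityThresholds(d$count, d$severity)
    if (th@t1 >= 2 && th@t1 <= 4 && th@t2 >= 8 && th@t2 <= 11) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / 15, 0.9)
})
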