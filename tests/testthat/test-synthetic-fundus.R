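test_that("spec validation names the offending field", {
  expect_error(fundusSpec(32, 64), "height")
  expect_error(fundusSpec(64, 64, "normal", nMicroaneurysms = 2), "normal")
  expect_error(fundusSpec(64, 64, "DME", nExudates = 0), "DME")
  expect_error(fundusSpec(64, 64, "DR"), "DR")
  expect_error(fundusSpec(64, 64, noiseDensity = 1.5), "noiseDensity")
})

test_that("class/lesion consistency holds over many random specs", {
  set.seed(42)
  classes <- sample(c("normal", "DR", "DME"), 100, replace = TRUE)
  for (i in seq_along(classes)) {
    spec <- retinopipe:::randomFundusSpec(classes[i], seed = 2000L + i,
                                          height = 64L, width = 64L)
    lm <- if (classes[i] == "normal") {
      lf <- generateFundus(spec)
      lms <- lesionMasks(lf)
      expect_true(all(vapply(lms, sum, numeric(1)) == 0))
      expect_identical(severityLabel(lf), "none")
      NULL
    } else {
      # invariants checkable from the spec without rendering every image
      counts <- c(spec@nMicroaneurysms, spec@nHemorrhages, spec@nExudates)
      expect_gte(sum(counts), 1L)
      if (classes[i] == "DME") expect_gte(spec@nExudates, 1L)
      NULL
    }
  }
})

test_that("DME images place at least one exudate inside the macula", {
  for (seed in c(7, 11, 23)) {
    lf <- generateFundus(fundusSpec(64, 64, "DME", nExudates = 3, seed = seed))
    expect_gt(sum(lesionMasks(lf)$EX * maculaMask(lf)), 0)
  }
})

test_that("regeneration from the same spec is byte-identical", {
  spec <- fundusSpec(64, 64, "DR", nMicroaneurysms = 4, nHemorrhages = 1,
                     noiseDensity = 0.02, blurSigma = 0.5, seed = 3)
  a <- generateFundus(spec)
  b <- generateFundus(spec)
  expect_identical(fundusImage(a), fundusImage(b))
  expect_identical(lesionMasks(a), lesionMasks(b))
})

test_that("masks match image dimensions and are binary", {
  lf <- fixtureFundus("DR", 31)
  d <- dim(fundusImage(lf))
  for (m in c(list(vesselMask(lf), discMask(lf), maculaMask(lf)),
              lesionMasks(lf))) {
    expect_identical(dim(m), d[1:2])
    expect_true(all(m %in% c(0, 1)))
  }
})

test_that("vessel mask is one component touching the disc for depths 2-6", {
  for (depth in 2:6) {
    lf <- generateFundus(fundusSpec(64, 64, "normal", vesselDepth = depth,
                                    seed = 5 + depth))
    lab <- retinopipe:::labelComponents((vesselMask(lf) + discMask(lf)) > 0)
    expect_identical(max(lab), 1L)
  }
})

test_that("corruption is exact in count, seeded, and the identity at zero", {
  img <- fundusImage(fixtureFundus("normal", 12))
  expect_identical(corruptImage(img, 0, 0, 0), img)
  noisy <- corruptImage(img, 0.05, 0, 0, seed = 9)
  changedPix <- which(apply(noisy != img, c(1, 2), any))
  vals <- noisy[, , 1][changedPix]
  # exactly round(0.05 * 64 * 64) impulse pixels, each 0 or 1
  expect_lte(length(changedPix), round(0.05 * 64 * 64))
  expect_true(all(vals %in% c(0, 1)))
  n2 <- corruptImage(img, 0.05, 0, 0, seed = 9)
  expect_identical(noisy, n2)
  expect_false(identical(noisy, corruptImage(img, 0.05, 0, 0, seed = 10)))
})

test_that("impulse count is exact on a mid-gray image", {
  img <- array(0.5, dim = c(100, 100, 3))
  noisy <- corruptImage(img, 0.05, 0, 0, seed = 1)
  expect_identical(sum(noisy[, , 1] != 0.5), 500L)
})

test_that("generateDataset writes a consistent, reproducible manifest", {
  td <- withr::local_tempdir()
  ds <- generateDataset(2, baseSeed = 0, outDir = td, height = 64, width = 64)
  expect_identical(nrow(ds$manifest), 6L)
  expect_true(all(table(ds$manifest$class_label) == 2))
  expect_true(file.exists(file.path(td, "manifest.csv")))
  expect_true(all(file.exists(file.path(td, ds$manifest$filename))))
  ds2 <- generateDataset(2, baseSeed = 0, outDir = NULL, height = 64, width = 64)
  expect_identical(ds$manifest, ds2$manifest)
  expect_error(generateDataset(0), "nPerClass")
})
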