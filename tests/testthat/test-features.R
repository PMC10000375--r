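candidatesFor <- function(lf) {
  seg <- segmentVessels(fundusImage(lf), discMask = discMask(lf))
  list(seg = seg, cand = detectCandidates(fundusImage(lf), seg))
}

test_that("normal images yield no lesion candidates", {
  hits <- vapply(1:8, function(seed) {
    nrow(candidatesFor(fixtureFundus("normal", 90 + seed))$cand$regions)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.9)
})

test_that("planted microaneurysms are recovered", {
  recalls <- vapply(c(1, 2, 3), function(seed) {
    lf <- generateFundus(fundusSpec(64, 64, "DR", nMicroaneurysms = 5,
                                    seed = 300 + seed))
    cc <- candidatesFor(lf)
    reg <- cc$cand$regions
    dark <- reg[reg$type %in% c("MA", "HE"), , drop = FALSE]
    truth <- lesionMasks(lf)$MA
    lab <- retinopipe:::labelComponents(truth > 0)
    found <- 0
    for (k in seq_len(max(lab))) {
      px <- which(lab == k)
      r0 <- mean(((px - 1) %% 64) + 1)
      c0 <- mean(((px - 1) %/% 64) + 1)
      if (nrow(dark) > 0 &&
          min(sqrt((dark$row - r0)^2 + (dark$col - c0)^2)) <= 5) {
        found <- found + 1
      }
    }
    found / max(lab)
  }, numeric(1))
  expect_gte(mean(recalls), 0.8)
})

test_that("candidates never overlap vessel or disc pixels", {
  lf <- fixtureFundus("DR", 95)
  cc <- candidatesFor(lf)
  px <- unlist(cc$cand$pixels)
  if (length(px)) {
    expect_equal(sum(cc$seg@vesselMask[px]), 0)
    expect_equal(sum(cc$seg@discMask[px]), 0)
  }
  succeed()
})

test_that("feature vector has the fixed schema and zero-case semantics", {
  flatCand <- list(regions = data.frame(type = character(), row = numeric(),
    col = numeric(), area = numeric(), eccentricity = numeric(),
    theta = numeric(), meanR = numeric(), meanG = numeric(),
    meanB = numeric()), pixels = list(), imageDim = c(64, 64))
  lf <- fixtureFundus("normal", 96)
  seg <- segmentVessels(fundusImage(lf), discMask = discMask(lf))
  fv <- lesionFeatures(fundusImage(lf), flatCand, seg, maculaMask(lf))
  expect_identical(names(fv), featureSchema())
  expect_length(fv, 40L)
  expect_equal(unname(fv[c("ma_count", "he_count", "ex_count",
                           "lesion_area_fraction")]), rep(0, 4))
  expect_equal(unname(fv[paste0("orient_bin_", 1:8)]), rep(0, 8))
  expect_true(all(is.finite(fv)))
})

test_that("a circular region reports near-zero eccentricity", {
  img <- array(0.55, dim = c(64, 64, 3))
  img[, , 2] <- 0.45
  # paint one dark circular lesion
  for (r in 1:64) for (c in 1:64) {
    if ((r - 30)^2 + (c - 40)^2 <= 16) img[r, c, ] <- c(0.3, 0.05, 0.05)
  }
  seg <- new("VesselSegmentation", vesselMask = matrix(0, 64, 64),
             clusterLabels = integer(0), discMask = matrix(0, 64, 64),
             samples = matrix(0, 0, 4))
  cand <- detectCandidates(img, seg)
  expect_identical(nrow(cand$regions), 1L)
  fv <- lesionFeatures(img, cand, seg, matrix(0, 64, 64))
  expect_lt(fv[["mean_eccentricity"]], 0.3)
  expect_gt(fv[["mean_circularity"]], 0.95)
})

test_that("adding lesions never decreases the corresponding count", {
  base <- generateFundus(fundusSpec(64, 64, "DR", nMicroaneurysms = 2,
                                    seed = 101))
  more <- generateFundus(fundusSpec(64, 64, "DR", nMicroaneurysms = 6,
                                    seed = 101))
  cb <- candidatesFor(base)
  cm <- candidatesFor(more)
  nb <- sum(cb$cand$regions$type %in% c("MA", "HE"))
  nm <- sum(cm$cand$regions$type %in% c("MA", "HE"))
  expect_gte(nm, nb)
})

test_that("cosine similarity follows its closed form", {
  expect_equal(cosineSimilarity(c(1, 2), c(1, 2)), 1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosineSimilarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_error(cosineSimilarity(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(cosineSimilarity(1:2, 1:3), "dimension")
})
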