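test_that("denoiser leaves clean images essentially untouched", {
  const <- matrix(0.5, 32, 32)
  expect_identical(iemDenoise(const), const)
  img <- fundusImage(fixtureFundus("normal", 41))
  res <- iemDenoise(img, details = TRUE)
  expect_lt(mean(res$flagged), 0.01)          # flag rate < 1% on clean input
  untouched <- !res$flagged
  for (ch in 1:3) {
    expect_identical(res$image[, , ch][untouched], img[, , ch][untouched])
  }
})

test_that("an isolated impulse is restored to the background level", {
  m <- matrix(128 / 255, 21, 21)
  m[11, 11] <- 1
  out <- iemDenoise(m)
  expect_lt(abs(out[11, 11] - 128 / 255) * 255, 1)
})

test_that("denoising salt-and-pepper improves PSNR by >= 5 dB", {
  for (seed in c(1, 2)) {
    clean <- fundusImage(fixtureFundus("DR", 60 + seed))
    noisy <- corruptImage(clean, 0.05, 0, 0, seed = seed)
    den <- iemDenoise(noisy)
    expect_gte(psnr(den, clean), psnr(noisy, clean) + 5)
  }
})

test_that("diffusion is conservative, stable, and edge-preserving", {
  const <- matrix(0.3, 16, 16)
  expect_equal(diffusionFilter(const, iters = 5), const)
  img <- matrix(runif(32 * 32, 0.2, 0.8), 32, 32)
  expect_identical(diffusionFilter(img, iters = 0), img)
  expect_error(diffusionFilter(img, dt = 0.3), "dt")
  # noisy step edge: total variation falls, the step gradient survives
  set.seed(8)
  step <- matrix(rep(c(0.2, 0.8), each = 16), 16, 32, byrow = TRUE)
  noisy <- step + matrix(rnorm(16 * 32, sd = 0.03), 16, 32)
  out <- diffusionFilter(noisy, iters = 10, dt = 0.2, kappa = 0.1)
  tv <- function(m) sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
  expect_lt(tv(out), tv(noisy))
  gradStep <- function(m) mean(abs(m[, 17] - m[, 16]))
  expect_gte(gradStep(out), 0.5 * gradStep(noisy))
  expect_lt(abs(mean(out) - mean(noisy)) / mean(noisy), 0.005)
})

test_that("contrast fitness ranks richer histograms higher", {
  expect_equal(contrastFitness(matrix(0.4, 32, 32)), 0)
  grad <- matrix(rep(seq(0, 1, length.out = 64), each = 64), 64, 64)
  binary <- matrix(rep(c(0, 1), each = 32 * 64), 64, 64)
  expect_gt(contrastFitness(grad), contrastFitness(binary))
  expect_error(contrastFitness(matrix(numeric(0), 0, 0)), "empty")
})

test_that("contrast fitness is stable under image tiling", {
  # a periodic test pattern tiles without seams, isolating the scaling law
  img <- outer(1:64, 1:64, function(i, j) {
    0.5 + 0.22 * sin(2 * pi * 3 * i / 64) + 0.18 * cos(2 * pi * 5 * j / 64)
  })
  tiled <- rbind(cbind(img, img), cbind(img, img))
  f1 <- contrastFitness(img)
  f4 <- contrastFitness(tiled)
  expect_lt(abs(f4 - f1) / f1, 0.05)
})

test_that("HHO enhancement never lowers fitness and preserves ordering", {
  img <- luminance(fundusImage(fixtureFundus("DME", 45)))
  low <- 0.4 + 0.2 * img   # compress contrast into [0.4, 0.6]
  cfg <- hhoConfig(15, 50, rep(0, 3), rep(1, 3), seed = 0)
  res <- hhoEnhance(low, cfg)
  expect_gt(contrastFitness(res$image), contrastFitness(low))
  # monotone mapping preserves intensity ranks
  expect_equal(cor(as.vector(low), as.vector(res$image), method = "spearman"),
               1, tolerance = 1e-12)
  res2 <- hhoEnhance(low, cfg)
  expect_identical(res$image, res2$image)
})

test_that("HHO enhancement is within reach of a larger random search", {
  img <- luminance(fundusImage(fixtureFundus("DME", 45)))
  low <- 0.4 + 0.2 * img
  cfg <- hhoConfig(15, 50, rep(0, 3), rep(1, 3), seed = 0)
  res <- hhoEnhance(low, cfg)
  bounds <- res$transform@bounds
  set.seed(123)
  fitRand <- max(replicate(1500, {
    p <- runif(3, bounds[1, ], bounds[2, ])
    contrastFitness(retinopipe:::contrastMap(low, p[1], p[2], p[3]))
  }))
  expect_gte(res$transform@fitness, 0.95 * fitRand)
})

test_that("the preprocessing chain is the identity when disabled", {
  img <- fundusImage(fixtureFundus("normal", 46))
  cfg <- list(denoise = list(enabled = FALSE),
              diffusion = list(enabled = FALSE),
              enhance = list(enabled = FALSE))
  expect_identical(preprocessFundus(img, cfg), img)
})

test_that("preprocessing a corrupted fundus does not hurt PSNR", {
  clean <- fundusImage(fixtureFundus("DR", 47))
  noisy <- corruptImage(clean, 0.05, 0.1, 0.4, seed = 2)
  cfg <- list(denoise = list(enabled = TRUE, window = 5L, thresholdK = 6),
              diffusion = list(enabled = TRUE, iters = 5L, dt = 0.2,
                               kappa = 0.1),
              enhance = list(enabled = FALSE))
  out <- preprocessFundus(noisy, cfg, details = TRUE)
  expect_gte(psnr(out$image, clean), psnr(noisy, clean))
  expect_named(out$timings, c("denoise", "diffusion", "enhance"))
})
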