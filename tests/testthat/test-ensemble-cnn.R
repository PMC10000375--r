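tinyArch <- function(h = 8L, w = 8L, c = 2L, M = 3L) {
  structure(list(layers = list(
    list(kind = "conv", filters = 3L, kernel = 3L, stride = 1L, pad = 1L),
    list(kind = "relu"),
    list(kind = "maxpool", kernel = 2L, stride = 2L, pad = 0L),
    list(kind = "fc", units = 6L),
    list(kind = "relu"),
    list(kind = "fc", units = M),
    list(kind = "softmax")),
    inputShape = c(h, w, c), M = M, scale = 1),
    class = "CNNArchitecture")
}

test_that("analytic gradients match finite differences", {
  set.seed(5)
  arch <- tinyArch()
  x <- array(runif(8 * 8 * 2 * 4), dim = c(8, 8, 2, 4))
  y <- c(1L, 2L, 3L, 1L)
  w <- retinopipe:::.cnnInit(arch, arch$inputShape, 7L)
  g <- retinopipe:::.cnnGrad(x, y, arch, arch$inputShape, w)
  eps <- 1e-3
  for (li in seq_along(w)) {
    idx <- cbind(sample(nrow(w[[li]]$W), 4, replace = TRUE),
                 sample(ncol(w[[li]]$W), 4, replace = TRUE))
    for (k in seq_len(nrow(idx))) {
      wp <- w; wm <- w
      wp[[li]]$W[idx[k, 1], idx[k, 2]] <- wp[[li]]$W[idx[k, 1], idx[k, 2]] + eps
      wm[[li]]$W[idx[k, 1], idx[k, 2]] <- wm[[li]]$W[idx[k, 1], idx[k, 2]] - eps
      num <- (retinopipe:::.cnnLoss(x, y, arch, arch$inputShape, wp) -
              retinopipe:::.cnnLoss(x, y, arch, arch$inputShape, wm)) / (2 * eps)
      expect_equal(g[[li]]$W[idx[k, 1], idx[k, 2]], num, tolerance = 5e-2)
    }
    # one bias per layer
    wp <- w; wm <- w
    wp[[li]]$b[1] <- wp[[li]]$b[1] + eps
    wm[[li]]$b[1] <- wm[[li]]$b[1] - eps
    num <- (retinopipe:::.cnnLoss(x, y, arch, arch$inputShape, wp) -
            retinopipe:::.cnnLoss(x, y, arch, arch$inputShape, wm)) / (2 * eps)
    expect_equal(g[[li]]$b[1], num, tolerance = 5e-2)
  }
})

test_that("subspace masks have the right size and are seeded", {
  masks <- sampleSubspaces(6, 0.5, 4, seed = 3)
  expect_length(masks, 4L)
  expect_true(all(vapply(masks, length, integer(1)) == 3L))
  expect_identical(masks, sampleSubspaces(6, 0.5, 4, seed = 3))
  full <- sampleSubspaces(5, 1, 3, seed = 0)
  expect_true(all(vapply(full, identical, logical(1), 1:5)))
  expect_error(sampleSubspaces(5, 0, 3), "rFraction")
})

test_that("augmentation is the identity at zero ranges and seeded", {
  img <- fundusImage(fixtureFundus("DR", 120))
  expect_identical(augmentImage(img), img)
  a1 <- augmentImage(img, rotation = 20, widthShift = 0.1, zoom = 0.1,
                     hflip = TRUE, seed = 5)
  a2 <- augmentImage(img, rotation = 20, widthShift = 0.1, zoom = 0.1,
                     hflip = TRUE, seed = 5)
  expect_identical(a1, a2)
  expect_false(identical(a1, img))
  expect_true(all(a1 >= 0 & a1 <= 1))
})

test_that("inverse-pair shifts cancel up to interpolation error", {
  img <- fundusImage(fixtureFundus("DR", 121))
  shifted <- augmentImage(img, widthShift = 0.25, seed = 31)
  # recover the drawn shift and undo it; interior pixels must match
  drawn <- withr::with_seed(31, {
    runif(1, 0, 0)          # rotation draw
    runif(1, 0, 0)          # shear draw
    exp(runif(1, 0, 0))     # zoom draw
    runif(1, -0.25, 0.25)   # width shift draw
  })
  px <- round(drawn * dim(img)[2])
  interior <- 17:48
  back <- if (px >= 0) shifted[, interior + px, , drop = FALSE]
          else shifted[, interior + px, , drop = FALSE]
  expect_equal(dim(back)[2], length(interior))
  expect_lt(mean(abs(back - img[, interior, , drop = FALSE])), 0.08)
})

test_that("a short training run reduces the loss on separable data", {
  set.seed(2)
  n <- 30
  x <- array(0, dim = c(8, 8, 2, n))
  y <- rep(1:3, length.out = n)
  for (i in seq_len(n)) {    # class-dependent mean patterns + noise
    x[, , 1, i] <- 0.2 + 0.25 * (y[i] - 1) + runif(64, 0, 0.05)
    x[, , 2, i] <- 0.8 - 0.25 * (y[i] - 1) + runif(64, -0.05, 0)
  }
  m <- trainMember(x, y, tinyArch(), mask = 1:2, epochs = 15, batchSize = 8,
                   lr = 1e-2, seed = 1)
  expect_lt(m$loss[length(m$loss)], m$loss[1])
  p <- retinopipe:::memberScores(m, x)
  expect_gte(mean(max.col(p) == y), 0.9)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(3)
  x <- array(runif(8 * 8 * 2 * 12), dim = c(8, 8, 2, 12))
  y <- rep(1:3, 4)
  m1 <- trainMember(x, y, tinyArch(), mask = 1:2, epochs = 2, seed = 9)
  m2 <- trainMember(x, y, tinyArch(), mask = 1:2, epochs = 2, seed = 9)
  expect_identical(m1$weights, m2$weights)
})

test_that("input normalization is enforced", {
  x <- array(2, dim = c(8, 8, 2, 2))
  expect_error(trainMember(x, c(1L, 2L), tinyArch(), mask = 1:2),
               "normalized")
})

test_that("fusion is the weighted average with low-index tie-breaks", {
  set.seed(4)
  x <- array(runif(32 * 32 * 2 * 9), dim = c(32, 32, 2, 9))
  y <- rep(1:3, 3)
  model <- trainEnsemble(x, y, classNames = c("a", "b", "c"), L = 2,
                         rFraction = 1, scale = 0.02, epochs = 1,
                         batchSize = 4, seed = 0)
  # hand-build the fusion from member scores
  pred <- predictEnsemble(model, x)
  manual <- 0.5 * pred$memberScores[[1]] + 0.5 * pred$memberScores[[2]]
  expect_equal(unname(pred$scores), unname(manual), tolerance = 1e-12)
  expect_equal(unname(rowSums(pred$scores)), rep(1, 9), tolerance = 1e-6)
  # convex combination bounds per class
  for (cl in 1:3) {
    lo <- pmin(pred$memberScores[[1]][, cl], pred$memberScores[[2]][, cl])
    hi <- pmax(pred$memberScores[[1]][, cl], pred$memberScores[[2]][, cl])
    expect_true(all(pred$scores[, cl] >= lo - 1e-9 &
                    pred$scores[, cl] <= hi + 1e-9))
  }
  # degenerate weights reduce fusion to a single member
  model2 <- model
  model2@weights <- c(1, 0)
  pred2 <- predictEnsemble(model2, x)
  expect_equal(unname(pred2$scores), unname(pred2$memberScores[[1]]))
  # explicit tie: equal scores pick the lowest class index
  tie <- matrix(c(0.5, 0.5, 0), 1)
  expect_identical(c("a", "b", "c")[max.col(tie, ties.method = "first")], "a")
})

test_that("classifier and ensemble diversity follow their definitions", {
  a <- c(1, 1, 2, 3)
  expect_equal(classifierDiversity(a, a), 0)
  expect_equal(classifierDiversity(c(1, 1, 1, 1), c(2, 2, 2, 2)), 1)
  expect_equal(classifierDiversity(rep(1, 100), c(rep(2, 25), rep(1, 75))),
               0.25)
  expect_error(classifierDiversity(integer(0), integer(0)), "empty")
  set.seed(6)
  x <- array(runif(32 * 32 * 2 * 6), dim = c(32, 32, 2, 6))
  y <- rep(1:3, 2)
  model <- trainEnsemble(x, y, L = 2, rFraction = 0.5, scale = 0.02,
                         epochs = 1, batchSize = 3, seed = 1)
  pred <- predictEnsemble(model, x)
  l1 <- max.col(pred$memberScores[[1]], ties.method = "first")
  l2 <- max.col(pred$memberScores[[2]], ties.method = "first")
  expect_equal(ensembleDiversity(model, x), classifierDiversity(l1, l2))
  one <- model
  one@members <- model@members[1]
  one@subspaceMasks <- model@subspaceMasks[1]
  one@weights <- 1
  expect_error(ensembleDiversity(one, x), "2 members")
})
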