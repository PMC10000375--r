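test_that("prey energy decays linearly and validates its iteration", {
  expect_equal(preyEnergy(0.8, 100, 100), 0)
  expect_equal(preyEnergy(0.8, 0, 100), 1.6)
  expect_equal(preyEnergy(-0.5, 50, 100), -0.5)
  expect_error(preyEnergy(0.5, 101, 100), "iter")
})

test_that("jump strength maps [0,1] onto [2,0]", {
  expect_equal(jumpStrength(1), 0)
  expect_equal(jumpStrength(0), 2)
  expect_equal(jumpStrength(0.5), 1)
  expect_error(jumpStrength(1.2), "r5")
})

test_that("Levy steps are seeded, shaped, and heavier-tailed than Gaussian", {
  expect_identical(levyStep(3, seed = 4), levyStep(3, seed = 4))
  expect_length(levyStep(3, seed = 1), 3L)
  draws <- levyStep(1e5, seed = 0)
  z <- (draws - mean(draws)) / sd(draws)
  kurtosis <- mean(z^4)
  expect_gt(kurtosis, 3)
})

test_that("hawk update follows the documented branch structure", {
  lb <- c(0, 0); ub <- c(10, 10)
  # hard besiege with prey == current: fixed point
  X <- c(4, 4)
  out <- hawkUpdate(X, 1, Xp = X, Xrand = c(1, 1), Xa = c(5, 5), Ep = 0,
                    lb, ub, draws = list(r = 0.9, r5 = 0.5))
  expect_equal(out, X)
  # |Ep| >= 2 takes the exploration branch: with q >= 0.5 the update uses
  # Xrand, never the prey
  out <- hawkUpdate(c(2, 2), 1, Xp = c(9, 9), Xrand = c(5, 5), Xa = c(3, 3),
                    Ep = 2, lb, ub,
                    draws = list(q = 0.9, r1 = 0, r2 = 0.5))
  expect_equal(out, c(5, 5))   # Xrand - 0 * |...|
  # rapid dive where neither Y nor Z improves keeps the current position
  worse <- function(x) -sum(x)   # current position is the best in the box
  out <- hawkUpdate(c(10, 10), worse(c(10, 10)), Xp = c(10, 10),
                    Xrand = c(0, 0), Xa = c(5, 5), Ep = 0.6, lb, ub,
                    objective = worse,
                    draws = list(r = 0.1, r5 = 0.5, B = c(0.5, 0.5),
                                 levy = c(-1, -1)))
  expect_equal(out, c(10, 10))
})

test_that("optimization converges on the sphere and stays in the box", {
  sphere <- function(x) sum((x - 3)^2)
  res <- hhoOptimize(sphere, hhoConfig(20, 200, c(0, 0), c(5, 5), seed = 0))
  expect_lte(bestFitness(res), 1e-4)
  expect_true(all(bestPosition(res) >= 0 & bestPosition(res) <= 5))
  expect_true(all(diff(fitnessHistory(res)) <= 0))
  expect_length(fitnessHistory(res), 200L)
})

test_that("single-iteration run returns the fittest initial hawk", {
  obj <- function(x) sum(x^2)
  res <- hhoOptimize(obj, hhoConfig(10, 1, c(-1, -1), c(1, 1), seed = 2))
  expect_length(fitnessHistory(res), 1L)
  expect_equal(bestFitness(res), obj(bestPosition(res)))
})

test_that("constant objectives and non-finite objectives are handled", {
  res <- hhoOptimize(function(x) 7, hhoConfig(5, 3, 0, 1, seed = 1))
  expect_equal(bestFitness(res), 7)
  expect_error(
    hhoOptimize(function(x) NaN, hhoConfig(5, 3, 0, 1, seed = 1)),
    "non-finite")
})

test_that("runs are reproducible under a fixed config seed", {
  obj <- function(x) sum((x - 1)^2)
  cfg <- hhoConfig(8, 20, c(0, 0), c(2, 2), seed = 11)
  expect_identical(bestPosition(hhoOptimize(obj, cfg)),
                   bestPosition(hhoOptimize(obj, cfg)))
})
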