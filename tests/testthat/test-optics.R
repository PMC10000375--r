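test_that("core distance matches its definition on small cases", {
  s <- matrix(c(0, 1, 2, 3), ncol = 1)
  expect_equal(coreDistance(s, 2, MinPts = 2, eps = 5), 1)
  # isolated point: nearest neighbour beyond eps
  s2 <- matrix(c(0, 10), ncol = 1)
  expect_true(is.na(coreDistance(s2, 1, MinPts = 2, eps = 5)))
  # duplicates give zero core distance
  s3 <- matrix(c(1, 1, 5), ncol = 1)
  expect_equal(coreDistance(s3, 1, MinPts = 2, eps = 2), 0)
  expect_error(coreDistance(s3, 9, MinPts = 2, eps = 2), "out of range")
})

test_that("reachability distance is the max of core distance and distance", {
  s <- matrix(c(0, 2, 3, 4, 9), ncol = 1)
  # o = 3 (value 3): neighbours within eps=2 are {2,3,4}; core = 1
  expect_equal(reachabilityDistance(5, 3, s, MinPts = 3, eps = 2), 6) # D wins
  expect_equal(reachabilityDistance(2, 3, s, MinPts = 3, eps = 2), 1) # core wins
  # non-core o: undefined
  expect_true(is.na(reachabilityDistance(1, 5, s, MinPts = 3, eps = 2)))
})

test_that("queue-based ordering matches the brute-force reference", {
  set.seed(0)
  pts <- matrix(runif(2 * 200), ncol = 2)
  prof <- opticsOrder(pts, MinPts = 5, eps = 0.1)
  ref <- bfOptics(pts, MinPts = 5, eps = 0.1)
  expect_identical(opticsOrdering(prof), as.integer(ref$order))
  expect_equal(coreDistances(prof), ref$core, tolerance = 1e-9)
  expect_equal(reachDistances(prof), ref$reach, tolerance = 1e-9)
  expect_true(all(reachDistances(prof) >= 0, na.rm = TRUE))
})

test_that("degenerate profiles behave", {
  prof <- opticsOrder(matrix(0.5, 1, 2), MinPts = 2, eps = 0.1)
  expect_identical(opticsOrdering(prof), 1L)
  expect_true(is.na(reachDistances(prof)))
})

test_that("two far-apart clusters produce exactly one large spike", {
  set.seed(3)
  a <- matrix(rnorm(2 * 50, sd = 0.03), ncol = 2)
  b <- sweep(matrix(rnorm(2 * 50, sd = 0.03), ncol = 2), 2, c(2, 0), `+`)
  pts <- rbind(a, b)
  prof <- opticsOrder(pts, MinPts = 5, eps = 5)
  r <- reachDistances(prof)
  expect_identical(sum(r > 1, na.rm = TRUE), 1L)  # single inter-cluster jump
})

test_that("cluster extraction recovers well-separated Gaussian blobs", {
  set.seed(7)
  a <- matrix(rnorm(2 * 100, sd = 0.05), ncol = 2)
  b <- sweep(matrix(rnorm(2 * 100, sd = 0.05), ncol = 2), 2, c(1, 0), `+`)
  pts <- rbind(a, b)
  truth <- rep(1:2, each = 100)
  prof <- opticsOrder(pts, MinPts = 5, eps = 0.5)
  labels <- extractClusters(prof, 0.1)
  expect_gte(adjustedRand(labels, truth), 0.9)
  # idempotent on the profile
  expect_identical(extractClusters(prof, 0.1), labels)
})

test_that("extraction thresholds behave at the extremes", {
  set.seed(9)
  pts <- matrix(runif(2 * 60), ncol = 2)
  prof <- opticsOrder(pts, MinPts = 4, eps = 2)
  # threshold above all reachabilities: one cluster per connected run
  hi <- extractClusters(prof, max(reachDistances(prof), na.rm = TRUE) + 1)
  expect_identical(sort(unique(hi[hi > 0])), 1L)
  # threshold 0: nothing can open a cluster unless core distance is 0
  lo <- extractClusters(prof, 0)
  expect_true(all(lo == -1L))
})

test_that("Jaccard distance is a metric on sampled set triples", {
  expect_equal(jaccardDistance(1:4, 1:4), 0)
  expect_equal(jaccardDistance(1:3, 4:6), 1)
  expect_equal(jaccardDistance(1, c(1, 2)), 0.5)
  expect_equal(jaccardDistance(integer(0), integer(0)), 0)
  set.seed(11)
  for (i in 1:25) {
    A <- sample(1:12, sample(0:6, 1))
    B <- sample(1:12, sample(0:6, 1))
    C <- sample(1:12, sample(0:6, 1))
    expect_equal(jaccardDistance(A, B), jaccardDistance(B, A))
    expect_equal(jaccardDistance(A, A), 0)
    expect_lte(jaccardDistance(A, C),
               jaccardDistance(A, B) + jaccardDistance(B, C) + 1e-12)
  }
})
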