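test_that("preprocessing with neutral settings is the identity", {
  img <- ShgImage(matrix(runif(400, 5, 50), 20, 20))
  out <- preprocessShg(img, medianRadiusPx = 0L, backgroundPercentile = 0)
  expect_equal(intensities(out), intensities(img))
  expect_equal(pixelSize(out), pixelSize(img))
})

test_that("background subtraction at a high percentile empties a flat image", {
  img <- ShgImage(matrix(7, 16, 16))
  out <- preprocessShg(img, medianRadiusPx = 0L, backgroundPercentile = 99.9)
  expect_true(all(intensities(out) == 0))
})

test_that("a median filter of radius 1 removes an isolated hot pixel", {
  m <- matrix(10, 9, 9)
  m[5, 5] <- 500
  out <- preprocessShg(ShgImage(m), medianRadiusPx = 1L,
                       backgroundPercentile = 0)
  expect_equal(max(intensities(out)), 10, tolerance = 1e-3)
  expect_equal(dim(out), c(9L, 9L))
})

test_that("two well-separated plateaus recover exact centroids and crisp membership", {
  res <- fuzzyCMeans(c(0, 0, 0, 10, 10, 10), FcmConfig(nClusters = 2L))
  expect_equal(centroids(res), c(0, 10), tolerance = 1e-8)
  u <- membership(res)
  expect_equal(u[1:3, 1], rep(1, 3))   # zero-distance rule
  expect_equal(u[4:6, 2], rep(1, 3))
})

test_that("membership rows always sum to one", {
  set.seed(11)
  x <- rnorm(300, 50, 20)
  for (cc in 2:3) {
    res <- fuzzyCMeans(x, FcmConfig(nClusters = cc))
    expect_lt(max(abs(rowSums(membership(res)) - 1)), 1e-9)
    expect_true(all(membership(res) >= 0 & membership(res) <= 1))
  }
})

test_that("fewer distinct values than clusters is a degenerate-input error", {
  expect_error(fuzzyCMeans(c(1, 1, 1, 2), FcmConfig(nClusters = 3L)),
               "degenerate")
})

test_that("the clustering objective never increases across iterations", {
  for (s in 1:5) {
    set.seed(s)
    x <- c(rnorm(150, 20, 8), rnorm(100, 120, 25))
    res <- fuzzyCMeans(x, FcmConfig(nClusters = 2L))
    expect_true(all(diff(res@objectiveTrace) <= 1e-9))
  }
})

test_that("converged objective matches a multi-restart oracle on a small input", {
  set.seed(21)
  x <- runif(120, 0, 100)
  res <- fuzzyCMeans(x, FcmConfig(nClusters = 2L, tol = 1e-12,
                                  maxIter = 5000L))
  best <- fcmRestartOracle(x, c = 2, m = 2, restarts = 20, seed = 2)
  expect_lt(abs(res@objective - best), 1e-6)
})

test_that("near-crisp fuzziness reproduces k-means assignments", {
  set.seed(31)
  x <- c(rnorm(120, 0, 1), rnorm(120, 12, 1))
  cfg <- FcmConfig(nClusters = 2L, fuzziness = 1.05)
  res <- fuzzyCMeans(x, cfg)
  hard <- max.col(membership(res))
  init <- quantile(x, probs = c(0.25, 0.75), names = FALSE)
  km <- kmeans(x, centers = matrix(sort(init), ncol = 1))
  kmLab <- km$cluster
  if (km$centers[1] > km$centers[2]) kmLab <- 3L - kmLab
  expect_equal(hard, unname(kmLab))
})

test_that("segmentation extracts exactly the bright plateau", {
  m <- matrix(10, 20, 20)
  m[, 11:20] <- 200
  mask <- segmentFibers(ShgImage(m))
  expect_identical(maskArray(mask), m == 200)
})

test_that("a constant image yields an empty mask with a warning", {
  expect_warning(mask <- segmentFibers(ShgImage(matrix(5, 12, 12))),
                 "distinct")
  expect_false(any(maskArray(mask)))
  expect_equal(dim(mask), c(12L, 12L))
})

test_that("segmentation is invariant to positive affine intensity rescaling", {
  out <- simulateFiberImage(FiberImageParams(shape = c(128L, 128L),
                                             targetFraction = 0.08,
                                             seed = 13L))
  x <- intensities(out$image)
  m1 <- segmentFibers(ShgImage(x))
  m2 <- segmentFibers(ShgImage(3.7 * x + 11))
  expect_identical(maskArray(m1), maskArray(m2))
})

test_that("stacks are max-projected by default and per-slice on request", {
  sl1 <- matrix(10, 16, 16)
  sl2 <- matrix(10, 16, 16)
  sl2[5:12, 5:12] <- 200
  stack <- ShgImage(array(c(sl1, sl2), dim = c(16, 16, 2)))
  proj <- segmentFibers(stack)
  expect_equal(length(dim(proj)), 2L)
  expect_identical(maskArray(proj), sl2 == 200)
  suppressWarnings(per <- segmentFibers(stack, projection = "slice"))
  expect_equal(dim(per), c(16L, 16L, 2L))
  expect_false(any(maskArray(per)[, , 1]))
})

test_that("segmentation of a seeded synthetic image overlaps the truth", {
  out <- simulateFiberImage(FiberImageParams(seed = 7L))
  mask <- segmentFibers(out$image)
  expect_gte(jaccard(maskArray(mask), maskArray(out$truth)), 0.6)
})
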