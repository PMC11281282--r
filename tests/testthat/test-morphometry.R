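test_that("an empty mask yields no components and an empty filtered mask", {
  mask <- FiberMask(matrix(FALSE, 10, 10))
  comp <- labelFiberComponents(mask)
  expect_equal(nrow(comp), 0L)
  filt <- shapeFilter(comp)
  expect_false(any(maskArray(filt)))
  expect_equal(dim(filt), c(10L, 10L))
})

test_that("diagonal touching follows the configured connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE
  m[3, 3] <- TRUE
  c8 <- labelFiberComponents(FiberMask(m),
                             ShapeFilterConfig(connectivity = 8L))
  c4 <- labelFiberComponents(FiberMask(m),
                             ShapeFilterConfig(connectivity = 4L))
  expect_equal(nrow(c8), 1L)
  expect_equal(nrow(c4), 2L)
})

test_that("a straight bar measures its closed-form length and width", {
  m <- matrix(FALSE, 20, 70)
  m[9:11, 11:60] <- TRUE            # 50 x 3 px bar
  comp <- labelFiberComponents(FiberMask(m, pixelSizeUm = 0.497))
  expect_equal(nrow(comp), 1L)
  expect_lt(abs(comp$skeleton_length_um - 49 * 0.497), 0.497)  # +- 1 px
  expect_lt(abs(comp$mean_width_um - 3 * 0.497) / (3 * 0.497), 0.30)
})

test_that("the shape filter drops disks and keeps bars", {
  px <- 0.497
  disk <- matrix(FALSE, 30, 30)
  for (i in 1:30) for (j in 1:30)
    if ((i - 15)^2 + (j - 15)^2 <= 64) disk[i, j] <- TRUE
  compD <- labelFiberComponents(FiberMask(disk, pixelSizeUm = px))
  expect_lt(compD$aspect, 2)
  expect_false(any(maskArray(shapeFilter(compD))))

  bar <- matrix(FALSE, 20, 80)
  bar[9:11, 11:70] <- TRUE          # 60 x 3 px bar
  compB <- labelFiberComponents(FiberMask(bar, pixelSizeUm = px))
  filt <- shapeFilter(compB)
  expect_identical(maskArray(filt), bar)
})

test_that("shape-filter output is always a subset of its input", {
  for (s in 1:3) {
    out <- simulateFiberImage(FiberImageParams(shape = c(128L, 128L),
                                               targetFraction = 0.08,
                                               seed = s))
    raw <- segmentFibers(out$image)
    filt <- shapeFilter(labelFiberComponents(raw))
    expect_false(any(maskArray(filt) & !maskArray(raw)))
  }
})

test_that("percent fiber volume computes the voxel fraction", {
  expect_equal(percentFiberVolume(FiberMask(matrix(FALSE, 5, 5))), 0)
  expect_equal(percentFiberVolume(FiberMask(matrix(TRUE, 5, 5))), 100)
  m <- matrix(FALSE, 20, 50)
  m[seq_len(250)] <- TRUE
  expect_equal(percentFiberVolume(FiberMask(m)), 25)
  expect_error(percentFiberVolume(array(logical(0), dim = c(0L, 0L))),
               "zero-size")
})

test_that("percent fiber volume is monotone under mask union", {
  set.seed(17)
  a <- matrix(runif(400) < 0.2, 20, 20)
  b <- matrix(runif(400) < 0.2, 20, 20)
  expect_gte(percentFiberVolume(FiberMask(a | b)),
             percentFiberVolume(FiberMask(a)))
})

test_that("patient aggregation returns means, standard errors and flags", {
  fovs <- data.frame(patient_id = c("P1", "P1", "P1", "P2"),
                     group = c("recurrent", "recurrent", "recurrent",
                               "non_recurrent"),
                     percent_fiber_volume = c(10, 20, 30, 5))
  agg <- patientAggregate(fovs)
  p1 <- agg[agg$patient_id == "P1", ]
  expect_equal(p1$mean_volume, 20)
  expect_equal(p1$se, 10 / sqrt(3), tolerance = 1e-12)
  expect_true(p1$se_defined)
  p2 <- agg[agg$patient_id == "P2", ]
  expect_equal(p2$se, 0)
  expect_false(p2$se_defined)
})

test_that("conflicting group labels within a patient are an error", {
  fovs <- data.frame(patient_id = c("P1", "P1"),
                     group = c("recurrent", "non_recurrent"),
                     percent_fiber_volume = c(1, 2))
  expect_error(patientAggregate(fovs), "conflicting group")
})

test_that("patient means are less variable than raw FOV values", {
  co <- simulateCohort(CohortParams(seed = 9L))
  agg <- patientAggregate(co$fovs)
  expect_lt(var(log(agg$mean_volume)),
            var(log(co$fovs$percent_fiber_volume)))
})

test_that("estimates track the truth on small synthetic images", {
  res <- vapply(1:5, function(s) {
    c(lo = estimateFraction(0.05, s, shape = c(256L, 256L))[["estimate"]],
      hi = estimateFraction(0.15, s, shape = c(256L, 256L))[["estimate"]])
  }, numeric(2))
  expect_true(all(res["hi", ] > res["lo", ]))
  expect_lt(abs(mean(res["lo", ]) - 5) / 5, 0.25)
  expect_lt(abs(mean(res["hi", ]) - 15) / 15, 0.25)
})

test_that("blob-only images are emptied by the shape filter", {
  out <- simulateFiberImage(FiberImageParams(
    shape = c(256L, 256L), nFibers = 0L, targetFraction = NA, nBlobs = 12L,
    seed = 23L))
  est <- extractFibers(out$image)
  expect_lt(est$percentFiberVolume, 0.5)
})
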