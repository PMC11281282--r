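test_that("fiber-free, blob-free parameters give an empty truth over pure noise", {
  out <- simulateFiberImage(FiberImageParams(
    shape = c(64L, 64L), nFibers = 0L, nBlobs = 0L, targetFraction = NA,
    seed = 4L))
  expect_false(any(maskArray(out$truth)))
  img <- intensities(out$image)
  expect_true(sd(img) > 0)
  expect_true(all(img >= 0))
})

test_that("truth-mask fraction tracks the target fraction", {
  out <- simulateFiberImage(FiberImageParams(targetFraction = 0.10,
                                             seed = 7L))
  frac <- mean(maskArray(out$truth))
  expect_gte(frac, 0.08)
  expect_lte(frac, 0.12)
  # convergence at larger grids: within 10% relative
  big <- simulateFiberImage(FiberImageParams(shape = c(1024L, 1024L),
                                             targetFraction = 0.10,
                                             seed = 2L))
  expect_lt(abs(mean(maskArray(big$truth)) - 0.10) / 0.10, 0.10)
})

test_that("image generation is bit-identical under a fixed seed", {
  p <- FiberImageParams(shape = c(96L, 96L), seed = 42L)
  a <- simulateFiberImage(p)
  b <- simulateFiberImage(p)
  expect_identical(intensities(a$image), intensities(b$image))
  expect_identical(maskArray(a$truth), maskArray(b$truth))
})

test_that("impossible fiber geometry is rejected", {
  expect_error(FiberImageParams(shape = c(16L, 16L), fiberWidthPx = 20),
               "impossible geometry")
})

test_that("degenerate cohort variances give identical FOV volumes", {
  co <- simulateCohort(CohortParams(sdBetween = 0, sdWithin = 0,
                                    groupEffectLog = 0, seed = 1L))
  expect_equal(length(unique(co$fovs$percent_fiber_volume)), 1L)
})

test_that("cohort tables satisfy their structural invariants", {
  co <- simulateCohort(CohortParams(seed = 3L))
  expect_true(all(co$fovs$percent_fiber_volume > 0))
  expect_true(all(co$patients$time > 0))
  expect_true(all(co$patients$event %in% c(0L, 1L)))
  expect_true(all(co$patients$n_fov >= 6 & co$patients$n_fov <= 18))
  expect_equal(nrow(co$patients), 26L)
  expect_equal(sum(co$patients$group == "recurrent"), 14L)
  # reproducibility
  co2 <- simulateCohort(CohortParams(seed = 3L))
  expect_identical(co, co2)
})

test_that("group effect on the log scale is recovered at large n", {
  co <- simulateCohort(CohortParams(nPatientsPerGroup = 1000L,
                                    groupEffectLog = 0.5, seed = 5L))
  lv <- log(co$fovs$percent_fiber_volume)
  d <- mean(lv[co$fovs$group == "recurrent"]) -
    mean(lv[co$fovs$group == "non_recurrent"])
  expect_lt(abs(d - 0.5), 0.05)
})

test_that("cohorts with fewer than 2 patients per group are rejected", {
  expect_error(CohortParams(nPatientsPerGroup = 1L), "at least 2 patients")
})

test_that("planted DE genes carry their stated fold change", {
  tab <- simulateDeTable(500L, planted = c(COL1A1 = 2.63), seed = 8L)
  row <- tab[tab$symbol == "COL1A1", ]
  expect_equal(nrow(row), 1L)
  expect_lt(abs(row$log2fc - 2.63), 0.1)
  expect_lt(row$padj, 0.01)
})

test_that("a single-gene table has padj equal to its p-value", {
  tab <- simulateDeTable(1L, planted = c(GENE = 1), seed = 1L)
  expect_identical(tab$padj, tab$pvalue)
})

test_that("duplicate planted symbols are rejected", {
  expect_error(
    simulateDeTable(10L, planted = c(A = 1, A = 2)), "duplicate")
  expect_error(simulateDeTable(1L, planted = c(A = 1, B = 2)), "at least")
})

test_that("null DE tables yield almost no BH discoveries", {
  counts <- vapply(1:200, function(s) {
    tab <- simulateDeTable(100L, seed = s)
    sum(tab$padj <= 0.05)
  }, numeric(1))
  expect_lt(mean(counts), 0.2)
})
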