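test_that("identical groups give t = 0 and a two-sided p of 1", {
  res <- tTestOneTailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p_two_sided, 1)
})

test_that("summary-statistic input reproduces a printed demographic p-value", {
  res <- tTestOneTailed(c(mean = 42.0, sd = 6.5, n = 12),
                        c(mean = 47.9, sd = 6.6, n = 14),
                        alternative = "less")
  # two-decimal summary inputs: printed 0.0326, recomputed within rounding
  expect_lt(abs(res$p_two_sided - 0.0326), 0.003)
  expect_equal(res$df, 24)
})

test_that("raw-value and matching summary inputs agree to 1e-12", {
  set.seed(53)
  a <- rnorm(9, 10, 2)
  b <- rnorm(14, 12, 3)
  r1 <- tTestOneTailed(a, b)
  r2 <- tTestOneTailed(c(mean = mean(a), sd = sd(a), n = length(a)),
                       c(mean = mean(b), sd = sd(b), n = length(b)))
  expect_lt(abs(r1$p_two_sided - r2$p_two_sided), 1e-12)
  expect_lt(abs(r1$p_one_sided - r2$p_one_sided), 1e-12)
})

test_that("p-values agree with the reference implementation on random pairs", {
  set.seed(61)
  for (i in 1:500) {
    a <- rnorm(sample(3:12, 1), 0, exp(runif(1, -1, 1)))
    b <- rnorm(sample(3:12, 1), runif(1, -2, 2), exp(runif(1, -1, 1)))
    pooled <- i %% 2 == 0
    mine <- tTestOneTailed(a, b, alternative = "greater", pooled = pooled)
    ref2 <- t.test(a, b, var.equal = pooled)$p.value
    ref1 <- t.test(a, b, var.equal = pooled,
                   alternative = "greater")$p.value
    expect_lt(abs(mine$p_two_sided - ref2), 1e-10)
    expect_lt(abs(mine$p_one_sided - ref1), 1e-10)
  }
})

test_that("zero variance in both groups with equal means is an error", {
  expect_error(tTestOneTailed(c(5, 5, 5), c(5, 5, 5)), "zero variance")
})

test_that("with no between-patient variance the mixed model matches the raw contrast", {
  co <- simulateCohort(CohortParams(sdBetween = 0, seed = 71L))
  fit <- fitRandomIntercept(co$fovs)
  lv <- log(co$fovs$percent_fiber_volume)
  d <- mean(lv[co$fovs$group == "recurrent"]) -
    mean(lv[co$fovs$group == "non_recurrent"])
  expect_lt(abs(fit$beta_group - d), 2 * fit$se_beta)
  expect_gte(fit$var_between, 0)
})

test_that("the group effect is invariant to rescaling all volumes", {
  co <- simulateCohort(CohortParams(seed = 73L))
  f1 <- fitRandomIntercept(co$fovs)
  fovs2 <- co$fovs
  fovs2$percent_fiber_volume <- fovs2$percent_fiber_volume * 3
  f2 <- fitRandomIntercept(fovs2)
  expect_equal(f1$beta_group, f2$beta_group, tolerance = 1e-6)
  expect_equal(f1$p_two_sided, f2$p_two_sided, tolerance = 1e-6)
})

test_that("non-positive volumes abort by default and are offset on request", {
  co <- simulateCohort(CohortParams(seed = 79L))
  fovs <- co$fovs
  fovs$percent_fiber_volume[3] <- 0
  expect_error(fitRandomIntercept(fovs), "non-positive")
  fit <- fitRandomIntercept(fovs, zeroPolicy = "offset")
  expect_match(fit$transform, "log\\(x \\+")
  expect_true(is.finite(fit$beta_group))
})

test_that("one-sided mixed-model p follows the direction of the effect", {
  co <- simulateCohort(CohortParams(groupEffectLog = 1.2, seed = 83L))
  fit <- fitRandomIntercept(co$fovs)
  expect_gt(fit$beta_group, 0)
  expect_equal(fit$p_one_sided, fit$p_two_sided / 2)
})

test_that("the median split partitions with ties going low", {
  p4 <- data.frame(patient_id = paste0("P", 1:4),
                   mean_volume = c(1, 2, 3, 4))
  sp <- medianSplit(p4)
  expect_equal(sp$threshold, 2.5)
  expect_setequal(sp$high$patient_id, c("P3", "P4"))
  p5 <- data.frame(patient_id = paste0("P", 1:5),
                   mean_volume = c(1, 2, 3, 4, 5))
  sp5 <- medianSplit(p5)
  expect_equal(sp5$threshold, 3)
  expect_true("P3" %in% sp5$low$patient_id)   # tie at the median goes low
  expect_equal(sort(c(sp5$high$patient_id, sp5$low$patient_id)),
               paste0("P", 1:5))
  expect_equal(sp5$tie_policy, "ties_to_low")
  expect_error(medianSplit(data.frame(patient_id = 1:4,
                                      mean_volume = rep(2, 4))),
               "identical")
})

test_that("the product-limit estimator matches hand computation", {
  km <- kaplanMeier(c(1, 2, 3, 4, 5), c(1, 0, 1, 1, 0))
  expect_equal(km$surv[km$time == 1], 4 / 5)
  expect_equal(km$surv[km$time == 3], 4 / 5 * 2 / 3)
  expect_equal(km$surv[km$time == 4], 4 / 5 * 2 / 3 * 1 / 2)
  # no events: flat at 1
  flat <- kaplanMeier(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(flat$surv == 1))
  # all events at distinct times: S(t_k) = (n - k)/n
  n <- 7
  all7 <- kaplanMeier(seq_len(n), rep(1, n))
  expect_equal(all7$surv, (n - seq_len(n)) / n)
})

test_that("survival curves are non-increasing and within [0, 1]", {
  set.seed(97)
  for (i in 1:20) {
    tm <- rexp(15, 0.2)
    ev <- rbinom(15, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    km <- kaplanMeier(tm, ev)
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_true(all(km$surv >= 0 & km$surv <= 1))
  }
})

test_that("identical survival groups give chi2 = 0 and HR = 1", {
  g <- data.frame(time = c(1, 2, 3, 4), event = c(1, 0, 1, 1))
  res <- logrankHazardRatio(g, g)
  expect_lt(res$chi2, 1e-10)
  expect_equal(res$hr, 1, tolerance = 1e-10)
})

test_that("the log-rank statistic matches the hand-computed toy example", {
  high <- data.frame(time = c(1, 4), event = c(1, 0))
  low <- data.frame(time = c(2, 5), event = c(1, 0))
  res <- logrankHazardRatio(high, low)
  # hand hypergeometric sums: O_high = 1, E_high = 1/2 + 1/3 = 5/6,
  # V = 1/4 + 2/9; chi2 = (1/6)^2 / (17/36) = 1/17
  expect_equal(res$expected[["high"]], 5 / 6, tolerance = 1e-12)
  expect_equal(res$chi2, 1 / 17, tolerance = 1e-12)
  expect_equal(res$hr, (1 / (5 / 6)) / (1 / (7 / 6)), tolerance = 1e-12)
})

test_that("zero events across both groups is an error", {
  g <- data.frame(time = c(1, 2), event = c(0, 0))
  expect_error(logrankHazardRatio(g, g), "no events")
})

test_that("FOV-level modelling is usually more sensitive than the patient-level test", {
  # with large within-patient scatter the mixed model uses the FOV
  # replication that patient means discard
  wins <- vapply(1:500, function(s) {
    co <- simulateCohort(CohortParams(sdWithin = 1.0, seed = 10000L + s))
    pm <- fitRandomIntercept(co$fovs)$p_one_sided
    agg <- co$patients
    pt <- tTestOneTailed(
      agg$mean_volume[agg$group == "recurrent"],
      agg$mean_volume[agg$group == "non_recurrent"],
      alternative = "greater")$p_one_sided
    pm < pt
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})
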