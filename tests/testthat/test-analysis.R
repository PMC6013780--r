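test_that("observed-crypt classification is monotone with clear boundaries", {
  f <- c(0, 0.03, 0.05, 0.0501, 0.15, 0.9999, 1)
  cls <- classifyObservedCrypt(f)
  expect_equal(as.character(cls),
               c("normal", "normal", "normal", "partial", "partial",
                 "partial", "full"))
  expect_true(all(diff(as.integer(cls)) >= 0))
  # real-data tolerance for 'full' is a configuration choice
  expect_equal(as.character(classifyObservedCrypt(0.995,
                                                  fullThreshold = 0.99)),
               "full")
  expect_error(classifyObservedCrypt(1.5), "\\[0, 1\\]")
})

test_that("decade summaries tabulate classes and stem-cell counts", {
  co <- data.frame(patientId = rep(c("a", "b"), each = 4),
                   ageYears = rep(c(25, 72), each = 4),
                   cryptId = 1:8,
                   oxphosFraction = c(0, 0, 0, 0, 1, 0.18, 0.55, 0))
  s <- decadeSummary(co)
  expect_equal(s$decade, c("21-30", "71-80"))
  expect_equal(s$pctPartial, c(0, 50))
  expect_equal(s$pctFull, c(0, 25))
  expect_equal(s$pctK1, c(0, 25))   # 0.18 -> one deficient stem cell
  expect_equal(s$pctK3, c(0, 25))   # 0.55 -> three
  expect_equal(s$pctK5, c(0, 25))
  # missing decades are absent rather than zero-filled
  expect_false("41-50" %in% s$decade)
  # permutation invariance
  set.seed(601)
  s2 <- decadeSummary(co[sample(nrow(co)), ])
  expect_equal(s2, s)
  # percentages are complete
  expect_equal(s$pctNormal + s$pctPartial + s$pctFull, c(100, 100))
})

test_that("exponential growth fits recover exact curves", {
  ages <- seq(20, 80, by = 10)
  fit <- fitExponentialGrowth(ages, 2 * exp(0.05 * ages))
  expect_equal(fit$a, 2, tolerance = 1e-6)
  expect_equal(fit$b, 0.05, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  set.seed(602)
  noisy <- fitExponentialGrowth(ages, 2 * exp(0.05 * ages) + rnorm(7, 0, 3))
  expect_lt(noisy$r2, 1)
  ord <- sample(7)
  refit <- fitExponentialGrowth(ages[ord], (2 * exp(0.05 * ages))[ord])
  expect_equal(refit$a, 2, tolerance = 1e-6)
  # zeros in early decades are handled (no log-linearisation)
  zfit <- fitExponentialGrowth(c(10, ages), c(0, 2 * exp(0.05 * ages)))
  expect_equal(zfit$b, 0.05, tolerance = 0.05)
  expect_error(fitExponentialGrowth(ages, rep(0, 7)), "degenerate")
  expect_error(fitExponentialGrowth(1:2, 1:2), "3 points")
})

test_that("the partial:full ratio trend test behaves", {
  binned <- data.frame(decade = c("21-30", "41-50", "61-70", "71-80"),
                       pctPartial = c(1, 2, 4, 5), pctFull = c(0.5, 1, 2, 2.5))
  tr <- suppressWarnings(partialFullRatioTrend(binned))  # exact-fit lm note
  expect_equal(tr$slope, 0, tolerance = 1e-12)
  inc <- binned
  inc$pctPartial <- c(1, 3, 9, 15)
  expect_gt(partialFullRatioTrend(inc)$slope, 0)
  zero <- binned
  zero$pctPartial <- c(1, 2.1, 3.9, 5.2)
  zero$pctFull[1] <- 0
  expect_warning(tr0 <- partialFullRatioTrend(zero), "excluded")
  expect_equal(nrow(tr0$ratios), 3L)
  expect_error(suppressWarnings(partialFullRatioTrend(zero[1:3, ])),
               ">= 3 decades")
})

test_that("partial-fraction histograms are normalised and peak near 1/N", {
  one <- data.frame(patientId = "p", ageYears = 50, cryptId = 1,
                    oxphosFraction = 0.15)
  h1 <- partialFractionHistogram(one)
  expect_equal(sum(h1$count), 1L)
  expect_equal(h1$frequency[h1$binLeft == 0.1], 1)

  set.seed(603)
  co <- smallAnalyticCohort()
  h <- partialFractionHistogram(co)
  expect_equal(sum(h$frequency), 1, tolerance = 1e-12)
  peak <- h[which.max(h$frequency), ]
  expect_gte(peak$binRight, 0.15)
  expect_lte(peak$binLeft, 0.25)
  # per-decade shapes stay close to the pooled shape
  hd <- partialFractionHistogram(co, byDecade = TRUE)
  for (d in unique(hd$decade)) {
    sub <- hd[hd$decade == d, ]
    nD <- sum(sub$count)
    common <- match(paste(sub$binLeft), paste(h$binLeft))
    dev <- abs(sub$frequency - h$frequency[common])
    se <- sqrt(pmax(h$frequency[common] * (1 - h$frequency[common]),
                    1e-12) / nD)
    expect_true(all(dev <= 3 * se + 0.02))
  }
  expect_error(partialFractionHistogram(one[0, ]), "no partial")
})

test_that("scoring a cohort against its own table gives zero discrepancy", {
  co <- smallAnalyticCohort()
  target <- decadeSummary(co)
  kCols <- paste0("pctK", 1:5)
  selfScore <- sum(target$nPatients *
                     rowSums((as.matrix(target[, kCols]) -
                                as.matrix(target[, kCols]))^2))
  expect_identical(selfScore, 0)
  expect_error(fitSimulationToCohort(co, pAsymGrid = numeric(0)), "empty")
})

test_that("fitting the fate bias on neutral data returns a near-zero bias", {
  set.seed(604)
  dr <- driftParams(lambda = 0.6)
  ind <- inductionParams()
  binned <- cryptDrift:::analyticBinnedCohort(dr, ind,
                                              cryptsPerPatient = 500L)
  fit <- fitAnalytic(binned, free = "delta", drift = dr, induction = ind,
                     patientAges = attr(binned, "patientAges"))
  expect_lt(abs(fit$estimates[["delta"]]), 0.05)
})
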