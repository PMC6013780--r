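test_that("induction rate evaluates the exponential law", {
  ind <- inductionParams()
  expect_equal(round(inductionRate(20, ind), 2), 0.14)
  expect_equal(round(inductionRate(70, ind), 1), 1.7)
  expect_equal(inductionRate(0, ind), 0.01 * 5)
  expect_error(inductionRate(-5, ind), "non-negative")
})

test_that("the clone-size master equation has the right limits", {
  # lambda = 0: point mass at n0 for all t
  frozen <- cloneSizeDistribution(driftParams(lambda = 0), t = 50, n0 = 2)
  expect_equal(unname(frozen), c(0, 0, 1, 0, 0, 0), tolerance = 1e-12)
  # t -> Inf: gambler's-ruin absorption masses 1/N and (N-1)/N
  lim <- cloneSizeDistribution(driftParams(lambda = 0.6), t = 1000)
  expect_equal(lim[["0"]], 0.8, tolerance = 1e-9)
  expect_equal(lim[["5"]], 0.2, tolerance = 1e-9)
  # normalisation and positivity at finite times
  for (t in c(0, 0.5, 5, 50)) {
    p <- cloneSizeDistribution(driftParams(lambda = 0.6, delta = 0.1), t)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
  expect_error(cloneSizeDistribution(driftParams(), t = -1), "non-negative")
  expect_error(cloneSizeDistribution(driftParams(), t = 1, n0 = 9), "0..N")
})

test_that("the spectral propagator agrees with the matrix exponential", {
  dr <- driftParams(lambda = 0.8, delta = 0.15, nSC = 6L)
  Q <- cryptDrift:::generatorMatrix(dr)
  prop <- cryptDrift:::chainPropagator(dr)
  for (t in c(0.3, 3, 30)) {
    expect_equal(prop(t), as.matrix(Matrix::expm(Q * t)), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("clone-size distribution matches a Monte-Carlo jump chain", {
  set.seed(301)
  n <- 2e4
  walkers <- simulateJumpChain(n, N = 5, lambda = 0.6, delta = 0, tEnd = 10)
  obs <- tabulate(walkers + 1L, nbins = 6L) / n
  expected <- cloneSizeDistribution(driftParams(lambda = 0.6), t = 10)
  for (s in 1:6) expect_true(within3SE(obs[s], expected[s], n))
})

test_that("fixation probability matches the ruin linear solve", {
  expect_equal(fixationProbability(driftParams(), 1), 0.2)
  expect_equal(fixationProbability(driftParams(), 5), 1)
  expect_equal(fixationProbability(driftParams(), 0), 0)
  # biased case against a brute-force linear solve of the hitting system
  for (delta in c(0.1, -0.2, 0.3)) {
    N <- 5
    up <- (1 + delta) / 2
    A <- diag(N - 1)
    b <- numeric(N - 1)
    for (n in 1:(N - 1)) {
      if (n < N - 1) A[n, n + 1] <- -up
      if (n > 1) A[n, n - 1] <- -(1 - up)
      if (n == N - 1) b[n] <- up
    }
    h <- solve(A, b)
    expect_equal(fixationProbability(driftParams(delta = delta), 1), h[1],
                 tolerance = 1e-12)
  }
  # closed form vs linear-algebra agreement at delta = 0 via limit
  expect_equal(fixationProbability(driftParams(delta = 1e-9), 2), 0.4,
               tolerance = 1e-6)
})

test_that("quasi-steady partial sizes decay linearly, independent of lambda", {
  expect_equal(unname(quasiSteadyPartialPmf(driftParams())),
               c(4, 3, 2, 1) / 10, tolerance = 1e-12)
  expect_equal(unname(quasiSteadyPartialPmf(driftParams(nSC = 2L))), 1)
  a <- quasiSteadyPartialPmf(driftParams(lambda = 0.3))
  b <- quasiSteadyPartialPmf(driftParams(lambda = 3))
  expect_equal(a, b, tolerance = 1e-12)
  # the maximum sits at one stem cell's share of the circumference
  expect_equal(names(which.max(a)), "1")
})

test_that("expected class fractions integrate the induction law", {
  dr <- driftParams()
  expect_equal(expectedClassFractions(dr, inductionParams(R0 = 0),
                                      c(20, 60))$full, c(0, 0))
  cf <- expectedClassFractions(dr, inductionParams(), seq(10, 80, 10))
  expect_true(all(diff(cf$full) > 0))      # fixation is irreversible
  expect_true(all(cf$partial >= 0 & cf$partial <= 1))
  expect_true(all(cf$full >= 0 & cf$full <= 1))
  # raw expected counts warn once clone overlap stops being negligible
  expect_warning(expectedClassFractions(dr, inductionParams(), 80,
                                        mode = "expected"),
                 "overlap")
  # in the low-rate regime the partial:full intensity ratio is roughly
  # age-stable (the observed near-constancy of the partial:full ratio)
  low <- expectedClassFractions(dr, inductionParams(R0 = 1e-4), c(40, 80),
                                mode = "expected")
  ratio <- low$partial / low$full
  expect_lt(max(ratio) / min(ratio), 2)
})

test_that("the fixed fraction responds sharply to fate bias", {
  vals <- vapply(c(0, 0.05, 0.1, 0.2), function(d)
    expectedClassFractions(driftParams(delta = d),
                           inductionParams(R0 = 1e-3), 80)$full, numeric(1))
  expect_true(all(diff(vals) > 0))
  # a small bias already moves the fixed fraction by a large factor
  expect_gt(vals[4] / vals[1], 1.5)
})

test_that("the analytic fit recovers parameters from noise-free data", {
  dr <- driftParams(lambda = 0.6)
  ind <- inductionParams()
  mids <- c(25.5, 45.5, 65.5, 75.5)
  cf <- expectedClassFractions(dr, ind, mids)
  binned <- data.frame(decade = c("21-30", "41-50", "61-70", "71-80"),
                       nPatients = c(10, 44, 21, 9),
                       nCrypts = 1000, meanAge = mids,
                       pctPartial = 100 * cf$partial,
                       pctFull = 100 * cf$full)
  fit <- fitAnalytic(binned, free = "lambda",
                     drift = driftParams(lambda = 0.2), induction = ind)
  expect_equal(fit$estimates[["lambda"]], 0.6, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-6)
  # freeing everything on too few bins is rejected as non-identifiable
  expect_error(fitAnalytic(binned[1:2, ], free = c("lambda", "R0", "eta")),
               "non-identifiable")
  expect_error(fitAnalytic(binned[1, , drop = FALSE]), "2 age groups")
})

test_that("profile grids bracket the optimum", {
  dr <- driftParams(lambda = 0.6)
  ind <- inductionParams()
  mids <- c(25.5, 45.5, 65.5)
  cf <- expectedClassFractions(dr, ind, mids)
  binned <- data.frame(decade = c("21-30", "41-50", "61-70"),
                       nPatients = c(10, 44, 21), nCrypts = 1000,
                       meanAge = mids, pctPartial = 100 * cf$partial,
                       pctFull = 100 * cf$full)
  fit <- fitAnalytic(binned, free = "lambda", drift = driftParams(lambda = 0.4),
                     induction = ind, profile = TRUE)
  prof <- fit$profile$lambda
  expect_gt(prof$rss[1], min(prof$rss))
  expect_gt(prof$rss[nrow(prof)], min(prof$rss))
})

test_that("the induction-onset MLE recovers the generating law", {
  set.seed(310)
  R0 <- 0.004; eta <- 0.05
  nCrypt <- 30000; Tend <- 80
  # direct Poisson first-event simulation as the oracle data
  u <- runif(nCrypt)
  Lam <- R0 * (exp(eta * Tend) - 1) / eta
  onset <- rep(NA_real_, nCrypt)
  hit <- u < 1 - exp(-Lam)
  E <- -log(1 - u[hit])
  onset[hit] <- log(1 + eta * E / R0) / eta
  exposure <- ifelse(is.na(onset), Tend, onset)
  fit <- fitInductionFromOnsets(onset[!is.na(onset)], exposure)
  expect_lt(abs(fit$eta - eta) / eta, 0.1)
  expect_lt(abs(fit$R0 - R0) / R0, 0.1)
})
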