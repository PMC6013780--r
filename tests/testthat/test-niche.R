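test_that("crypt initialisation and classification behave", {
  crypt <- initCrypt()
  expect_length(crypt@cells, 5L)
  expect_true(all(vapply(crypt@cells, function(c)
    c@wildType == 200L, logical(1))))
  cls <- classifyCrypt(crypt)
  expect_identical(cls$label, "normal")
  expect_identical(cls$kDeficient, 0L)
  expect_identical(classifyCrypt(2L, nSC = 5L)$label, "partial")
  expect_identical(classifyCrypt(5L, nSC = 5L)$label, "full")
  expect_error(clonalityOfDeficiency(crypt), "no OXPHOS-deficient")
})

test_that("pure asymmetry preserves the clonal configuration of the ring", {
  # five monoclonal cells with distinct lineages: under pAsym = 1 and no new
  # mutation every position keeps its lineage forever
  cells <- lapply(1:5, function(i)
    mtDnaState(wildType = 0L, mutantCounts = setNames(200L, paste0("L", i))))
  crypt <- new("CryptState", cells = cells, age = 0, cryptId = "c")
  noMut <- mutationRateSchedule(muStart = 1e-300, muEnd = 1e-299)
  set.seed(201)
  for (g in 1:30)
    crypt <- stepGeneration(crypt, fateParams(pAsym = 1), noMut)
  lin <- vapply(crypt@cells, function(c) names(c@mutantCounts), character(1))
  expect_identical(lin, paste0("L", 1:5))
  expect_equal(crypt@age, 30 * 7 / 365, tolerance = 1e-9)
})

test_that("a symmetric event copies the divider and expunges a neighbour", {
  cells <- lapply(1:5, function(i)
    mtDnaState(wildType = 0L, mutantCounts = setNames(200L, paste0("L", i))))
  crypt <- new("CryptState", cells = cells, age = 0, cryptId = "c")
  noMut <- mutationRateSchedule(muStart = 1e-300, muEnd = 1e-299)
  set.seed(202)
  nxt <- stepGeneration(crypt, fateParams(pAsym = 0), noMut)
  lin <- vapply(nxt@cells, function(c) names(c@mutantCounts), character(1))
  expect_length(lin, 5L)                      # ring size conserved
  expect_true(all(lin %in% paste0("L", 1:5)))
  expect_lt(length(unique(lin)), 5L)          # at least one replacement
})

test_that("neutral fixation probability of one labelled cell is 1/N", {
  for (N in c(3L, 5L, 7L)) {
    set.seed(210 + N)
    cfg <- nicheConfig(nSC = N, lifespanYears = 10)
    ens <- simulateEnsemble(config = cfg, fate = fateParams(pAsym = 0),
                            nRuns = 4000, recordAges = 10, mode = "labelled")
    k <- kMatrix(ens)[, 1]
    expect_true(all(k %in% c(0L, N)))   # absorbed by then
    expect_true(within3SE(mean(k == N), 1 / N, 4000))
  }
})

test_that("the labelled-cell count is a martingale under neutral drift", {
  set.seed(220)
  cfg <- nicheConfig(lifespanYears = 4)
  ens <- simulateEnsemble(config = cfg, fate = fateParams(pAsym = 0.9),
                          nRuns = 6000, recordAges = c(1, 2, 4),
                          mode = "labelled")
  k <- kMatrix(ens)
  for (j in 1:3) {
    se <- sd(k[, j]) / sqrt(nrow(k))
    expect_lt(abs(mean(k[, j]) - 1), 3 * se)
  }
})

test_that("realized replacement events match pSym x divisions per year", {
  set.seed(230)
  cfg <- nicheConfig(lifespanYears = 10)
  ens <- simulateEnsemble(config = cfg, fate = fateParams(pAsym = 0.99),
                          nRuns = 2000, recordAges = 10, mode = "labelled")
  scYears <- 2000 * 5 * 10
  rate <- sum(ens@params$replacementEvents) / scYears
  target <- replacementRate(0.01, cfg@divisionsPerYear)
  expect_lt(abs(rate - target), 3 * sqrt(target / scYears))
})

test_that("labelled clone sizes match the analytic birth-death chain", {
  # dual route: ring simulator at pSym = 0.01 vs the master-equation solve
  # with the clone step rate 2 * pSym * divisionsPerYear
  set.seed(240)
  cfg <- nicheConfig(lifespanYears = 20)
  n <- 10000
  ens <- simulateEnsemble(config = cfg, fate = fateParams(pAsym = 0.99),
                          nRuns = n, recordAges = 20, mode = "labelled")
  obs <- tabulate(kMatrix(ens)[, 1] + 1L, nbins = 6L) / n
  lam <- cloneStepRate(0.01, cfg@divisionsPerYear)
  expected <- cloneSizeDistribution(driftParams(lambda = lam), t = 20)
  for (s in 1:6)
    expect_true(within3SE(obs[s], expected[s], n))
})

test_that("ensembles are deterministic under a fixed seed and mu = 0 stays normal", {
  set.seed(250)
  a <- simulateEnsemble(nRuns = 30, recordAges = c(40, 80), muFactor = 0)
  set.seed(250)
  b <- simulateEnsemble(nRuns = 30, recordAges = c(40, 80), muFactor = 0)
  expect_identical(ensembleSummary(a), ensembleSummary(b))
  expect_true(all(kMatrix(a) == 0L))
  expect_equal(sum(ensembleSummary(a)$percent[ensembleSummary(a)$k == 0]),
               200)
})

test_that("deficiency accumulates with age and full crypts are clonal", {
  ens <- defaultEnsemble()
  pct <- 100 * colMeans(kMatrix(ens) >= 1L)
  expect_true(all(diff(pct) > 0))           # monotone accumulation by decade
  km <- kMatrix(ens)
  cm <- ens@params$clonalityMatrix
  full <- km == 5L
  expect_gt(sum(full), 100)
  expect_gte(mean(cm[full] == 1L), 0.99)    # >= 99% single-lineage
})

test_that("runCrypt records the requested ages over 4171 generations", {
  set.seed(260)
  tr <- runCrypt(recordAges = c(40, 80), fate = fateParams(pAsym = 1))
  expect_equal(tr$age, c(40, 80))
  expect_identical(attr(tr, "nDivisions"), 4171L)
  set.seed(261)
  trAsym <- runCrypt(recordAges = seq(20, 80, 20),
                     fate = fateParams(pAsym = 1))
  expect_true(all(trAsym$label != "full"))
})

test_that("rate conversions follow the weekly division arithmetic", {
  expect_equal(replacementRate(0.01, 52), 0.52)
  expect_equal(cloneStepRate(0.01, 52), 1.04)
  expect_equal(replacementRate(0, 52), 0)
  expect_error(fateParams(pAsym = 1.2), "probability")
})
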