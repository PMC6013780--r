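test_that("mutation rate schedule interpolates exponentially", {
  sch <- mutationRateSchedule()
  expect_equal(mutationRateAt(0, sch), 1e-5)
  expect_equal(mutationRateAt(80, sch), 6e-5)
  # geometric midpoint forced by the exponential form
  expect_equal(mutationRateAt(40, sch), 1e-5 * sqrt(6), tolerance = 1e-12)
  # extrapolation beyond tEnd follows the same law
  expect_equal(mutationRateAt(160, sch), 1e-5 * 36, tolerance = 1e-9)
  expect_error(mutationRateAt(-1, sch), "non-negative")
})

test_that("replication doubles the pool and mutants breed true", {
  wt <- mtDnaState()
  p <- replicatePool(wt, mu = 0)
  expect_equal(p$wildType, 400L)
  expect_length(p$mutantCounts, 0L)

  mut <- mtDnaState(mutantCounts = c(L1 = 200), copyNumber = 200L)
  p <- replicatePool(mut, mu = 0.5)   # mu irrelevant without wild-type
  expect_equal(unname(p$mutantCounts), 400L)
  expect_equal(names(p$mutantCounts), "L1")
  expect_equal(p$wildType, 0L)
})

test_that("new mutations per division match the Bernoulli mean", {
  set.seed(101)
  n <- 1e5
  wt <- mtDnaState()
  newMut <- vapply(seq_len(n), function(i)
    sum(replicatePool(wt, mu = 1e-5)$mutantCounts), numeric(1))
  expected <- 200 * 1e-5
  se <- sqrt(expected / n)   # Poisson-like variance of rare Bernoulli sums
  expect_lt(abs(mean(newMut) - expected), 3 * se)
  # each mutation event mints a distinct lineage id
  set.seed(102)
  p <- replicatePool(wt, mu = 0.05)
  expect_false(anyDuplicated(names(p$mutantCounts)) > 0)
  expect_true(all(p$mutantCounts[names(p$mutantCounts) != ""] >= 1))
})

test_that("segregation conserves molecules and follows the hypergeometric law", {
  half <- mtDnaState(mutantCounts = c(L1 = 100))
  pool <- replicatePool(half, mu = 0)
  expect_equal(pool$wildType + sum(pool$mutantCounts), 400L)

  d <- segregatePool(pool)
  expect_equal(d[[1]]@copyNumber, 200L)
  expect_equal(d[[2]]@copyNumber, 200L)
  # partition conservation: the daughters carry every pool molecule
  expect_equal(sum(d[[1]]@mutantCounts) + sum(d[[2]]@mutantCounts), 200L)
  expect_equal(d[[1]]@wildType + d[[2]]@wildType, 200L)

  pure <- segregatePool(replicatePool(mtDnaState(), mu = 0))
  expect_equal(pure[[1]]@wildType, 200L)
  expect_equal(pure[[2]]@wildType, 200L)

  expect_error(segregatePool(list(wildType = 10L,
                                  mutantCounts = integer(0),
                                  copyNumber = 200L)),
               "2 \\* copyNumber")

  # daughter mutant-count variance vs the closed-form hypergeometric value
  set.seed(103)
  n <- 4e4
  draws <- vapply(seq_len(n), function(i)
    sum(segregatePool(pool)[[1]]@mutantCounts), numeric(1))
  M <- 200
  vExp <- M * 0.5 * 0.5 * (2 * M - M) / (2 * M - 1)
  seVar <- vExp * sqrt(2 / (n - 1))
  expect_lt(abs(var(draws) - vExp), 3 * seVar)
  expect_lt(abs(mean(draws) - 100), 3 * sqrt(vExp / n))
})

test_that("heteroplasmy is a martingale under division", {
  set.seed(104)
  n <- 1e4
  parent <- mtDnaState(mutantCounts = c(L1 = 100))
  h <- vapply(seq_len(n), function(i)
    sum(divideCell(parent, mu = 0)[[1]]@mutantCounts) / 200, numeric(1))
  sdDaughter <- sqrt(0.25 * (200 / 399) / 200)
  expect_lt(abs(mean(h) - 0.5), 3 * sdDaughter / sqrt(n))
})

test_that("division matches the exhaustive enumeration oracle at M = 4", {
  # two divisions, mu = 0, start at 50% heteroplasmy: compare simulated
  # daughter-count distribution against the replicate-then-hypergeometric
  # transition matrix powered twice (chi-square GOF at alpha = 0.01)
  pExact <- enumerateDivisionPmf(M = 4, m0 = 2, steps = 2)
  runPath <- function(divide) {
    s <- mtDnaState(mutantCounts = c(L1 = 2), copyNumber = 4L)
    for (i in 1:2) s <- divide(s)
    sum(s@mutantCounts)
  }
  set.seed(105)
  n <- 2e4
  simR <- vapply(seq_len(n), function(i) runPath(function(s)
    divideCell(s, mu = 0)[[sample.int(2, 1)]]), numeric(1))
  obs <- tabulate(simR + 1L, nbins = 5L)
  chi <- suppressWarnings(chisq.test(obs, p = pExact))
  expect_gt(chi$p.value, 0.01)

  # the compiled single-cell path used by the ensemble driver agrees too
  set.seed(106)
  cppPath <- function() {
    wt <- 2L; ids <- 1; cnt <- 2L
    for (step in 1:2) {
      r <- cryptDrift:::cpp_divide_cell(wt, list(ids), list(cnt),
                                        4L, 0, 0L, 100)
      d <- r$daughters
      i <- sample.int(2, 1)
      wt <- d$wildType[i]
      ids <- d$lineageIds[[i]]
      cnt <- d$lineageCounts[[i]]
    }
    4L - wt
  }
  simC <- vapply(seq_len(n), function(i) cppPath(), numeric(1))
  chiC <- suppressWarnings(chisq.test(tabulate(simC + 1L, nbins = 5L),
                                      p = pExact))
  expect_gt(chiC$p.value, 0.01)
})

test_that("absorption is monotone and lineages never back-mutate", {
  set.seed(107)
  nLin <- 400
  states <- replicate(nLin, mtDnaState(mutantCounts = c(L1 = 100)),
                      simplify = FALSE)
  absorbed <- numeric(0)
  for (k in 1:25) {
    states <- lapply(states, function(s) divideCell(s, mu = 0)[[1]])
    h <- vapply(states, function(s) sum(s@mutantCounts), numeric(1))
    absorbed <- c(absorbed, mean(h == 0 | h == 200))
    # no back-mutation: a pure-mutant cell can never regain wild type
    expect_true(all(vapply(states, function(s)
      s@wildType + sum(s@mutantCounts) == 200L, logical(1))))
  }
  expect_true(all(diff(absorbed) >= 0))
})

test_that("the deficiency threshold is boundary-inclusive", {
  expect_true(isOxphosDeficient(mtDnaState(mutantCounts = c(L1 = 150))))
  expect_false(isOxphosDeficient(mtDnaState(mutantCounts = c(L1 = 149))))
  expect_false(isOxphosDeficient(mtDnaState()))
  expect_true(isOxphosDeficient(mtDnaState(mutantCounts = c(L1 = 100)),
                                theta = 0.5))
})

test_that("mtDNA state validity is enforced", {
  expect_error(mtDnaState(wildType = 100, mutantCounts = c(L1 = 50)),
               "copyNumber")
  expect_error(mtDnaState(wildType = -1, copyNumber = -1))
  expect_error(mtDnaState(mutantCounts = c(L1 = 2.5)), "whole numbers")
})
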