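# Shared fixtures for the test suite. Everything is generated in code under
# fixed seeds; the larger ensembles are memoised so several test files can
# share one simulation.

.fixtures <- new.env(parent = emptyenv())

# default-parameter mtDNA ensemble shared across test files
defaultEnsemble <- function() {
  if (is.null(.fixtures$ens)) {
    set.seed(20180425)
    .fixtures$ens <- simulateEnsemble(nRuns = 8000,
                                      recordAges = seq(20, 80, by = 10))
  }
  .fixtures$ens
}

# a small cohort from the analytic engine (fast)
smallAnalyticCohort <- function() {
  if (is.null(.fixtures$cohort)) {
    set.seed(11)
    d <- cohortDesign(decadeCounts = c("31-40" = 4L, "51-60" = 4L,
                                       "71-80" = 4L),
                      cryptsPerPatient = 400L, patientDispersion = Inf)
    .fixtures$cohort <- generateCohort(d, engine = "analytic",
                                       drift = driftParams(lambda = 0.6),
                                       induction = inductionParams(R0 = 0.02))
  }
  .fixtures$cohort
}

# exact pmf of the mutant-molecule count after `steps` divisions, starting
# from m0 mutants of M molecules, no new mutation: replicate-then-
# hypergeometric transition matrix, powered. Independent enumeration oracle
# for the division machinery.
enumerateDivisionPmf <- function(M, m0, steps) {
  Tm <- outer(0:M, 0:M, function(m, mp)
    dhyper(mp, 2 * m, 2 * M - 2 * m, M))
  p <- as.numeric(0:M == m0)
  for (i in seq_len(steps)) p <- p %*% Tm
  as.numeric(p)
}

# Monte-Carlo jump-chain oracle for the clone-size birth-death chain
simulateJumpChain <- function(n, N, lambda, delta, tEnd, n0 = 1L) {
  up <- lambda * (1 + delta) / 2
  dn <- lambda * (1 - delta) / 2
  vapply(seq_len(n), function(i) {
    s <- n0
    t <- 0
    repeat {
      if (s == 0L || s == N) return(s)
      t <- t + rexp(1, up + dn)
      if (t > tEnd) return(s)
      s <- s + (if (runif(1) < up / (up + dn)) 1L else -1L)
    }
  }, integer(1))
}

# binomial 3-standard-error helper
within3SE <- function(observed, expected, n) {
  se <- sqrt(pmax(expected * (1 - expected), 1e-12) / n)
  abs(observed - expected) <= 3 * se + 1e-12
}
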