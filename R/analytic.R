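#' Clone induction rate at a given age
#'
#' Evaluates the empirical time-increasing induction rate of OXPHOS-deficient
#' stem-cell clones, `R(t) = R0 * exp(eta * t)` events per crypt per year.
#' At the default parameters (eta = 0.05/yr, R0/N = 0.01/crypt/yr, N = 5)
#' this gives 0.14 per crypt per year at age 20 and about 1.7 at age 70.
#'
#' @param t age in years (vectorised, non-negative).
#' @param params an [InductionParams-class].
#' @return Induction events per crypt per year.
#' @examples
#' round(inductionRate(c(20, 70), inductionParams()), 2)
#' @export
inductionRate <- function(t, params = inductionParams()) {
  stopifnot(is(params, "InductionParams"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be non-negative")
  params@R0 * exp(params@eta * t)
}

# Generator of the clone-size birth-death chain on states 0..N with absorbing
# boundaries; up rate lambda*(1+delta)/2, down rate lambda*(1-delta)/2.
generatorMatrix <- function(params) {
  N <- params@nSC
  Q <- matrix(0, N + 1L, N + 1L)
  up <- params@lambda * (1 + params@delta) / 2
  dn <- params@lambda * (1 - params@delta) / 2
  for (n in seq_len(N - 1L)) {       # transient states 1..N-1 (row n+1)
    Q[n + 1L, n + 2L] <- up
    Q[n + 1L, n] <- dn
    Q[n + 1L, n + 1L] <- -(up + dn)
  }
  Q
}

# Spectral propagator: returns function(t) -> row-stochastic P(t) = expm(Q t).
# Falls back to Matrix::expm when the eigensystem is ill-conditioned.
chainPropagator <- function(params) {
  Q <- generatorMatrix(params)
  eg <- eigen(Q)
  ok <- all(abs(Im(eg$values)) < 1e-9) &&
    rcond(Re(eg$vectors)) > 1e-10
  if (ok) {
    V <- Re(eg$vectors)
    lam <- Re(eg$values)
    Vi <- solve(V)
    function(t) {
      P <- V %*% (exp(lam * t) * Vi)
      P[P < 0] <- 0
      P / rowSums(P)
    }
  } else {
    function(t) as.matrix(Matrix::expm(Q * t))
  }
}

#' Clone-size distribution of the neutral-drift chain
#'
#' Solves the continuous-time master equation of the clone-size birth--death
#' chain (absorbing at 0 and N) and returns the distribution over clone sizes
#' `0..N` at time `t` for a clone started at size `n0`.
#'
#' @param params a [DriftParams-class].
#' @param t time in years since induction (non-negative).
#' @param n0 initial clone size (0..N; 1 for a newly induced clone).
#' @return Named probability vector over sizes `0..N` (sums to 1 within 1e-9).
#' @examples
#' cloneSizeDistribution(driftParams(lambda = 0.6), t = 10)
#' @export
cloneSizeDistribution <- function(params, t, n0 = 1L) {
  stopifnot(is(params, "DriftParams"))
  N <- params@nSC
  n0 <- as.integer(n0)
  if (n0 < 0L || n0 > N) stop("n0 must lie in 0..N")
  if (!is.finite(t) || t < 0) stop("t must be non-negative")
  P <- chainPropagator(params)(t)
  p <- P[n0 + 1L, ]
  p[p < 0] <- 0
  p <- p / sum(p)
  stats::setNames(p, 0:N)
}

#' Fixation probability of a clone
#'
#' Probability that a clone of initial size `n0` eventually takes over the
#' whole niche (absorbs at N). Closed form for the biased ruin problem; for
#' strictly neutral dynamics (`delta = 0`) this is exactly `n0/N`.
#'
#' @inheritParams cloneSizeDistribution
#' @return Fixation probability.
#' @export
fixationProbability <- function(params, n0 = 1L) {
  stopifnot(is(params, "DriftParams"))
  N <- params@nSC
  n0 <- as.integer(n0)
  if (n0 < 0L || n0 > N) stop("n0 must lie in 0..N")
  if (params@delta == 0) return(n0 / N)
  r <- (1 - params@delta) / (1 + params@delta)   # down/up ratio
  (1 - r^n0) / (1 - r^N)
}

#' Quasi-steady distribution of partial clone sizes
#'
#' Steady-state relative occupancy of the transient clone sizes `1..N-1`
#' under constant unit injection of new clones at size 1. For strictly
#' neutral dynamics the distribution is proportional to `N - n`: it decays
#' linearly with clone size, peaks at a fraction `1/N` of the circumference,
#' is minimal at `1 - 1/N`, and its shape is independent of the
#' loss/replacement rate. Non-neutral dynamics (`delta != 0`) are handled by
#' the numerical steady-flux solve.
#'
#' @param params a [DriftParams-class].
#' @return Named probability vector over clone sizes `1..N-1`.
#' @examples
#' quasiSteadyPartialPmf(driftParams())    # (4, 3, 2, 1) / 10
#' @export
quasiSteadyPartialPmf <- function(params) {
  stopifnot(is(params, "DriftParams"))
  N <- params@nSC
  if (N == 2L) return(stats::setNames(1, "1"))
  if (params@lambda <= 0) stop("lambda must be positive for a steady flux")
  Q <- generatorMatrix(params)
  QT <- Q[2:N, 2:N]                 # transient block
  inj <- c(1, rep(0, N - 2L))       # unit injection at size 1
  x <- solve(t(QT), -inj)           # 0 = QT' x + inj
  x <- x / sum(x)
  stats::setNames(x, 1:(N - 1L))
}

#' Expected partial and full crypt fractions at a given age
#'
#' Integrates the induction rate against the clone-size distribution: a clone
#' induced at time `s` with size 1 contributes to the partial (sizes 1..N-1)
#' or full (size N, irreversible) compartment at `age` according to the drift
#' chain propagated over `age - s`. Clone induction is treated as a Poisson
#' process and clones as independent; `mode = "probability"` (default)
#' converts the accumulated intensities into per-crypt class probabilities
#' (`P(full) = 1 - exp(-Lfix)`, `P(partial) = exp(-Lfix) * (1 - exp(-Lpart))`),
#' while `mode = "expected"` returns the raw intensities (expected clone
#' counts), with a validity warning when cumulative induction exceeds one
#' event per crypt and clone overlap is no longer negligible.
#'
#' @param drift a [DriftParams-class].
#' @param induction an [InductionParams-class].
#' @param age age(s) in years (vectorised).
#' @param mode `"probability"` or `"expected"`.
#' @param nStep quadrature resolution (Simpson panels per age evaluation).
#' @return data.frame with columns `age`, `partial`, `full` (fractions in
#'   \[0, 1\]).
#' @export
expectedClassFractions <- function(drift, induction, age,
                                   mode = c("probability", "expected"),
                                   nStep = 160L) {
  stopifnot(is(drift, "DriftParams"), is(induction, "InductionParams"))
  mode <- match.arg(mode)
  if (any(age < 0)) stop("age must be non-negative")
  prop <- chainPropagator(drift)
  N <- drift@nSC
  out <- lapply(age, function(a) {
    if (a == 0 || induction@R0 == 0)
      return(data.frame(age = a, partial = 0, full = 0))
    L <- classIntensities(prop, induction, a, N, nStep)
    if (mode == "expected") {
      tot <- induction@R0 * (exp(induction@eta * a) - 1) /
        max(induction@eta, 1e-12)
      if (induction@eta == 0) tot <- induction@R0 * a
      if (tot > 1)
        warning(sprintf(paste0(
          "cumulative induction %.2f per crypt by age %g: clone overlap ",
          "is not negligible; expected counts exceed class probabilities"),
          tot, a), call. = FALSE)
      data.frame(age = a, partial = L["partial"], full = L["full"])
    } else {
      pFull <- 1 - exp(-L[["full"]])
      data.frame(age = a, partial = exp(-L[["full"]]) *
                   (1 - exp(-L[["partial"]])), full = pFull)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Simpson-rule intensities: Lpart = int_0^a R(s) Ppart(a - s) ds, same for
# absorption at N. Returns c(partial =, full =, byK = vector over 1..N-1).
classIntensities <- function(prop, induction, a, N, nStep = 160L) {
  m <- 2L * ceiling(nStep / 2)
  s <- seq(0, a, length.out = m + 1L)
  w <- c(1, rep(c(4, 2), length.out = m - 1L), 1) * (a / m) / 3
  R <- induction@R0 * exp(induction@eta * s)
  pPart <- numeric(m + 1L)
  pFull <- numeric(m + 1L)
  byK <- matrix(0, m + 1L, N - 1L)
  for (i in seq_along(s)) {
    p <- prop(a - s[i])[2L, ]      # from n0 = 1
    pPart[i] <- sum(p[2:N])
    pFull[i] <- p[N + 1L]
    byK[i, ] <- p[2:N]
  }
  c(partial = sum(w * R * pPart), full = sum(w * R * pFull),
    byK = as.numeric(colSums(w * R * byK)))
}

#' Fit the analytic model to decade-binned crypt frequencies
#'
#' Weighted least squares of the analytic model's expected partial and full
#' crypt percentages against a decade-binned summary (weights = patients per
#' decade, mirroring the pooling of patients into age brackets). Any subset
#' of `lambda`, `delta`, `R0`, `eta` may be freed; the rest are held at the
#' supplied values.
#'
#' @param binned data.frame with columns `decade`, `nPatients`, `pctPartial`,
#'   `pctFull` (as from [decadeSummary()]); prediction ages are the per-decade
#'   mean patient ages when a `meanAge` column (or `patientAges`) is present,
#'   otherwise the decade midpoints.
#' @param free character vector naming the free parameters (subset of
#'   `c("lambda", "delta", "R0", "eta")`).
#' @param drift,induction starting/fixed parameter objects.
#' @param nSC effective stem-cell number (fixed).
#' @param use which observed columns enter the objective: `"partial"`,
#'   `"full"` or both (default).
#' @param patientAges optional data.frame with columns `decade`, `age`: when
#'   given, per-decade predictions average over these patient ages exactly.
#' @param profile logical: also return a one-dimensional profile grid of the
#'   objective around the optimum for each free parameter.
#' @return list with `estimates` (named vector), `rss`, `fitted` (data.frame),
#'   `profile` (list of data.frames or NULL), and `convergence`.
#' @export
fitAnalytic <- function(binned, free = "lambda",
                        drift = driftParams(), induction = inductionParams(),
                        nSC = drift@nSC, use = c("partial", "full"),
                        patientAges = NULL, profile = FALSE) {
  stopifnot(all(free %in% c("lambda", "delta", "R0", "eta")))
  use <- match.arg(use, several.ok = TRUE)
  if (nrow(binned) < 2L) stop("need at least 2 age groups")
  if (length(free) >= 3L && nrow(binned) < 3L)
    stop("non-identifiable: freeing ", length(free),
         " parameters needs at least 3 age bins")
  ages <- predictionAges(binned, patientAges)
  w <- binned$nPatients
  start <- c(lambda = drift@lambda, delta = drift@delta,
             R0 = induction@R0, eta = induction@eta)
  lower <- c(lambda = 1e-4, delta = -0.95, R0 = 1e-8, eta = 0)
  upper <- c(lambda = 50, delta = 0.95, R0 = 50, eta = 1)
  obj <- function(th) {
    par <- start
    par[free] <- th
    pred <- predictDecades(par, nSC, ages)
    rss <- 0
    if ("partial" %in% use)
      rss <- rss + sum(w * (binned$pctPartial - pred$partial)^2)
    if ("full" %in% use)
      rss <- rss + sum(w * (binned$pctFull - pred$full)^2)
    rss
  }
  fit <- stats::optim(start[free], obj, method = "L-BFGS-B",
                      lower = lower[free], upper = upper[free],
                      control = list(factr = 1e7))
  est <- start
  est[free] <- fit$par
  pred <- predictDecades(est, nSC, ages)
  fitted <- data.frame(decade = binned$decade, age = vapply(ages, mean,
                                                            numeric(1)),
                       pctPartial = pred$partial, pctFull = pred$full)
  prof <- NULL
  if (profile) {
    prof <- lapply(stats::setNames(free, free), function(pname) {
      v <- est[pname]
      grid <- v * seq(0.5, 1.5, length.out = 21)
      if (pname == "delta") grid <- seq(-0.3, 0.3, length.out = 21)
      rss <- vapply(grid, function(g) {
        th <- est[free]
        th[pname] <- g
        obj(th)
      }, numeric(1))
      data.frame(value = grid, rss = rss)
    })
  }
  list(estimates = est, rss = fit$value, fitted = fitted, profile = prof,
       convergence = fit$convergence)
}

# per-decade prediction ages: list of patient-age vectors
predictionAges <- function(binned, patientAges) {
  if (!is.null(patientAges)) {
    lapply(binned$decade, function(d)
      patientAges$age[patientAges$decade == d])
  } else if ("meanAge" %in% names(binned)) {
    as.list(binned$meanAge)
  } else {
    lapply(strsplit(as.character(binned$decade), "-"), function(p)
      mean(as.numeric(p)))
  }
}

predictDecades <- function(par, nSC, ages) {
  dr <- driftParams(nSC = nSC, lambda = par[["lambda"]],
                    delta = par[["delta"]])
  ind <- inductionParams(R0 = par[["R0"]], eta = par[["eta"]])
  allAges <- sort(unique(unlist(ages)))
  cf <- expectedClassFractions(dr, ind, allAges)
  look <- function(a, col) cf[[col]][match(a, cf$age)]
  list(partial = 100 * vapply(ages, function(a)
         mean(look(a, "partial")), numeric(1)),
       full = 100 * vapply(ages, function(a)
         mean(look(a, "full")), numeric(1)))
}

#' Fit the induction law to deficiency-onset times
#'
#' Maximum-likelihood fit of the exponentially increasing induction rate
#' `R0 * exp(eta * t)` to right-censored first-onset times (the age at which
#' a crypt first contains a deficient stem cell), as produced by the mtDNA
#' ensemble. For a Poisson first-event process the log-likelihood is
#' `sum log R(t_i) - sum_j int_0^{T_j} R`, with the integral over each
#' crypt's observation window; `R0` profiles out in closed form.
#'
#' @param onsetAges ages (years) of observed first onsets.
#' @param exposureAges censoring age for every crypt (length = number of
#'   crypts, onset crypts included at their onset age).
#' @return list with `R0`, `eta` and the maximised log-likelihood.
#' @export
fitInductionFromOnsets <- function(onsetAges, exposureAges) {
  if (length(onsetAges) == 0L) stop("no onsets observed")
  D <- length(onsetAges)
  cumInt <- function(eta, t) if (eta == 0) t else (exp(eta * t) - 1) / eta
  prof <- function(eta) {
    Texp <- sum(cumInt(eta, exposureAges))
    R0 <- D / Texp
    D * log(R0) + eta * sum(onsetAges) - R0 * Texp
  }
  opt <- stats::optimize(prof, c(0, 0.5), maximum = TRUE)
  eta <- opt$maximum
  list(R0 = D / sum(cumInt(eta, exposureAges)), eta = eta,
       logLik = opt$objective)
}
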