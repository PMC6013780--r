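#' Classify an observed crypt by its deficiency fraction
#'
#' `full` requires the observed fraction to reach `fullThreshold` (default 1:
#' fixed crypts emit exactly 1 under the observation model; lower the
#' threshold, e.g. to 0.99, for real-data tolerance); `normal` means at or
#' below the detection floor; anything between is `partial`.
#'
#' @param fraction observed fraction(s) in \[0, 1\].
#' @param detectionFloor minimum detectable fraction (default 0.05).
#' @param fullThreshold fraction at which a crypt counts as fully deficient.
#' @return factor with levels `normal`, `partial`, `full`.
#' @export
classifyObservedCrypt <- function(fraction, detectionFloor = 0.05,
                                  fullThreshold = 1) {
  if (any(fraction < 0) || any(fraction > 1))
    stop("fraction must lie in [0, 1]")
  out <- ifelse(fraction >= fullThreshold, "full",
                ifelse(fraction <= detectionFloor, "normal", "partial"))
  factor(out, levels = c("normal", "partial", "full"))
}

decadeBreaks <- c(16, 20, 30, 40, 50, 60, 70, 80)
decadeLabels <- c("17-20", "21-30", "31-40", "41-50", "51-60", "61-70",
                  "71-80")

assignDecade <- function(age) {
  cut(age, breaks = decadeBreaks, labels = decadeLabels, right = TRUE)
}

decadeMidpoint <- function(decade) {
  vapply(strsplit(as.character(decade), "-"), function(p)
    mean(as.numeric(p)), numeric(1))
}

#' Decade-binned cohort summary
#'
#' Groups a cohort by age decade and tabulates, per decade, the number of
#' patients and crypts, the percentage of partially and fully deficient
#' crypts, the mean patient age, and the percentage of crypts with
#' k = 1..N deficient stem cells (observed fractions binned into increments
#' of `1/N` and converted to stem-cell counts). Decades with no crypts are
#' reported as missing (absent rows), not as zeros.
#'
#' @param cohort a cohort data.frame (see [generateCohort()]).
#' @param detectionFloor,fullThreshold see [classifyObservedCrypt()].
#' @param N effective stem cells per crypt (default 5).
#' @return data.frame with columns `decade`, `nPatients`, `nCrypts`,
#'   `meanAge`, `pctNormal`, `pctPartial`, `pctFull` and `pctK1`..`pctKN`.
#' @export
decadeSummary <- function(cohort, detectionFloor = 0.05, fullThreshold = 1,
                          N = 5L) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  dec <- assignDecade(cohort$ageYears)
  if (any(is.na(dec)))
    stop("ages outside the 17-80 decade range")
  cls <- classifyObservedCrypt(cohort$oxphosFraction, detectionFloor,
                               fullThreshold)
  k <- binFractionToScCount(cohort$oxphosFraction, N)
  k[cls == "normal"] <- 0L
  k[cls == "full"] <- as.integer(N)
  rows <- lapply(levels(dec)[table(dec) > 0L], function(d) {
    sel <- dec == d
    n <- sum(sel)
    kc <- tabulate(k[sel], nbins = N)
    data.frame(decade = d,
               nPatients = length(unique(cohort$patientId[sel])),
               nCrypts = n,
               meanAge = mean(cohort$ageYears[sel]),
               pctNormal = 100 * sum(cls[sel] == "normal") / n,
               pctPartial = 100 * sum(cls[sel] == "partial") / n,
               pctFull = 100 * sum(cls[sel] == "full") / n,
               t(stats::setNames(100 * kc / n, paste0("pctK", seq_len(N)))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit an exponential growth curve
#'
#' Nonlinear least squares of `y = a * exp(b * t)` (handles zero-valued early
#' decades, unlike a log-linear fit), with the coefficient of determination
#' `R^2 = 1 - SSres/SStot`.
#'
#' @param ages time points (years).
#' @param percentages observed values.
#' @return list with `a`, `b`, `r2` and the fitted values.
#' @examples
#' f <- fitExponentialGrowth(seq(20, 80, 10), 2 * exp(0.05 * seq(20, 80, 10)))
#' c(f$a, f$b, f$r2)
#' @export
fitExponentialGrowth <- function(ages, percentages) {
  if (length(ages) < 3L) stop("need at least 3 points")
  if (all(percentages == 0)) stop("degenerate input: all values are zero")
  pos <- percentages > 0
  b0 <- if (sum(pos) >= 2L)
    stats::coef(stats::lm(log(percentages[pos]) ~ ages[pos]))[[2L]] else 0.05
  a0 <- max(mean(percentages[pos]) / mean(exp(b0 * ages[pos])), 1e-8)
  fit <- minpack.lm::nlsLM(y ~ a * exp(b * t),
                           data = data.frame(t = ages, y = percentages),
                           start = list(a = a0, b = b0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  pred <- stats::predict(fit)
  ssRes <- sum((percentages - pred)^2)
  ssTot <- sum((percentages - mean(percentages))^2)
  list(a = stats::coef(fit)[["a"]], b = stats::coef(fit)[["b"]],
       r2 = 1 - ssRes / ssTot, fitted = pred)
}

#' Trend of the partial:full crypt ratio with age
#'
#' Ordinary least-squares regression of the per-decade ratio of partially to
#' fully deficient crypt percentages against the decade midpoint age.
#' Decades with zero full crypts are excluded with a warning (the ratio is
#' undefined there). Under neutral drift with a time-increasing induction
#' rate the ratio is approximately constant, so the slope should not differ
#' significantly from zero.
#'
#' @param binned a decade summary (see [decadeSummary()]).
#' @return list with `slope`, `intercept`, `pValue`, `ratios` (data.frame).
#' @export
partialFullRatioTrend <- function(binned) {
  ok <- binned$pctFull > 0
  if (any(!ok))
    warning(sum(!ok), " decade(s) with zero full crypts excluded")
  use <- binned[ok, ]
  if (nrow(use) < 3L) stop("need >= 3 decades with nonzero full counts")
  df <- data.frame(age = decadeMidpoint(use$decade),
                   ratio = use$pctPartial / use$pctFull)
  fit <- stats::lm(ratio ~ age, data = df)
  cf <- summary(fit)$coefficients
  list(slope = cf["age", "Estimate"],
       intercept = cf["(Intercept)", "Estimate"],
       pValue = cf["age", "Pr(>|t|)"], ratios = df)
}

#' Histogram of partial-crypt deficiency fractions
#'
#' Normalised frequency distribution of the observed OXPHOS-deficiency
#' fraction across all partial crypts (fractions strictly between the
#' detection floor and 1), optionally per decade. Under neutral drift with
#' N = 5 the modal bin sits at a fraction of ~0.15-0.2 (one stem cell's
#' clonal output) and the shape is independent of age.
#'
#' @param cohort a cohort data.frame.
#' @param binWidth histogram bin width (default 0.05).
#' @param byDecade logical: add a per-decade breakdown.
#' @param detectionFloor minimum detectable fraction.
#' @return data.frame with `binLeft`, `binRight`, `count`, `frequency`
#'   (plus `decade` when `byDecade`).
#' @export
partialFractionHistogram <- function(cohort, binWidth = 0.05,
                                     byDecade = FALSE,
                                     detectionFloor = 0.05) {
  f <- cohort$oxphosFraction
  part <- f > detectionFloor & f < 1
  if (sum(part) == 0L) stop("no partial crypts in cohort")
  breaks <- seq(0, 1, by = binWidth)
  histOne <- function(x) {
    ct <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
    data.frame(binLeft = breaks[-length(breaks)], binRight = breaks[-1L],
               count = ct, frequency = ct / sum(ct))
  }
  if (!byDecade) return(histOne(f[part]))
  dec <- assignDecade(cohort$ageYears)
  out <- lapply(levels(dec)[tapply(part, dec, sum, default = 0) > 0],
                function(d) {
    h <- histOne(f[part & dec == d])
    h$decade <- d
    h
  })
  do.call(rbind, out)
}

#' Fit the asymmetric fate-outcome probability by simulation
#'
#' Grid fit of the multi-scale simulator to a cohort: for each candidate
#' asymmetric-fate probability an ensemble is simulated, summarised as a
#' decade-by-deficient-stem-cell-count percentage table through the same
#' observation model as the cohort, and scored by the patient-count-weighted
#' sum of squared percentage differences. The best-fitting probability is
#' the grid argmin; exact ties are reported.
#'
#' @param cohort a cohort data.frame.
#' @param pAsymGrid candidate asymmetric fate-outcome probabilities.
#' @param config,schedule,theta simulator parameters, see
#'   [simulateEnsemble()].
#' @param disp a [DispersionParams-class].
#' @param nRunsPerPoint crypts per grid point (an ensemble below ~500 crypts
#'   triggers a warning with the implied percentage standard errors).
#' @param copyNumber mtDNA molecules per cell.
#' @return list with `bestPAsym` (NA when tied), `surface` (data.frame
#'   `pAsym`, `score`), `ties`, `targetTable` and `modelTables`.
#' @export
fitSimulationToCohort <- function(cohort, pAsymGrid = c(0.95, 0.97, 0.99, 1),
                                  config = nicheConfig(),
                                  schedule = mutationRateSchedule(),
                                  theta = 0.75, disp = dispersionParams(),
                                  nRunsPerPoint = 2000L, copyNumber = 200L) {
  if (length(pAsymGrid) == 0L) stop("empty parameter grid")
  N <- config@nSC
  target <- decadeSummary(cohort, disp@detectionFloor, N = N)
  kCols <- paste0("pctK", seq_len(N))
  w <- target$nPatients
  recordAges <- target$meanAge
  modelTables <- list()
  scores <- vapply(pAsymGrid, function(pa) {
    ens <- simulateEnsemble(config, fateParams(pAsym = pa), schedule, theta,
                            nRuns = nRunsPerPoint, recordAges = recordAges,
                            copyNumber = copyNumber)
    tabs <- vapply(seq_along(recordAges), function(j) {
      k <- kMatrix(ens)[, j]
      f <- observeSectionFraction(k, N, disp)
      f[f <= disp@detectionFloor & f < 1] <- 0
      kHat <- binFractionToScCount(f, N)
      100 * tabulate(kHat, nbins = N) / nRunsPerPoint
    }, numeric(N))
    modelTables[[as.character(pa)]] <<- t(tabs)
    sum(w * rowSums((as.matrix(target[, kCols]) - t(tabs))^2))
  }, numeric(1))
  if (nRunsPerPoint < 500L)
    warning(sprintf(paste0(
      "ensemble of %d crypts per grid point: percentage standard errors up ",
      "to ~%.1f points may blur the fit"), nRunsPerPoint,
      100 * sqrt(0.25 / nRunsPerPoint)))
  best <- which(scores <= min(scores) + 1e-12)
  list(bestPAsym = if (length(best) == 1L) pAsymGrid[best] else NA_real_,
       surface = data.frame(pAsym = pAsymGrid, score = scores),
       ties = pAsymGrid[best], targetTable = target,
       modelTables = modelTables)
}
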