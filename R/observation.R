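#' Observed section fraction for k deficient stem cells
#'
#' Maps the stem-cell-level state of a crypt to the OXPHOS-deficient fraction
#' of the circumference seen in a transverse section. The deficient progeny
#' form a contiguous patch of base fraction `k/N`, perturbed by zero-mean
#' Gaussian jitter of scale `sigma` (lateral dispersion of the progeny as
#' they migrate up the crypt) and clamped to \[0, 1\]. Normal crypts
#' (`k = 0`) read exactly 0 and fixed crypts (`k = N`) exactly 1.
#'
#' @param k number of deficient stem cells (vectorised, 0..N).
#' @param N effective stem cells per crypt.
#' @param disp a [DispersionParams-class].
#' @return Observed fraction(s) in \[0, 1\].
#' @export
observeSectionFraction <- function(k, N, disp = dispersionParams()) {
  stopifnot(is(disp, "DispersionParams"))
  k <- as.integer(k)
  if (any(is.na(k)) || any(k < 0L) || any(k > N))
    stop("k must lie in 0..N")
  f <- k / N
  mid <- k > 0L & k < N
  f[mid] <- pmin(pmax(f[mid] + stats::rnorm(sum(mid), 0, disp@sigma), 0), 1)
  f
}

#' Convert an observed fraction to a stem-cell count
#'
#' Bins the observed deficiency fraction into increments of `1/N` (0.2 for
#' N = 5) and converts to the number of deficient stem cells: `k` is the
#' smallest integer with `fraction <= k/N` (half-open bins with inclusive
#' upper edges: (0, 0.2] -> 1, (0.2, 0.4] -> 2, ...); a fraction of exactly
#' 0 maps to 0 and exactly 1 always maps to N.
#'
#' @param fraction observed fraction(s) in \[0, 1\].
#' @param N effective stem cells per crypt.
#' @return Integer stem-cell count(s) 0..N.
#' @examples
#' binFractionToScCount(c(0, 0.15, 0.2, 0.21, 1), N = 5)
#' @export
binFractionToScCount <- function(fraction, N) {
  if (any(fraction < 0) || any(fraction > 1))
    stop("fraction must lie in [0, 1]")
  k <- as.integer(ceiling(fraction * N - 1e-9))
  k[fraction == 0] <- 0L
  pmin(k, as.integer(N))
}

#' Predicted partial-fraction histogram for a candidate stem-cell number
#'
#' Pushes the quasi-steady partial clone-size distribution (proportional to
#' `N - k` under neutrality) through the section-observation model: each
#' size-k clone reads as a Gaussian of mean `k/N` and scale `sigma`, clamped
#' to the interval, with fractions at or below the detection floor scored as
#' normal and hence excluded. Bin masses are conditioned on the observable
#' partial range.
#'
#' @param N candidate stem-cell number.
#' @param disp a [DispersionParams-class].
#' @param breaks histogram break points over (0, 1).
#' @param drift optional [DriftParams-class] for a non-neutral size
#'   distribution (defaults to neutral with the given `N`).
#' @return data.frame with `binLeft`, `binRight`, `frequency` (sums to 1).
#' @export
predictedPartialHistogram <- function(N, disp = dispersionParams(),
                                      breaks = seq(0, 1, by = 0.05),
                                      drift = NULL) {
  if (is.null(drift)) drift <- driftParams(nSC = as.integer(N), lambda = 1)
  w <- quasiSteadyPartialPmf(drift)
  ks <- as.integer(names(w))
  lo <- pmax(breaks[-length(breaks)], disp@detectionFloor)
  hi <- pmin(breaks[-1L], 1)
  mass <- numeric(length(lo))
  for (i in seq_along(ks)) {
    m <- ks[i] / N
    if (disp@sigma == 0) {
      inBin <- m > lo & m <= hi
      mass[inBin] <- mass[inBin] + w[i]
    } else {
      p <- stats::pnorm(hi, m, disp@sigma) - stats::pnorm(lo, m, disp@sigma)
      p[hi <= lo] <- 0
      mass <- mass + w[i] * p
    }
  }
  tot <- sum(mass)
  if (tot <= 0) stop("no observable mass in (detectionFloor, 1)")
  data.frame(binLeft = breaks[-length(breaks)], binRight = breaks[-1L],
             frequency = mass / tot)
}

#' Scan candidate stem-cell numbers against a partial-fraction histogram
#'
#' For each candidate N, predicts the partial-crypt deficiency-fraction
#' histogram ([predictedPartialHistogram()]) on the observed bins and scores
#' it by the sum of squared frequency differences; the best-fitting N is the
#' argmin. Exact ties are reported explicitly rather than silently resolved.
#'
#' @param observedHist data.frame with columns `binLeft`, `binRight` and
#'   either `frequency` or `count` (as from [partialFractionHistogram()]).
#' @param candidateNs integer candidates (default 3:8).
#' @param disp a [DispersionParams-class].
#' @return list with `bestN` (NA when tied), `scores` (data.frame `N`,
#'   `score`) and `ties` (integer vector of tied candidates).
#' @examples
#' set.seed(1)
#' h <- partialFractionHistogram(data.frame(
#'   patientId = "p", ageYears = 60, cryptId = seq_len(500),
#'   oxphosFraction = observeSectionFraction(
#'     sample(1:4, 500, TRUE, prob = 4:1), N = 5)))
#' scanScNumber(h)$bestN
#' @export
scanScNumber <- function(observedHist, candidateNs = 3:8,
                         disp = dispersionParams()) {
  if (nrow(observedHist) == 0L) stop("empty histogram")
  f <- observedHist$frequency
  if (is.null(f)) {
    if (is.null(observedHist$count)) stop("need a frequency or count column")
    f <- observedHist$count / sum(observedHist$count)
  } else {
    f <- f / sum(f)
  }
  breaks <- c(observedHist$binLeft, observedHist$binRight[nrow(observedHist)])
  scores <- vapply(candidateNs, function(N) {
    pred <- predictedPartialHistogram(N, disp, breaks)
    sum((pred$frequency - f)^2)
  }, numeric(1))
  best <- which(scores <= min(scores) + 1e-12)
  list(bestN = if (length(best) == 1L) as.integer(candidateNs[best]) else
         NA_integer_,
       scores = data.frame(N = as.integer(candidateNs), score = scores),
       ties = as.integer(candidateNs[best]))
}
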