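#' Construct an mtDNA state
#'
#' @param wildType wild-type molecule count. Defaults to `copyNumber` minus
#'   the mutant molecules.
#' @param mutantCounts named vector of molecules per mutant lineage (names are
#'   lineage identifiers); empty by default.
#' @param copyNumber mtDNA molecules per cell, default 200.
#' @return An [MtDnaState-class] object.
#' @examples
#' mtDnaState()                                  # 200 wild-type molecules
#' mtDnaState(mutantCounts = c(L1 = 150))        # 75% heteroplasmy
#' @export
mtDnaState <- function(wildType = NULL, mutantCounts = integer(0),
                       copyNumber = 200L) {
  mutantCounts <- as.integer2(mutantCounts)
  copyNumber <- as.integer2(copyNumber)
  if (is.null(wildType)) wildType <- copyNumber - sum(mutantCounts)
  new("MtDnaState", wildType = as.integer2(wildType),
      mutantCounts = mutantCounts, copyNumber = copyNumber)
}

#' Construct a mutation-rate schedule
#'
#' @param muStart per-replication mutation probability at time 0 (default 1e-5).
#' @param muEnd probability at `tEnd` years (default 6e-5).
#' @param tEnd years at which `muEnd` is reached (default 80).
#' @return A [MutationRateSchedule-class] object.
#' @export
mutationRateSchedule <- function(muStart = 1e-5, muEnd = 6e-5, tEnd = 80) {
  new("MutationRateSchedule", muStart = muStart, muEnd = muEnd, tEnd = tEnd)
}

#' Construct a niche configuration
#'
#' @param nSC effective stem cells per crypt (default 5).
#' @param divisionsPerYear stem-cell divisions per year (default 365/7,
#'   i.e. one division per week over 365-day years).
#' @param lifespanYears simulated lifetime (default 80; 4171 divisions).
#' @return A [NicheConfig-class] object.
#' @export
nicheConfig <- function(nSC = 5L, divisionsPerYear = 365 / 7,
                        lifespanYears = 80) {
  new("NicheConfig", nSC = as.integer2(nSC),
      divisionsPerYear = divisionsPerYear, lifespanYears = lifespanYears,
      nDivisions = as.integer(floor(lifespanYears * divisionsPerYear)))
}

#' Construct fate-outcome parameters
#'
#' @param pAsym probability of asymmetric fate outcome per dividing stem cell
#'   (default 0.99, the best-fit value; `1 - pAsym` is the symmetric
#'   probability).
#' @return A [FateParams-class] object.
#' @export
fateParams <- function(pAsym = 0.99) new("FateParams", pAsym = pAsym)

#' Construct neutral-drift parameters
#'
#' @param nSC effective stem cell number N (default 5).
#' @param lambda total clone step rate per year (default 0.6).
#' @param delta fate bias of marked cells, in (-1, 1) (default 0, neutral).
#' @return A [DriftParams-class] object.
#' @export
driftParams <- function(nSC = 5L, lambda = 0.6, delta = 0) {
  new("DriftParams", nSC = as.integer2(nSC), lambda = lambda, delta = delta)
}

#' Construct clone-induction parameters
#'
#' Defaults follow the fitted law with growth rate 0.05 per year and baseline
#' 0.01 per crypt per year per stem cell (so `R0 = 0.05` for N = 5).
#'
#' @param R0 induction events per crypt per year at t = 0.
#' @param eta exponential growth rate per year.
#' @return An [InductionParams-class] object.
#' @export
inductionParams <- function(R0 = 0.05, eta = 0.05) {
  new("InductionParams", R0 = R0, eta = eta)
}

#' Construct section-observation parameters
#'
#' @param sigma circumferential dispersion scale, fraction of circumference
#'   (default 0.03).
#' @param detectionFloor minimum detectable deficiency fraction (default 0.05).
#' @return A [DispersionParams-class] object.
#' @export
dispersionParams <- function(sigma = 0.03, detectionFloor = 0.05) {
  new("DispersionParams", sigma = sigma, detectionFloor = detectionFloor)
}

#' Construct a cohort design
#'
#' @param decadeCounts named integer vector of patients per decade; the
#'   default reproduces the 148-patient study composition.
#' @param cryptsPerPatient crypts scored per biopsy (default 1000, giving a
#'   default cohort of ~148,000 crypts).
#' @param patientDispersion gamma shape of the mean-1 patient-level
#'   mutation-burden multiplier; `Inf` disables heterogeneity (default 4).
#' @return A [CohortDesign-class] object.
#' @export
cohortDesign <- function(decadeCounts = c("17-20" = 2L, "21-30" = 10L,
                                          "31-40" = 25L, "41-50" = 44L,
                                          "51-60" = 37L, "61-70" = 21L,
                                          "71-80" = 9L),
                         cryptsPerPatient = 1000L, patientDispersion = 4) {
  new("CohortDesign", decadeCounts = as.integer2(decadeCounts),
      cryptsPerPatient = as.integer2(cryptsPerPatient),
      patientDispersion = patientDispersion)
}

# strict integer coercion that keeps names and rejects fractional input
as.integer2 <- function(x) {
  if (is.null(x) || length(x) == 0L) return(setNames(integer(0), names(x)))
  if (any(!is.finite(x)) || any(abs(x - round(x)) > 1e-8))
    stop("expected whole numbers, got: ", paste(x, collapse = ", "))
  setNames(as.integer(round(x)), names(x))
}

setMethod("show", "MtDnaState", function(object) {
  h <- sum(object@mutantCounts) / object@copyNumber
  cat("MtDnaState:", object@wildType, "wild-type +",
      sum(object@mutantCounts), "mutant /", object@copyNumber,
      sprintf("molecules (heteroplasmy %.3f, %d lineage%s)\n", h,
              length(object@mutantCounts),
              if (length(object@mutantCounts) == 1L) "" else "s"))
})

setMethod("show", "MutationRateSchedule", function(object) {
  cat(sprintf(
    "MutationRateSchedule: %.3g -> %.3g per replication over %g years\n",
    object@muStart, object@muEnd, object@tEnd))
})

setMethod("show", "NicheConfig", function(object) {
  cat(sprintf(
    "NicheConfig: %d stem cells, %.2f divisions/year, %g years (%d divisions)\n",
    object@nSC, object@divisionsPerYear, object@lifespanYears,
    object@nDivisions))
})

setMethod("show", "FateParams", function(object) {
  cat(sprintf("FateParams: %.1f%% asymmetric / %.1f%% symmetric fate outcome\n",
              100 * object@pAsym, 100 * (1 - object@pAsym)))
})

setMethod("show", "CryptState", function(object) {
  k <- sum(vapply(object@cells, function(c)
    sum(c@mutantCounts) / c@copyNumber >= 0.75, logical(1)))
  cat(sprintf("CryptState '%s': ring of %d stem cells, age %.2f years (%d at >=75%% heteroplasmy)\n",
              object@cryptId, length(object@cells), object@age, k))
})

setMethod("show", "DriftParams", function(object) {
  cat(sprintf("DriftParams: N = %d, lambda = %.3g /clone/year, delta = %.3g\n",
              object@nSC, object@lambda, object@delta))
})

setMethod("show", "InductionParams", function(object) {
  cat(sprintf("InductionParams: R(t) = %.3g * exp(%.3g t) per crypt per year\n",
              object@R0, object@eta))
})

setMethod("show", "DispersionParams", function(object) {
  cat(sprintf("DispersionParams: sigma = %.3g, detection floor = %.3g\n",
              object@sigma, object@detectionFloor))
})

setMethod("show", "CohortDesign", function(object) {
  cat(sprintf("CohortDesign: %d patients, %d crypts each, dispersion shape %g\n",
              sum(object@decadeCounts), object@cryptsPerPatient,
              object@patientDispersion))
  print(object@decadeCounts)
})

setMethod("show", "EnsembleSummary", function(object) {
  cat(sprintf("EnsembleSummary: %d crypts, ages %s\n", object@nRuns,
              paste(object@recordAges, collapse = ", ")))
  cat(sprintf("  mode = %s, pAsym = %.3g, N = %d\n",
              object@params$mode, object@params$pAsym, object@params$nSC))
  utils::head(object@summary)
})

#' @rdname accessors
#' @export
setGeneric("nSC", function(x) standardGeneric("nSC"))
#' Accessors for model parameter objects
#'
#' @param x a parameter object.
#' @return `nSC()` the stem cell number; `ensembleSummary()` the per-age
#'   class-count table; `kMatrix()` the raw crypts-by-ages matrix of
#'   deficient-cell counts.
#' @name accessors
#' @export
setMethod("nSC", "NicheConfig", function(x) x@nSC)
#' @rdname accessors
#' @export
setMethod("nSC", "DriftParams", function(x) x@nSC)

#' @rdname accessors
#' @export
setGeneric("ensembleSummary", function(x) standardGeneric("ensembleSummary"))
#' @rdname accessors
#' @export
setMethod("ensembleSummary", "EnsembleSummary", function(x) x@summary)

#' @rdname accessors
#' @export
setGeneric("kMatrix", function(x) standardGeneric("kMatrix"))
#' @rdname accessors
#' @export
setMethod("kMatrix", "EnsembleSummary", function(x) x@kMatrix)
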