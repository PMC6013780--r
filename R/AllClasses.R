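#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Per-stem-cell mtDNA population
#'
#' Holds the mitochondrial genome pool of a single crypt stem cell: the number
#' of wild-type molecules and the molecule counts of each mutant lineage,
#' keyed by a lineage identifier minted at the originating mutation event.
#' Outside the transient doubled pool of a division, wild-type plus mutant
#' molecules always sum to the cellular copy number.
#'
#' @slot wildType integer, wild-type molecule count.
#' @slot mutantCounts named integer vector, molecules per mutant lineage;
#'   names are lineage identifiers.
#' @slot copyNumber integer, total mtDNA molecules per cell (default 200).
#' @seealso [mtDnaState()], [divideCell()], [isOxphosDeficient()]
#' @export
setClass("MtDnaState",
  representation(wildType = "integer", mutantCounts = "integer",
                 copyNumber = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@wildType) != 1L || is.na(object@wildType) ||
        object@wildType < 0L)
      msg <- c(msg, "wildType must be a single non-negative integer")
    if (any(is.na(object@mutantCounts)) || any(object@mutantCounts < 0L))
      msg <- c(msg, "mutantCounts must be non-negative")
    if (length(object@mutantCounts) > 0L &&
        (is.null(names(object@mutantCounts)) ||
         anyDuplicated(names(object@mutantCounts))))
      msg <- c(msg, "mutantCounts must have unique lineage names")
    if (length(object@copyNumber) != 1L || object@copyNumber < 1L)
      msg <- c(msg, "copyNumber must be a positive integer")
    if (is.null(msg) &&
        object@wildType + sum(object@mutantCounts) != object@copyNumber)
      msg <- c(msg, "wildType + sum(mutantCounts) must equal copyNumber")
    if (is.null(msg)) TRUE else msg
  })

#' Time-increasing mtDNA mutation rate schedule
#'
#' Probability that an mtDNA replication event yields a new mutant molecule,
#' interpolated exponentially in calendar time from `muStart` at time 0 to
#' `muEnd` at `tEnd` years; later times extrapolate the same law.
#'
#' @slot muStart numeric, per-replication mutation probability at time 0
#'   (default 1e-5).
#' @slot muEnd numeric, probability at `tEnd` (default 6e-5).
#' @slot tEnd numeric, years (default 80).
#' @seealso [mutationRateSchedule()], [mutationRateAt()]
#' @export
setClass("MutationRateSchedule",
  representation(muStart = "numeric", muEnd = "numeric", tEnd = "numeric"),
  validity = function(object) {
    if (object@muStart <= 0 || object@muEnd >= 1 ||
        object@muStart > object@muEnd)
      return("need 0 < muStart <= muEnd < 1")
    if (object@tEnd <= 0) return("tEnd must be positive")
    TRUE
  })

#' Stem-cell niche configuration
#'
#' Geometry and tempo of the simulated crypt stem-cell niche: `nSC` stem cells
#' arranged as a one-dimensional ring (annulus) dividing synchronously once
#' per week. `nDivisions` is derived as the whole number of divisions in
#' `lifespanYears` 365-day years (4171 for 80 years of weekly divisions).
#'
#' @slot nSC integer, effective stem cells per crypt (default 5).
#' @slot divisionsPerYear numeric, default 365/7.
#' @slot lifespanYears numeric, default 80.
#' @slot nDivisions integer, derived.
#' @seealso [nicheConfig()], [simulateEnsemble()]
#' @export
setClass("NicheConfig",
  representation(nSC = "integer", divisionsPerYear = "numeric",
                 lifespanYears = "numeric", nDivisions = "integer"),
  validity = function(object) {
    if (object@nSC < 2L) return("nSC must be >= 2")
    if (object@divisionsPerYear <= 0) return("divisionsPerYear must be > 0")
    if (object@lifespanYears <= 0) return("lifespanYears must be > 0")
    if (object@nDivisions !=
        as.integer(floor(object@lifespanYears * object@divisionsPerYear)))
      return("nDivisions must equal floor(lifespanYears * divisionsPerYear)")
    TRUE
  })

#' Division fate-outcome probabilities
#'
#' Per dividing stem cell: with probability `pAsym` the division has an
#' asymmetric fate outcome (one daughter stays in the niche, one leaves,
#' clonal configuration unchanged); otherwise the outcome is symmetric (both
#' daughters remain and a neighbouring stem cell is expunged -- one
#' loss/replacement event).
#'
#' @slot pAsym numeric in \[0, 1\] (default 0.99, the best-fit value).
#' @seealso [fateParams()], [replacementRate()]
#' @export
setClass("FateParams",
  representation(pAsym = "numeric"),
  validity = function(object) {
    if (length(object@pAsym) != 1L || is.na(object@pAsym) ||
        object@pAsym < 0 || object@pAsym > 1)
      return("pAsym must be a single probability in [0, 1]")
    TRUE
  })

#' Ring state of one simulated crypt
#'
#' @slot cells list of [MtDnaState-class] objects (ring order).
#' @slot age numeric, years.
#' @slot cryptId character.
#' @seealso [initCrypt()], [stepGeneration()], [classifyCrypt()]
#' @export
setClass("CryptState",
  representation(cells = "list", age = "numeric", cryptId = "character"),
  validity = function(object) {
    if (length(object@cells) < 2L) return("ring must have >= 2 cells")
    if (!all(vapply(object@cells, is, logical(1), "MtDnaState")))
      return("cells must all be MtDnaState")
    M <- vapply(object@cells, function(c) c@copyNumber, integer(1))
    if (length(unique(M)) != 1L) return("all cells must share copyNumber")
    if (object@age < 0) return("age must be non-negative")
    TRUE
  })

#' Neutral-drift clone dynamics parameters
#'
#' Parameters of the one-dimensional neutral-drift model: `nSC` effective stem
#' cells on the crypt circumference and total clone step rate `lambda` (events
#' per clone per year, split `lambda*(1+delta)/2` up and `lambda*(1-delta)/2`
#' down). `delta` is the fate bias of marked cells: a marked cell replaces an
#' unmarked neighbour with relative efficiency `1+delta` (0 = strictly
#' neutral).
#'
#' @slot nSC integer (default 5).
#' @slot lambda numeric, per-year clone step rate (default 0.6).
#' @slot delta numeric in (-1, 1) (default 0).
#' @seealso [driftParams()], [cloneSizeDistribution()], [cloneStepRate()]
#' @export
setClass("DriftParams",
  representation(nSC = "integer", lambda = "numeric", delta = "numeric"),
  validity = function(object) {
    if (object@nSC < 2L) return("nSC must be >= 2")
    if (object@lambda < 0) return("lambda must be >= 0")
    if (object@delta <= -1 || object@delta >= 1)
      return("delta must lie in (-1, 1)")
    TRUE
  })

#' Clone induction rate parameters
#'
#' Rate at which new OXPHOS-deficient stem-cell clones are induced per crypt,
#' increasing with age as `R0 * exp(eta * t)` events per crypt per year.
#'
#' @slot R0 numeric, rate at t = 0 (default 0.05 = 0.01 * 5).
#' @slot eta numeric, per-year growth rate (default 0.05).
#' @seealso [inductionParams()], [inductionRate()]
#' @export
setClass("InductionParams",
  representation(R0 = "numeric", eta = "numeric"),
  validity = function(object) {
    if (object@R0 < 0) return("R0 must be >= 0")
    if (object@eta < 0) return("eta must be >= 0")
    TRUE
  })

#' Section observation parameters
#'
#' Maps stem-cell-level clonal state to the OXPHOS-deficient circumference
#' fraction seen in a transverse histological section: lateral dispersion of
#' the deficient progeny is modelled as zero-mean Gaussian jitter of scale
#' `sigma` (fraction of circumference) around `k/N`, and fractions below
#' `detectionFloor` are recorded as 0 (histological sensitivity).
#'
#' @slot sigma numeric >= 0 (default 0.03).
#' @slot detectionFloor numeric in \[0, 1) (default 0.05).
#' @seealso [dispersionParams()], [observeSectionFraction()]
#' @export
setClass("DispersionParams",
  representation(sigma = "numeric", detectionFloor = "numeric"),
  validity = function(object) {
    if (object@sigma < 0) return("sigma must be >= 0")
    if (object@detectionFloor < 0 || object@detectionFloor >= 1)
      return("detectionFloor must lie in [0, 1)")
    TRUE
  })

#' Synthetic cohort design
#'
#' Patients-per-decade composition of the emulated biopsy cohort (default: the
#' 148-patient composition 17-20: 2, 21-30: 10, 31-40: 25, 41-50: 44,
#' 51-60: 37, 61-70: 21, 71-80: 9), crypts scored per patient, and the gamma
#' shape of the mean-1 patient-level multiplier on induction/mutation rate
#' modelling patient-to-patient variability in mtDNA mutation burden.
#'
#' @slot decadeCounts named integer vector, patients per decade label.
#' @slot cryptsPerPatient integer (default 1000).
#' @slot patientDispersion numeric gamma shape, `Inf` = no heterogeneity
#'   (default 4).
#' @seealso [cohortDesign()], [generateCohort()]
#' @export
setClass("CohortDesign",
  representation(decadeCounts = "integer", cryptsPerPatient = "integer",
                 patientDispersion = "numeric"),
  validity = function(object) {
    if (is.null(names(object@decadeCounts)))
      return("decadeCounts must be named by decade label, e.g. '21-30'")
    if (!all(grepl("^[0-9]+-[0-9]+$", names(object@decadeCounts))))
      return("decade labels must be of the form 'lo-hi'")
    if (any(object@decadeCounts < 0L)) return("decadeCounts must be >= 0")
    if (object@cryptsPerPatient < 1L) return("cryptsPerPatient must be >= 1")
    if (object@patientDispersion <= 0) return("patientDispersion must be > 0")
    TRUE
  })

#' Ensemble simulation summary
#'
#' Result container of [simulateEnsemble()]: per-age counts of crypts with
#' k = 0..N OXPHOS-deficient stem cells, a clonality audit of the deficient
#' crypts, and the raw per-crypt deficient-cell counts.
#'
#' @slot summary data.frame with columns age, k, count, percent.
#' @slot clonality data.frame with columns age, clonality, count.
#' @slot kMatrix integer matrix, crypts x recorded ages.
#' @slot recordAges numeric.
#' @slot nRuns integer.
#' @slot params list, all generating parameters (scheme flags included).
#' @export
setClass("EnsembleSummary",
  representation(summary = "data.frame", clonality = "data.frame",
                 kMatrix = "matrix", recordAges = "numeric",
                 nRuns = "integer", params = "list"))
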