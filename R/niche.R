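#' Initialise a crypt at birth
#'
#' @param config a [NicheConfig-class].
#' @param copyNumber mtDNA molecules per stem cell (default 200).
#' @param cryptId identifier for the crypt.
#' @return A [CryptState-class] of `nSC` fully wild-type stem cells, age 0.
#' @export
initCrypt <- function(config = nicheConfig(), copyNumber = 200L,
                      cryptId = "crypt1") {
  stopifnot(is(config, "NicheConfig"))
  cells <- replicate(config@nSC, mtDnaState(copyNumber = copyNumber),
                     simplify = FALSE)
  new("CryptState", cells = cells, age = 0, cryptId = cryptId)
}

#' Advance a crypt by one synchronous division round
#'
#' All stem cells divide and half of the daughters are lost so that the niche
#' retains its original size. Cells are resolved in uniformly random order;
#' each dividing cell independently has an asymmetric fate outcome with
#' probability `pAsym` (one random daughter keeps the ring position, the other
#' is discarded towards differentiation) and otherwise a symmetric outcome
#' (both daughters remain, occupying the divider's position and that of one
#' uniformly chosen ring neighbour, which is expunged with all its content --
#' one loss/replacement event). A cell expunged before its own turn does not
#' divide.
#'
#' @param crypt a [CryptState-class].
#' @param fate a [FateParams-class].
#' @param schedule a [MutationRateSchedule-class] (evaluated at the crypt's
#'   current age).
#' @param config a [NicheConfig-class] (supplies the division interval).
#' @param neighbourhood `"ring"` (default; the 1D annulus) or `"global"`
#'   (any other stem cell may be replaced; sensitivity variant).
#' @param scheme mtDNA replication scheme, see [replicatePool()].
#' @return The advanced [CryptState-class] (ring size unchanged).
#' @export
stepGeneration <- function(crypt, fate = fateParams(),
                           schedule = mutationRateSchedule(),
                           config = nicheConfig(),
                           neighbourhood = c("ring", "global"),
                           scheme = c("doubling", "resample")) {
  stopifnot(is(crypt, "CryptState"), is(fate, "FateParams"))
  validObject(crypt)
  neighbourhood <- match.arg(neighbourhood)
  scheme <- match.arg(scheme)
  ser <- serializeRing(crypt@cells)
  mu <- mutationRateAt(crypt@age, schedule)
  res <- cpp_step_generation(ser$wildType, ser$lineageIds, ser$lineageCounts,
                             ser$copyNumber, mu, fate@pAsym,
                             neighbourhood == "ring",
                             match(scheme, c("doubling", "resample")) - 1L,
                             ser$nextId)
  new("CryptState",
      cells = deserializeRing(res$ring, ser$copyNumber, ser$nameTab),
      age = crypt@age + 1 / config@divisionsPerYear, cryptId = crypt@cryptId)
}

#' Classify a crypt by its deficient stem-cell count
#'
#' @param crypt a [CryptState-class] (or an integer count of deficient cells
#'   together with `nSC`).
#' @param theta heteroplasmy threshold, default 0.75.
#' @param nSC ring size when `crypt` is given as a count.
#' @return A list with `label` (`"normal"`, `"partial"` or `"full"`) and
#'   `kDeficient` (0..N).
#' @export
classifyCrypt <- function(crypt, theta = 0.75, nSC = NULL) {
  if (is(crypt, "CryptState")) {
    k <- sum(vapply(crypt@cells, isOxphosDeficient, logical(1), theta = theta))
    N <- length(crypt@cells)
  } else {
    k <- as.integer(crypt)
    if (is.null(nSC)) stop("nSC required when classifying a count")
    N <- as.integer(nSC)
    if (k < 0L || k > N) stop("k must lie in 0..nSC")
  }
  label <- if (k == 0L) "normal" else if (k == N) "full" else "partial"
  list(label = label, kDeficient = as.integer(k))
}

#' Clonality of the OXPHOS-deficient compartment
#'
#' Counts the distinct dominant mutant lineages among the deficient stem
#' cells of a crypt. Fully deficient crypts produced by neutral drift are
#' overwhelmingly clonal (one dominant lineage); independent mutations in the
#' same crypt yield counts above one.
#'
#' @param crypt a [CryptState-class] with at least one deficient cell.
#' @param theta heteroplasmy threshold, default 0.75.
#' @return Integer number of distinct dominant lineages.
#' @export
clonalityOfDeficiency <- function(crypt, theta = 0.75) {
  stopifnot(is(crypt, "CryptState"))
  def <- Filter(function(c) isOxphosDeficient(c, theta), crypt@cells)
  if (length(def) == 0L)
    stop("crypt has no OXPHOS-deficient stem cell")
  dom <- vapply(def, function(c) {
    cnts <- c@mutantCounts
    ids <- as.numeric(names(cnts))
    best <- which(cnts == max(cnts))
    as.character(min(ids[best]))
  }, character(1))
  length(unique(dom))
}

#' Simulate a single crypt trajectory
#'
#' Runs the multi-scale model for one crypt over the configured lifespan and
#' reports its classification at the requested ages.
#'
#' @inheritParams simulateEnsemble
#' @param recordAges ages (years) at which to record the classification.
#' @return A data.frame with columns `age`, `kDeficient`, `label`,
#'   `clonality` and attribute `nDivisions`.
#' @export
runCrypt <- function(config = nicheConfig(), fate = fateParams(),
                     schedule = mutationRateSchedule(), theta = 0.75,
                     recordAges = seq(10, 80, by = 10), copyNumber = 200L,
                     neighbourhood = c("ring", "global"),
                     scheme = c("doubling", "resample")) {
  ens <- simulateEnsemble(config, fate, schedule, theta, nRuns = 1L,
                          recordAges = recordAges, copyNumber = copyNumber,
                          neighbourhood = neighbourhood, scheme = scheme)
  k <- as.integer(kMatrix(ens)[1L, ])
  out <- data.frame(age = ens@recordAges, kDeficient = k,
                    label = vapply(k, function(x)
                      classifyCrypt(x, nSC = config@nSC)$label, character(1)),
                    clonality = as.integer(ens@params$clonalityMatrix[1L, ]))
  attr(out, "nDivisions") <- config@nDivisions
  out
}

#' Simulate an ensemble of independent crypts
#'
#' The workhorse of the multi-scale model: simulates `nRuns` independent
#' crypts over the configured lifespan and summarises, at each recorded age,
#' the counts and percentages of crypts with k = 0..N OXPHOS-deficient stem
#' cells, together with a clonality audit of the deficient crypts.
#'
#' Three modes are available. `"mtdna"` (default) runs the full multi-scale
#' model (mtDNA mutation under the rate schedule, relaxed replication, random
#' segregation, deficiency at the heteroplasmy threshold). `"labelled"`
#' tracks the neutral drift of `nLabelled` initially labelled stem cells with
#' no mtDNA content (for drift validation). `"induction"` induces labelled
#' clones as a Poisson process with rate `R0 * exp(eta * t)` per crypt per
#' year (the analytic model's assumption) and drifts them with the same fate
#' machinery.
#'
#' @param config a [NicheConfig-class].
#' @param fate a [FateParams-class].
#' @param schedule a [MutationRateSchedule-class] (mtdna mode).
#' @param theta heteroplasmy threshold (mtdna mode), default 0.75.
#' @param nRuns number of independent crypts (30,000 reproduces the reference
#'   ensemble size; smaller ensembles are fine for exploration).
#' @param recordAges ages in years at which to record classifications.
#' @param mode `"mtdna"`, `"labelled"` or `"induction"`.
#' @param copyNumber mtDNA molecules per cell (default 200).
#' @param muFactor multiplier on the mutation rate (patient-level burden).
#' @param nLabelled initially labelled cells in `"labelled"` mode (default 1).
#' @param induction an [InductionParams-class] (`"induction"` mode).
#' @param neighbourhood `"ring"` or `"global"` symmetric replacement.
#' @param scheme mtDNA replication scheme, see [replicatePool()].
#' @return An [EnsembleSummary-class].
#' @examples
#' set.seed(7)
#' ens <- simulateEnsemble(nRuns = 50, recordAges = c(40, 80))
#' ensembleSummary(ens)
#' @export
simulateEnsemble <- function(config = nicheConfig(), fate = fateParams(),
                             schedule = mutationRateSchedule(), theta = 0.75,
                             nRuns = 30000L,
                             recordAges = seq(10, 80, by = 10),
                             mode = c("mtdna", "labelled", "induction"),
                             copyNumber = 200L, muFactor = 1,
                             nLabelled = 1L,
                             induction = inductionParams(),
                             neighbourhood = c("ring", "global"),
                             scheme = c("doubling", "resample")) {
  stopifnot(is(config, "NicheConfig"), is(fate, "FateParams"), nRuns >= 1)
  mode <- match.arg(mode)
  neighbourhood <- match.arg(neighbourhood)
  scheme <- match.arg(scheme)
  recordAges <- sort(unique(recordAges))
  if (any(recordAges < 0) || any(recordAges > config@lifespanYears + 1e-9))
    stop("recordAges must lie within [0, lifespanYears]")
  recGens <- ageToGeneration(recordAges, config)
  ring <- neighbourhood == "ring"
  N <- config@nSC
  firstOnset <- NULL
  replacementEvents <- NULL
  if (mode == "mtdna") {
    res <- cpp_simulate_mtdna(as.integer(nRuns), N, as.integer(copyNumber),
                              schedule@muStart * muFactor,
                              schedule@muEnd * muFactor,
                              schedule@tEnd, config@nDivisions,
                              config@divisionsPerYear, fate@pAsym, theta,
                              recGens,
                              match(scheme, c("doubling", "resample")) - 1L,
                              ring, 1.0)
    kMat <- res$k
    clonMat <- res$clonality
    firstOnset <- ifelse(res$firstOnsetGen < 0, NA_integer_,
                         res$firstOnsetGen)
  } else if (mode == "labelled") {
    res <- cpp_simulate_labelled(as.integer(nRuns), N, fate@pAsym,
                                 config@nDivisions, recGens, ring,
                                 as.integer(nLabelled), TRUE)
    kMat <- res$k
    replacementEvents <- res$events
    clonMat <- matrix(NA_integer_, nrow(kMat), ncol(kMat))
  } else {
    res <- cpp_simulate_induction(as.integer(nRuns), N, fate@pAsym,
                                  config@nDivisions, config@divisionsPerYear,
                                  induction@R0, induction@eta, recGens, ring)
    kMat <- res$k
    clonMat <- res$clonality
  }
  colnames(kMat) <- as.character(recordAges)
  tab <- do.call(rbind, lapply(seq_along(recordAges), function(j) {
    cnt <- tabulate(kMat[, j] + 1L, nbins = N + 1L)
    data.frame(age = recordAges[j], k = 0:N, count = cnt,
               percent = 100 * cnt / nRuns)
  }))
  clon <- do.call(rbind, lapply(seq_along(recordAges), function(j) {
    cl <- clonMat[, j]
    cl <- cl[!is.na(cl) & cl > 0]
    if (length(cl) == 0L) return(NULL)
    agg <- table(cl)
    data.frame(age = recordAges[j], clonality = as.integer(names(agg)),
               count = as.integer(agg))
  }))
  if (is.null(clon))
    clon <- data.frame(age = numeric(0), clonality = integer(0),
                       count = integer(0))
  new("EnsembleSummary", summary = tab, clonality = clon, kMatrix = kMat,
      recordAges = recordAges, nRuns = as.integer(nRuns),
      params = list(mode = mode, nSC = N, pAsym = fate@pAsym, theta = theta,
                    copyNumber = copyNumber,
                    muStart = schedule@muStart, muEnd = schedule@muEnd,
                    muTEnd = schedule@tEnd, muFactor = muFactor,
                    divisionsPerYear = config@divisionsPerYear,
                    nDivisions = config@nDivisions,
                    neighbourhood = neighbourhood, scheme = scheme,
                    nLabelled = nLabelled,
                    R0 = induction@R0, eta = induction@eta,
                    firstOnsetGen = firstOnset,
                    replacementEvents = replacementEvents,
                    clonalityMatrix = clonMat))
}

#' Stem-cell replacement-rate conversions
#'
#' `replacementRate()` converts the symmetric fate-outcome probability per
#' division into the loss/replacement rate experienced by a single stem cell
#' (events per SC per year): `pSym * divisionsPerYear`, e.g. 1% symmetric
#' outcome at 52 weekly divisions per year gives 0.52 replacements per SC per
#' year. `cloneStepRate()` converts the same probability into the total step
#' rate of a clone's size random walk: a contiguous clone on the ring has two
#' boundary cells, each generating up- and down-steps at `pSym/2` per
#' division, so the clone chain steps at twice the per-SC replacement rate.
#'
#' @param pSym symmetric fate-outcome probability per division.
#' @param divisionsPerYear divisions per year (default 52 weekly divisions).
#' @return Events per year.
#' @examples
#' replacementRate(0.01)        # 0.52 / year
#' cloneStepRate(0.01)          # 1.04 / year
#' @export
replacementRate <- function(pSym, divisionsPerYear = 52) {
  stopifnot(pSym >= 0, pSym <= 1)
  pSym * divisionsPerYear
}

#' @rdname replacementRate
#' @export
cloneStepRate <- function(pSym, divisionsPerYear = 52) {
  2 * replacementRate(pSym, divisionsPerYear)
}

#' Effective stem-cell number from the modal clone fraction
#'
#' The modal bin of the partial-crypt deficiency-fraction distribution sits at
#' the clonal output of a single stem cell, a fraction `1/N` of the crypt
#' circumference; the observed peak at ~0.2 therefore implies ~5 effective
#' stem cells.
#'
#' @param modalFraction location of the histogram peak, in (0, 1).
#' @return Estimated integer stem-cell number `round(1/modalFraction)`.
#' @export
effectiveScNumber <- function(modalFraction) {
  stopifnot(modalFraction > 0, modalFraction < 1)
  as.integer(round(1 / modalFraction))
}

# age (years) -> completed generations, capped at nDivisions
ageToGeneration <- function(age, config) {
  g <- as.integer(floor(age * config@divisionsPerYear + 1e-9))
  pmin(g, config@nDivisions)
}

# Lineage names are arbitrary strings at the R level but numeric ids in the
# compiled core; the serialization maps names to codes and back, so fresh
# lineages minted during a step get names beyond the existing codes.
serializeRing <- function(cells) {
  M <- cells[[1L]]@copyNumber
  allNames <- unique(unlist(lapply(cells, function(c)
    names(c@mutantCounts))))
  nameTab <- stats::setNames(seq_along(allNames), allNames)
  list(wildType = vapply(cells, function(c) c@wildType, integer(1)),
       lineageIds = lapply(cells, function(c)
         as.numeric(nameTab[names(c@mutantCounts)])),
       lineageCounts = lapply(cells, function(c) unname(c@mutantCounts)),
       copyNumber = M,
       nameTab = nameTab,
       nextId = length(allNames) + 1)
}

deserializeRing <- function(ring, copyNumber, nameTab = NULL) {
  codeToName <- function(code) {
    known <- match(code, nameTab)
    out <- names(nameTab)[known]
    out[is.na(known)] <- as.character(code[is.na(known)])
    out
  }
  lapply(seq_along(ring$wildType), function(i) {
    cnt <- ring$lineageCounts[[i]]
    names(cnt) <- codeToName(ring$lineageIds[[i]])
    mtDnaState(wildType = ring$wildType[i], mutantCounts = cnt,
               copyNumber = copyNumber)
  })
}
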