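#' Sample patient ages for a cohort design
#'
#' Draws, for each decade of the design, the stated number of patients with
#' ages uniform over the decade's integer years.
#'
#' @param design a [CohortDesign-class].
#' @return data.frame with columns `patientId`, `decade`, `age`.
#' @export
samplePatientAges <- function(design = cohortDesign()) {
  stopifnot(is(design, "CohortDesign"))
  rows <- lapply(names(design@decadeCounts), function(dec) {
    n <- design@decadeCounts[[dec]]
    if (n == 0L) return(NULL)
    b <- as.numeric(strsplit(dec, "-")[[1L]])
    data.frame(decade = dec,
               age = sample(seq(b[1L], b[2L]), n, replace = TRUE))
  })
  out <- do.call(rbind, rows)
  out$patientId <- sprintf("P%03d", seq_len(nrow(out)))
  out[, c("patientId", "decade", "age")]
}

#' Generate a synthetic biopsy cohort
#'
#' Emulates the statistical structure of a decade-stratified biopsy cohort:
#' for each patient a mean-1 gamma multiplier on the induction/mutation rate
#' models patient-to-patient variability in mtDNA mutation burden; each
#' crypt's stem-cell-level state at the patient's age comes from the chosen
#' engine; and the observed circumference fraction is produced by the
#' section-observation model with the detection floor applied (fractions at
#' or below the floor score 0). Clusters of adjacent fully deficient crypts
#' are already counted as single clones (crypt fission is not modelled), so
#' cluster collapsing is a no-op.
#'
#' Engines: `"simulator"` runs the full multi-scale mtDNA model per crypt;
#' `"analytic"` samples crypt states from the analytic neutral-drift model
#' (Poisson clone induction at rate `R0 * exp(eta * t)`, clone sizes from the
#' birth--death chain).
#'
#' @param design a [CohortDesign-class].
#' @param engine `"simulator"` or `"analytic"`.
#' @param config,fate,schedule,theta multi-scale model parameters
#'   (simulator engine); see [simulateEnsemble()].
#' @param drift,induction analytic-model parameters (analytic engine).
#' @param disp a [DispersionParams-class].
#' @param copyNumber mtDNA molecules per cell (simulator engine).
#' @param patientAges optional pre-sampled data.frame from
#'   [samplePatientAges()] (sampled fresh otherwise).
#' @return data.frame (the cohort table) with columns `patientId`,
#'   `ageYears`, `cryptId`, `oxphosFraction` and metadata attributes
#'   (`engine`, parameters, patient multipliers).
#' @examples
#' set.seed(1)
#' d <- cohortDesign(decadeCounts = c("41-50" = 2L), cryptsPerPatient = 50L)
#' cohort <- generateCohort(d, engine = "analytic")
#' head(cohort)
#' @export
generateCohort <- function(design = cohortDesign(),
                           engine = c("simulator", "analytic"),
                           config = nicheConfig(), fate = fateParams(),
                           schedule = mutationRateSchedule(), theta = 0.75,
                           drift = driftParams(), induction = inductionParams(),
                           disp = dispersionParams(), copyNumber = 200L,
                           patientAges = NULL) {
  stopifnot(is(design, "CohortDesign"))
  engine <- match.arg(engine)
  if (is.null(patientAges)) patientAges <- samplePatientAges(design)
  nPat <- nrow(patientAges)
  mult <- if (is.finite(design@patientDispersion))
    stats::rgamma(nPat, shape = design@patientDispersion,
                  rate = design@patientDispersion) else rep(1, nPat)
  N <- if (engine == "simulator") config@nSC else drift@nSC
  sampler <- if (engine == "analytic")
    analyticCryptSampler(drift, induction, maxAge = max(patientAges$age))
  rows <- vector("list", nPat)
  for (i in seq_len(nPat)) {
    age <- patientAges$age[i]
    nC <- design@cryptsPerPatient
    if (engine == "simulator") {
      ens <- simulateEnsemble(config, fate, schedule, theta, nRuns = nC,
                              recordAges = age, copyNumber = copyNumber,
                              muFactor = mult[i])
      k <- as.integer(kMatrix(ens)[, 1L])
    } else {
      k <- sampler(nC, age, mult[i])
    }
    f <- observeSectionFraction(k, N, disp)
    f[f <= disp@detectionFloor & f < 1] <- 0
    rows[[i]] <- data.frame(patientId = patientAges$patientId[i],
                            ageYears = age, cryptId = seq_len(nC),
                            oxphosFraction = f)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "engine") <- engine
  attr(out, "design") <- list(decadeCounts = design@decadeCounts,
                              cryptsPerPatient = design@cryptsPerPatient,
                              patientDispersion = design@patientDispersion)
  attr(out, "patientMultipliers") <- stats::setNames(mult,
                                                     patientAges$patientId)
  attr(out, "nSC") <- N
  out
}

# Sampler of per-crypt deficient-cell counts under the analytic model:
# K ~ Poisson(total induction), induction times from the R0*exp(eta t)
# density, clone sizes from the drift chain pmf (cached on a lag grid).
analyticCryptSampler <- function(drift, induction, maxAge, gridStep = 0.25) {
  prop <- chainPropagator(drift)
  N <- drift@nSC
  lags <- seq(0, maxAge + gridStep, by = gridStep)
  pmf <- t(vapply(lags, function(l) prop(l)[2L, ], numeric(N + 1L)))
  eta <- induction@eta
  function(nCrypts, age, mult = 1) {
    R0 <- induction@R0 * mult
    Ltot <- if (eta == 0) R0 * age else R0 * (exp(eta * age) - 1) / eta
    nClone <- stats::rpois(nCrypts, Ltot)
    k <- integer(nCrypts)
    idx <- which(nClone > 0L)
    for (i in idx) {
      u <- stats::runif(nClone[i])
      s <- if (eta == 0) u * age else log(1 + u * (exp(eta * age) - 1)) / eta
      li <- pmin(length(lags), pmax(1L, round((age - s) / gridStep) + 1L))
      sizes <- vapply(li, function(j)
        sample.int(N + 1L, 1L, prob = pmf[j, ]) - 1L, integer(1))
      k[i] <- min(N, sum(sizes))
    }
    k
  }
}

#' Write / read a cohort table
#'
#' Delimited-text round trip for cohort tables: CSV with header columns
#' `patient_id`, `age_years`, `crypt_id`, `oxphos_fraction`. Reading
#' validates every row and reports malformed rows with their line numbers.
#'
#' @param cohort a cohort data.frame (see [generateCohort()]).
#' @param path file path.
#' @return `readCohort()` returns the cohort data.frame (columns `patientId`,
#'   `ageYears`, `cryptId`, `oxphosFraction`); `writeCohort()` returns `path`
#'   invisibly.
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(all(c("patientId", "ageYears", "cryptId", "oxphosFraction") %in%
                  names(cohort)))
  out <- data.frame(patient_id = cohort$patientId,
                    age_years = cohort$ageYears,
                    crypt_id = cohort$cryptId,
                    oxphos_fraction = formatC(cohort$oxphosFraction,
                                              format = "g", digits = 12))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = c("character", "numeric",
                                              "character", "numeric"))
  need <- c("patient_id", "age_years", "crypt_id", "oxphos_fraction")
  if (!identical(names(raw), need))
    stop("malformed cohort header: expected ", paste(need, collapse = ", "))
  bad <- which(is.na(raw$oxphos_fraction) | raw$oxphos_fraction < 0 |
                 raw$oxphos_fraction > 1)
  if (length(bad) > 0L)
    stop("invalid oxphos_fraction outside [0, 1] on line(s) ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "))
  bad <- which(is.na(raw$age_years) | raw$age_years < 17 |
                 raw$age_years > 80)
  if (length(bad) > 0L)
    stop("age_years outside [17, 80] on line(s) ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "))
  data.frame(patientId = raw$patient_id, ageYears = raw$age_years,
             cryptId = raw$crypt_id, oxphosFraction = raw$oxphos_fraction)
}
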