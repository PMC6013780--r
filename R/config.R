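#' Run configuration for the pipeline commands
#'
#' Builds the flat key-value configuration driving [cmdSimulate()],
#' [cmdGenerateCohort()], [cmdAnalyze()] and [cmdRecover()]. All keys default
#' to the reference parameter set (weekly divisions, 200 mtDNA copies,
#' mutation rate 1e-5 rising to 6e-5 by 80 years, 75% deficiency threshold,
#' 5 stem cells, 99% asymmetric fate outcome, 30,000 simulation runs).
#' Unknown keys in `path` or `...` are errors, not warnings.
#'
#' @param path optional YAML file of key-value overrides.
#' @param ... further key overrides (applied after the file).
#' @return A named list of validated configuration values (class
#'   `cryptDriftConfig`).
#' @export
runConfig <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    engine = "simulator",        # cohort engine
    n_sc = 5L,
    copy_number = 200L,
    mu_start = 1e-5,
    mu_end = 6e-5,
    mu_t_end = 80,
    theta = 0.75,
    p_asym = 0.99,
    divisions_per_year = 365 / 7,
    lifespan_years = 80,
    n_runs = 30000L,
    record_ages = seq(10, 80, by = 10),
    lambda = 0.6,
    delta = 0,
    r0 = 0.05,
    eta = 0.05,
    sigma = 0.03,
    detection_floor = 0.05,
    crypts_per_patient = 1000L,
    patient_dispersion = 4,
    neighbourhood = "ring",
    replication_scheme = "doubling",
    out_dir = "cryptdrift-output")
  apply_over <- function(cfg, over, src) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0L)
      stop("unknown configuration key(s) in ", src, ": ",
           paste(unknown, collapse = ", "))
    for (k in names(over)) cfg[[k]] <- over[[k]]
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- apply_over(cfg, yaml::read_yaml(path), path)
  }
  cfg <- apply_over(cfg, list(...), "arguments")
  validateConfig(cfg)
  class(cfg) <- "cryptDriftConfig"
  cfg
}

validateConfig <- function(cfg) {
  with(cfg, {
    if (p_asym < 0 || p_asym > 1) stop("p_asym must lie in [0, 1]")
    if (theta <= 0 || theta > 1) stop("theta must lie in (0, 1]")
    if (mu_start <= 0 || mu_end >= 1 || mu_start > mu_end)
      stop("need 0 < mu_start <= mu_end < 1")
    if (n_sc < 2) stop("n_sc must be >= 2")
    if (n_runs < 1) stop("n_runs must be >= 1")
    if (!engine %in% c("simulator", "analytic"))
      stop("engine must be 'simulator' or 'analytic'")
    if (!neighbourhood %in% c("ring", "global"))
      stop("neighbourhood must be 'ring' or 'global'")
    if (!replication_scheme %in% c("doubling", "resample"))
      stop("replication_scheme must be 'doubling' or 'resample'")
    if (sigma < 0) stop("sigma must be >= 0")
    if (detection_floor < 0 || detection_floor >= 1)
      stop("detection_floor must lie in [0, 1)")
  })
  invisible(cfg)
}

configObjects <- function(cfg) {
  list(config = nicheConfig(nSC = cfg$n_sc,
                            divisionsPerYear = cfg$divisions_per_year,
                            lifespanYears = cfg$lifespan_years),
       fate = fateParams(pAsym = cfg$p_asym),
       schedule = mutationRateSchedule(cfg$mu_start, cfg$mu_end,
                                       cfg$mu_t_end),
       drift = driftParams(nSC = cfg$n_sc, lambda = cfg$lambda,
                           delta = cfg$delta),
       induction = inductionParams(R0 = cfg$r0, eta = cfg$eta),
       disp = dispersionParams(sigma = cfg$sigma,
                               detectionFloor = cfg$detection_floor))
}

#' Derive an independent substream seed from a master seed
#'
#' Deterministic counter-based fan-out of one master seed into independent
#' component seeds, so that parallel and serial execution of the pipeline
#' stages agree; results stay below 2^31.
#'
#' @param master master seed (integer).
#' @param stream substream counter (integer).
#' @return An integer seed.
#' @export
deriveSeed <- function(master, stream) {
  x <- (as.numeric(master) %% 2147483647) + 1
  s <- (as.numeric(stream) %% 65536) + 1
  as.integer((x * 48271 + s * 16807) %% 2147483647)
}

writeMetadata <- function(outDir, cfg, extra = list()) {
  meta <- c(list(package = "cryptDrift",
                 version = as.character(utils::packageVersion("cryptDrift")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S",
                                    tz = "UTC")),
            unclass(cfg), extra)
  jsonlite::write_json(meta, file.path(outDir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

writeTable <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) formatC(v, format = "g", digits = 12))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline commands
#'
#' Thin command-style drivers tying the modules into reproducible runs; each
#' writes delimited result tables plus a machine-readable `metadata.json`
#' (all parameters, seed, scheme flags, package version) sufficient to
#' reproduce the run bit-exactly. An `inst/scripts/cryptdrift` Rscript
#' exposes them as shell subcommands.
#'
#' * `cmdSimulate()`: runs [simulateEnsemble()] and writes
#'   `ensemble_summary.csv` and `clonality.csv`.
#' * `cmdGenerateCohort()`: runs [generateCohort()] and writes `cohort.csv`.
#' * `cmdAnalyze()`: reads a cohort and writes `decade_summary.csv`,
#'   `partial_histogram.csv`, `growth_fits.json` and `ratio_trend.json`.
#' * `cmdRecover()`: runs the parameter-recovery experiments (stem-cell
#'   number scan, loss/replacement rate, induction law, fate asymmetry) and
#'   writes `recovery.json` with per-target estimates, tolerances and
#'   pass/fail flags.
#'
#' @param cfg a configuration from [runConfig()].
#' @param outDir output directory (created if needed; default from config).
#' @param cohortPath path to a cohort CSV (for `cmdAnalyze()`).
#' @return The output directory, invisibly (each command); `cmdRecover()`
#'   returns the recovery report list invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmdSimulate <- function(cfg = runConfig(), outDir = cfg$out_dir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(deriveSeed(cfg$seed, 1L))
  ob <- configObjects(cfg)
  ens <- simulateEnsemble(ob$config, ob$fate, ob$schedule, cfg$theta,
                          nRuns = cfg$n_runs, recordAges = cfg$record_ages,
                          copyNumber = cfg$copy_number,
                          neighbourhood = cfg$neighbourhood,
                          scheme = cfg$replication_scheme)
  writeTable(ensembleSummary(ens), file.path(outDir, "ensemble_summary.csv"))
  writeTable(ens@clonality, file.path(outDir, "clonality.csv"))
  writeMetadata(outDir, cfg, list(command = "simulate",
                                  nRuns = ens@nRuns))
  invisible(outDir)
}

#' @rdname pipeline
#' @export
cmdGenerateCohort <- function(cfg = runConfig(), outDir = cfg$out_dir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(deriveSeed(cfg$seed, 2L))
  ob <- configObjects(cfg)
  cohort <- generateCohort(
    cohortDesign(cryptsPerPatient = cfg$crypts_per_patient,
                 patientDispersion = cfg$patient_dispersion),
    engine = cfg$engine, config = ob$config, fate = ob$fate,
    schedule = ob$schedule, theta = cfg$theta, drift = ob$drift,
    induction = ob$induction, disp = ob$disp,
    copyNumber = cfg$copy_number)
  writeCohort(cohort, file.path(outDir, "cohort.csv"))
  writeMetadata(outDir, cfg, list(command = "generate-cohort",
                                  nPatients = length(unique(cohort$patientId)),
                                  nCrypts = nrow(cohort)))
  invisible(outDir)
}

#' @rdname pipeline
#' @export
cmdAnalyze <- function(cohortPath, cfg = runConfig(), outDir = cfg$out_dir) {
  cohort <- readCohort(cohortPath)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  binned <- decadeSummary(cohort, cfg$detection_floor, N = cfg$n_sc)
  writeTable(binned, file.path(outDir, "decade_summary.csv"))
  hist <- partialFractionHistogram(cohort,
                                   detectionFloor = cfg$detection_floor)
  writeTable(hist, file.path(outDir, "partial_histogram.csv"))
  mids <- decadeMidpoint(binned$decade)
  growth <- list(
    partial = tryCatch(fitExponentialGrowth(mids, binned$pctPartial)[
      c("a", "b", "r2")], error = function(e) list(error = conditionMessage(e))),
    full = tryCatch(fitExponentialGrowth(mids, binned$pctFull)[
      c("a", "b", "r2")], error = function(e) list(error = conditionMessage(e))))
  jsonlite::write_json(growth, file.path(outDir, "growth_fits.json"),
                       auto_unbox = TRUE, digits = NA)
  trend <- tryCatch(
    suppressWarnings(partialFullRatioTrend(binned)[
      c("slope", "intercept", "pValue")]),
    error = function(e) list(error = conditionMessage(e)))
  jsonlite::write_json(trend, file.path(outDir, "ratio_trend.json"),
                       auto_unbox = TRUE, digits = NA)
  writeMetadata(outDir, cfg, list(command = "analyze", cohort = cohortPath))
  invisible(outDir)
}

#' @rdname pipeline
#' @export
cmdRecover <- function(cfg = runConfig(), outDir = cfg$out_dir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rep <- recoveryReport(seed = cfg$seed, nSeeds = 1L,
                        scanCrypts = 6000L, gridCrypts = 2000L,
                        cohortCryptsPerDecade = 2000L)
  jsonlite::write_json(rep, file.path(outDir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeMetadata(outDir, cfg, list(command = "recover"))
  invisible(rep)
}
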