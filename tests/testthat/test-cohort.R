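test_that("patient ages follow the decade composition exactly", {
  set.seed(501)
  ages <- samplePatientAges(cohortDesign())
  expect_equal(nrow(ages), 148L)
  expect_equal(as.vector(table(ages$decade)[names(table(ages$decade))]),
               unname(c("17-20" = 2, "21-30" = 10, "31-40" = 25,
                        "41-50" = 44, "51-60" = 37, "61-70" = 21,
                        "71-80" = 9)[sort(unique(ages$decade))]))
  for (i in seq_len(nrow(ages))) {
    b <- as.numeric(strsplit(ages$decade[i], "-")[[1]])
    expect_true(ages$age[i] >= b[1] && ages$age[i] <= b[2])
  }
  set.seed(501)
  expect_identical(samplePatientAges(cohortDesign()), ages)
})

test_that("cohort generation respects the design and the engines agree", {
  set.seed(502)
  d <- cohortDesign(decadeCounts = c("41-50" = 3L), cryptsPerPatient = 40L)
  co <- generateCohort(d, engine = "analytic")
  expect_equal(nrow(co), 120L)
  expect_equal(length(unique(co$patientId)), 3L)
  expect_true(all(co$oxphosFraction >= 0 & co$oxphosFraction <= 1))
  expect_identical(attr(co, "engine"), "analytic")
  expect_error(generateCohort(d, engine = "nonsense"))

  # zero mutation/induction gives an all-normal cohort
  set.seed(503)
  co0 <- generateCohort(d, engine = "analytic",
                        induction = inductionParams(R0 = 0))
  expect_true(all(co0$oxphosFraction == 0))
  set.seed(504)
  sim0 <- generateCohort(cohortDesign(decadeCounts = c("41-50" = 2L),
                                      cryptsPerPatient = 20L),
                         engine = "simulator",
                         schedule = mutationRateSchedule(1e-300, 1e-299))
  expect_true(all(sim0$oxphosFraction == 0))
})

test_that("cross-engine class fractions agree when induction is matched", {
  # the analytic solver vs the stochastic ring simulator in induction mode,
  # both at the same Poisson induction law and matched clone step rate; the
  # comparison runs in the low-induction regime where the analytic model's
  # clone-independence assumption holds
  set.seed(505)
  n <- 10000
  ind <- inductionParams(R0 = 3e-4, eta = 0.05)
  cfg <- nicheConfig()
  ens <- simulateEnsemble(config = cfg, fate = fateParams(pAsym = 0.99),
                          nRuns = n, recordAges = c(40, 80),
                          mode = "induction", induction = ind)
  lam <- cloneStepRate(0.01, cfg@divisionsPerYear)
  cf <- expectedClassFractions(driftParams(lambda = lam), ind, c(40, 80))
  for (j in 1:2) {
    k <- kMatrix(ens)[, j]
    expect_true(within3SE(mean(k > 0 & k < 5), cf$partial[j], n))
    expect_true(within3SE(mean(k == 5), cf$full[j], n))
  }
})

test_that("deficiency burden rises between the fourth and eighth decades", {
  set.seed(506)
  d <- cohortDesign(decadeCounts = c("31-40" = 5L, "71-80" = 5L),
                    cryptsPerPatient = 300L)
  co <- generateCohort(d, engine = "simulator")
  dec <- ifelse(co$ageYears <= 40, "young", "old")
  fracDef <- tapply(co$oxphosFraction > 0, dec, mean)
  expect_gt(fracDef[["old"]], fracDef[["young"]])
})

test_that("cohort tables round-trip through CSV", {
  set.seed(507)
  d <- cohortDesign(decadeCounts = c("21-30" = 2L), cryptsPerPatient = 30L)
  co <- generateCohort(d, engine = "analytic")
  path <- withr::local_tempfile(fileext = ".csv")
  writeCohort(co, path)
  back <- readCohort(path)
  expect_equal(back$oxphosFraction, co$oxphosFraction, tolerance = 1e-10)
  expect_identical(back$patientId, co$patientId)
  expect_identical(back$ageYears, as.numeric(co$ageYears))

  empty <- co[0, ]
  writeCohort(empty, path)
  expect_equal(nrow(readCohort(path)), 0L)

  bad <- co
  bad$oxphosFraction[3] <- 1.2
  writeCohort(bad, path)
  expect_error(readCohort(path), "line\\(s\\) 4")
  worse <- co
  worse$ageYears[1] <- 90
  writeCohort(worse, path)
  expect_error(readCohort(path), "17, 80")
})

test_that("patient heterogeneity vanishes as the dispersion shape grows", {
  # with no heterogeneity the analytic engine reproduces the model's class
  # fractions at generated scale
  set.seed(508)
  d <- cohortDesign(decadeCounts = c("71-80" = 6L), cryptsPerPatient = 1500L,
                    patientDispersion = Inf)
  ind <- inductionParams(R0 = 5e-4)
  dr <- driftParams(lambda = 0.6)
  ages <- samplePatientAges(d)
  co <- generateCohort(d, engine = "analytic", drift = dr, induction = ind,
                       patientAges = ages)
  cls <- classifyObservedCrypt(co$oxphosFraction)
  cf <- expectedClassFractions(dr, ind, ages$age)
  n <- nrow(co)
  expect_true(within3SE(mean(cls == "full"), mean(cf$full), n))
  expect_true(within3SE(mean(cls == "partial"), mean(cf$partial), n))
})
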