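test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulationConfig(fracLowCh4 = 0), "fracLowCh4")
  expect_error(simulationConfig(fracLowCh4 = 1.2), "fracLowCh4")
  expect_error(simulationConfig(nHC = 1), "nHC")
  expect_error(simulationConfig(maleFrac = 1.5), "maleFrac")
  expect_error(simulationConfig(
    scannerProbs = c(Siemens = 0.5, GE = 0.5, Philips = 0.5)),
    "scannerProbs")
  expect_error(simulationConfig(
    survivalTruth = c(lambda0 = 0.01, logHR_low = 0, b_age = 0, b_sex = 0,
                      b_moca = 0, visit_interval = 0, max_followup = 96,
                      dropout_rate = 0)), "visit_interval")
})

test_that("identical configs give byte-identical cohorts", {
  cfg <- simulationConfig(seed = 33)
  expect_identical(generateHCCohort(cfg), generateHCCohort(cfg))
  s1 <- generatePDMCICohort(cfg)
  s2 <- generatePDMCICohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$visits, s2$visits)
  expect_identical(s1$truth$subjects, s2$truth$subjects)
  # the generator leaves the caller's RNG stream untouched
  set.seed(5); before <- runif(3)
  set.seed(5); invisible(generateHCCohort(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("noise-free HC GMD equals the linear predictor exactly", {
  tr <- c(constant = 0.55, b_age = -0.0012, b_sex = -0.008, b_GE = 0.005,
          b_philips = -0.004, b_tiv = 2e-05, resid_sd = 0)
  hc <- generateHCCohort(simulationConfig(seed = 2, normingTruth = tr))
  pred <- tr[["constant"]] + tr[["b_age"]] * hc$age +
    tr[["b_sex"]] * hc$sex + tr[["b_GE"]] * (hc$scanner == "GE") +
    tr[["b_philips"]] * (hc$scanner == "Philips") + tr[["b_tiv"]] * hc$tiv
  expect_equal(hc$ch4_gmd, pred, tolerance = 1e-12)
})

test_that("HC marginals and OLS refit recover the planted truth at n = 5000", {
  cfg <- simulationConfig(seed = 21, nHC = 5000L)
  hc <- generateHCCohort(cfg)
  # truncation at 30 barely moves the first two moments at these params
  expect_lt(abs(mean(hc$age) - 60.6) / (11.6 / sqrt(5000)), 3.5)
  expect_lt(abs(sd(hc$age) - 11.6) / (11.6 / sqrt(2 * 5000)), 3.5)
  expect_lt(abs(mean(hc$sex) - 0.614) / sqrt(0.614 * 0.386 / 5000), 3)

  fit <- lm(ch4_gmd ~ age + sex + I(scanner == "GE") +
              I(scanner == "Philips") + tiv, data = hc)
  truth <- unname(cfg@normingTruth[1:6])
  dev <- abs(coef(fit) - truth) / sqrt(diag(vcov(fit)))
  expect_true(all(dev < 3))
})

test_that("latent low-Ch4 subgroup has the configured size and shifts", {
  cfg <- simulationConfig(seed = 8, nPD = 2000L)
  sim <- generatePDMCICohort(cfg)
  low <- sim$truth$subjects$latent_low_ch4
  expect_equal(sum(low), round(2000 * 32 / 148))
  # GMD shift: compare group means, noise SD 0.025 -> SE ~ 0.0015
  dGmd <- mean(sim$cohort$ch4_gmd[low == 1]) -
    mean(sim$cohort$ch4_gmd[low == 0])
  expect_lt(abs(dGmd - cfg@gmdShiftLow), 0.005)
  dScopa <- mean(sim$cohort$scopa_aut[low == 1]) -
    mean(sim$cohort$scopa_aut[low == 0])
  expect_gt(dScopa, 3)  # configured +6, attenuated by rounding/clipping
  expect_true(all(sim$cohort$moca >= 21 & sim$cohort$moca <= 26))
  expect_true(all(sim$cohort$updrs_1_2 <= 2))  # no baseline milestones
})

test_that("with no dropout and long follow-up every subject reaches an event", {
  sv <- c(lambda0 = 0.05, logHR_low = log(1.95), b_age = 0.02, b_sex = 0.1,
          b_moca = -0.15, visit_interval = 6, max_followup = 6000,
          dropout_rate = 0)
  sim <- generatePDMCICohort(simulationConfig(seed = 4, nPD = 150L,
                                              survivalTruth = sv))
  ev <- buildMilestoneEvents(sim$visits)
  expect_true(all(ev$event))
  expect_identical(sort(ev$subject_id), sort(sim$cohort$subject_id))
})

test_that("visit-grid events match the latent first-passage times", {
  sim <- generatePDMCICohort(simulationConfig(seed = 12, nPD = 400L))
  ev <- buildMilestoneEvents(sim$visits)
  mg <- merge(ev, sim$truth$subjects, by = "subject_id")
  expect_equal(mg$event, mg$observed_event)
  expect_equal(mg$time, mg$observed_time)
  # grid event time is the first visit at or after the latent time
  withEv <- mg[mg$event, ]
  expect_true(all(withEv$time >= withEv$latent_event_time))
  expect_true(all(withEv$time - withEv$latent_event_time < 6))
  expect_equal(withEv$first_milestone_type, withEv$milestone_type)
})

test_that("null clinical shifts produce nominal type-I error downstream", {
  cfg0 <- function(seed) simulationConfig(
    seed = seed, gmdShiftLow = 0,
    clinicalShifts = c(updrs1 = 0, updrs2 = 0, updrs3 = 0, scopa_aut = 0,
                       rbdsq = 0, upsit = 0, moca = 0))
  reps <- 600
  rej <- vapply(seq_len(reps), function(r) {
    sim <- generatePDMCICohort(cfg0(30000 + r))
    low <- sim$truth$subjects$latent_low_ch4 == 1
    kruskalWallis(sim$cohort$scopa_aut[low],
                  sim$cohort$scopa_aut[!low])$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.025)
  expect_lt(mean(rej), 0.075)
})

test_that("generated GM images carry the planted region GMD", {
  for (planted in c(0, 0.5, 0.91)) {
    im <- generateGMImage(planted, c(8, 8, 8), seed = 1)
    expect_equal(computeRegionGMD(im$map, im$mask)$value, planted,
                 tolerance = 1e-10)
    expect_true(all(voxelArray(im$map) >= 0 & voxelArray(im$map) <= 1))
  }
  # different seeds: different voxel patterns, same extracted value
  a <- generateGMImage(0.37, c(6, 6, 6), seed = 1)
  b <- generateGMImage(0.37, c(6, 6, 6), seed = 2)
  expect_false(identical(voxelArray(a$map), voxelArray(b$map)))
  expect_equal(computeRegionGMD(a$map, a$mask)$value,
               computeRegionGMD(b$map, b$mask)$value, tolerance = 1e-10)
  expect_error(generateGMImage(1.2), "planted_gmd")
  expect_error(generateGMImage(0.5, c(3, 8, 8)), "grid_shape")
})

test_that("synthetic cohort round-trips through the on-disk format", {
  sim <- generatePDMCICohort(simulationConfig(seed = 9, nPD = 30L))
  dir <- tempfile("synth")
  paths <- writeSyntheticCohort(sim, dir)
  back <- read.csv(paths[["cohort"]])
  expect_equal(back$ch4_gmd, sim$cohort$ch4_gmd, tolerance = 1e-12)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$seed, 9)
  expect_equal(truth$survivalTruth[["logHR_low"]], log(1.95),
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
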