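oneBin <- function(cohort) computeSubtypeThresholds(
  cohort, durationBins = c(0, Inf), minPerBin = 1L)

uniformCohort <- function(n, seed) {
  set.seed(seed)
  data.frame(updrs2 = runif(n, 0, 52), updrs3 = runif(n, 0, 132),
             scopa_aut = runif(n, 0, 69), rbdsq = runif(n, 0, 13),
             moca = runif(n, 0, 30), disease_duration = runif(n, 0, 10))
}

test_that("composite motor score is the UPDRS-II + III sum", {
  expect_equal(compositeMotorScore(5, 22), 27)
  expect_equal(compositeMotorScore(0, 0), 0)
  # sum of the low-Ch4 group's published medians, as an illustrative input
  expect_equal(compositeMotorScore(7.0, 27.0), 34.0)
  expect_error(compositeMotorScore(NA, 3), "requires")
})

test_that("duration-bin 75th percentiles use linear interpolation", {
  co <- uniformCohort(100, 1)
  co$scopa_aut <- 1:100  # known order statistics
  thr <- oneBin(co)
  expect_equal(unname(percentileMatrix(thr)[1, "scopa_aut"]), 75.25)
  # degenerate constant score: threshold equals the constant
  co$rbdsq <- 7
  expect_equal(unname(percentileMatrix(oneBin(co))[1, "rbdsq"]), 7)
  # determinism
  expect_equal(percentileMatrix(computeSubtypeThresholds(co)),
               percentileMatrix(computeSubtypeThresholds(co)))
  # per-bin minimum n guard and bin coverage errors
  expect_error(computeSubtypeThresholds(co[1:5, ],
                                        durationBins = c(0, Inf)),
               "only 5")
  expect_error(assignSubtype(transform(co, disease_duration = -1),
                             oneBin(co)), "outside")
})

test_that("the three-subtype rule follows the strict percentile definitions", {
  co <- uniformCohort(200, 2)
  thr <- oneBin(co)
  p <- percentileMatrix(thr)[1, ]
  mk <- function(motor, scopa, rbd, cog) data.frame(
    updrs2 = 0, updrs3 = motor, scopa_aut = scopa, rbdsq = rbd,
    moca = 30 - cog, disease_duration = 1)
  eps <- 1e-6
  # everything strictly below -> mild motor predominant
  below <- mk(p["motor"] - eps, p["scopa_aut"] - eps, p["rbdsq"] - eps,
              p["cog_burden"] - eps)
  expect_equal(assignSubtype(below, thr)$subtype, "mild_motor_predominant")
  # motor above with exactly one non-motor above -> diffuse malignant
  one <- mk(p["motor"] + eps, p["scopa_aut"] + eps, p["rbdsq"] - eps,
            p["cog_burden"] - eps)
  expect_equal(assignSubtype(one, thr)$subtype, "diffuse_malignant")
  # all three non-motor above, motor below -> still diffuse malignant
  allNm <- mk(p["motor"] - eps, p["scopa_aut"] + eps, p["rbdsq"] + eps,
              p["cog_burden"] + eps)
  expect_equal(assignSubtype(allNm, thr)$subtype, "diffuse_malignant")
  # exact ties satisfy neither strict inequality -> intermediate
  ties <- mk(p["motor"], p["scopa_aut"], p["rbdsq"], p["cog_burden"])
  expect_equal(assignSubtype(ties, thr)$subtype, "intermediate")
})

test_that("labels partition all inputs and are monotone in burden", {
  co <- uniformCohort(3000, 3)
  thr <- computeSubtypeThresholds(co)
  lab <- assignSubtype(co, thr)
  expect_true(all(lab$subtype %in% c("diffuse_malignant", "intermediate",
                                     "mild_motor_predominant")))
  expect_equal(nrow(lab), nrow(co))

  # raising burden on one axis never moves malignant-ward labels back
  rank3 <- c(mild_motor_predominant = 1, intermediate = 2,
             diffuse_malignant = 3)
  worse <- co
  worse$scopa_aut <- pmin(worse$scopa_aut + 20, 69)
  lab2 <- assignSubtype(worse, thr)
  expect_true(all(rank3[lab2$subtype] >= rank3[lab$subtype]))
  worse2 <- co
  worse2$moca <- pmax(worse2$moca - 10, 0)  # worse cognition
  lab3 <- assignSubtype(worse2, thr)
  expect_true(all(rank3[lab3$subtype] >= rank3[lab$subtype]))
})

test_that("MoCA enters as burden: lower MoCA can only raise severity", {
  co <- uniformCohort(500, 4)
  thr <- oneBin(co)
  p <- percentileMatrix(thr)[1, ]
  # cog axis exceeds iff 30 - moca > threshold, i.e. moca strictly below
  # its own 25th percentile
  subj <- data.frame(updrs2 = 0, updrs3 = 0, scopa_aut = 0, rbdsq = 0,
                     moca = 30 - p["cog_burden"] + 1e-3,
                     disease_duration = 1)
  expect_false(assignSubtype(subj, thr)$exceeds_cog)
  subj$moca <- 30 - p["cog_burden"] - 1e-3
  expect_true(assignSubtype(subj, thr)$exceeds_cog)
})

test_that("thresholds serialize to JSON and back unchanged", {
  co <- uniformCohort(300, 5)
  thr <- computeSubtypeThresholds(co)
  path <- tempfile(fileext = ".json")
  saveSubtypeThresholds(thr, path)
  thr2 <- readSubtypeThresholds(path)
  expect_equal(binEdges(thr2), binEdges(thr))
  expect_equal(percentileMatrix(thr2), percentileMatrix(thr))
  expect_identical(assignSubtype(co, thr2)$subtype,
                   assignSubtype(co, thr)$subtype)
  unlink(path)
})
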