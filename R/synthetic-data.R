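#' @include AllClasses.R
NULL

# Run expr with a private RNG stream, restoring the caller's state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.rtruncnorm_min <- function(n, mean, sd, min) {
  lo <- stats::pnorm((min - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, lo, 1))
}

.clipRound <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)

#' Construct a synthetic-cohort simulation configuration
#'
#' Defaults emulate the reference study conditions: 171 healthy controls
#' for the norming reference; 148 PD-MCI subjects of whom a latent 32/148
#' have low Ch4 grey-matter density with shifted (worse) clinical scores;
#' ages 60.6 +/- 11.6 years truncated at 30, 61.4% male; three scanner
#' types (Siemens/GE/Philips, 0.6/0.2/0.2); six-monthly visits; and an
#' exponential proportional-hazards time to first cognitive milestone with
#' hazard ratio 1.95 for the low-Ch4 group. See
#' [SimulationConfig-class] for the meaning of every field.
#'
#' @param nHC,nPD cohort sizes.
#' @param fracLowCh4 latent low-Ch4 fraction among PD-MCI.
#' @param seed integer RNG seed recorded in the config; all generator
#'   output is a deterministic function of the config.
#' @param ageMean,ageSd,maleFrac,tivMean,tivSd covariate distribution
#'   parameters (years, proportion, mL).
#' @param scannerProbs named probabilities over Siemens, GE, Philips.
#' @param normingTruth true healthy-control GMD model (GMD units):
#'   `constant`, `b_age`, `b_sex`, `b_GE`, `b_philips`, `b_tiv`,
#'   `resid_sd`.
#' @param gmdShiftLow additive GMD shift for the latent low subgroup.
#' @param clinicalShifts additive score shifts for the latent low
#'   subgroup (UPSIT and MoCA shifts are negative: lower = worse).
#' @param survivalTruth planted proportional-hazards truth; see
#'   [SimulationConfig-class].
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 7)
#' cfg
#' @export
simulationConfig <- function(
    nHC = 171L, nPD = 148L, fracLowCh4 = 32 / 148, seed = 1L,
    ageMean = 60.6, ageSd = 11.6, maleFrac = 0.614,
    tivMean = 1450, tivSd = 130,
    scannerProbs = c(Siemens = 0.6, GE = 0.2, Philips = 0.2),
    normingTruth = c(constant = 0.55, b_age = -0.0012, b_sex = -0.008,
                     b_GE = 0.005, b_philips = -0.004, b_tiv = 2e-05,
                     resid_sd = 0.025),
    gmdShiftLow = -0.05,
    clinicalShifts = c(updrs1 = 1, updrs2 = 2, updrs3 = 5, scopa_aut = 6,
                       rbdsq = 1, upsit = -6, moca = -1),
    survivalTruth = c(lambda0 = 0.008, logHR_low = log(1.95), b_age = 0.02,
                      b_sex = 0.1, b_moca = -0.15, visit_interval = 6,
                      max_followup = 96, dropout_rate = 0.002)) {
  new("SimulationConfig",
      nHC = as.integer(nHC), nPD = as.integer(nPD),
      fracLowCh4 = fracLowCh4, seed = as.integer(seed),
      ageMean = ageMean, ageSd = ageSd, maleFrac = maleFrac,
      tivMean = tivMean, tivSd = tivSd, scannerProbs = scannerProbs,
      normingTruth = normingTruth, gmdShiftLow = gmdShiftLow,
      clinicalShifts = clinicalShifts, survivalTruth = survivalTruth)
}

.drawCovariates <- function(n, config, prefix) {
  data.frame(
    subject_id = sprintf("%s-%04d", prefix, seq_len(n)),
    age = .rtruncnorm_min(n, config@ageMean, config@ageSd, 30),
    sex = as.integer(stats::runif(n) < config@maleFrac),
    scanner = sample(.SCANNER_LEVELS, n, replace = TRUE,
                     prob = config@scannerProbs),
    tiv = stats::rnorm(n, config@tivMean, config@tivSd),
    stringsAsFactors = FALSE)
}

.gmdLinearPredictor <- function(covars, truth) {
  truth[["constant"]] + truth[["b_age"]] * covars$age +
    truth[["b_sex"]] * covars$sex +
    truth[["b_GE"]] * (covars$scanner == "GE") +
    truth[["b_philips"]] * (covars$scanner == "Philips") +
    truth[["b_tiv"]] * covars$tiv
}

#' Generate a synthetic healthy-control norming cohort
#'
#' Draws `nHC` control subjects with age, sex, scanner, TIV, a MoCA in the
#' healthy range (>= 27) and raw Ch4 GMD from the configured linear model
#' `GMD = constant + b_age*age + b_sex*sex + b_GE*I(GE) +
#' b_philips*I(Philips) + b_tiv*TIV + eps`, `eps ~ N(0, resid_sd)`.
#' Output is byte-identical for identical configs (the seed is part of
#' the config).
#'
#' @param config a [SimulationConfig-class].
#' @return data.frame with columns `subject_id`, `age`, `sex` (male = 1),
#'   `scanner`, `tiv` (mL), `moca`, `mci_flag`, `ch4_gmd`.
#' @examples
#' hc <- generateHCCohort(simulationConfig(seed = 1))
#' head(hc)
#' @export
generateHCCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  .withSeed(config@seed + 101L, {
    hc <- .drawCovariates(config@nHC, config, "HC")
    hc$moca <- .clipRound(stats::rnorm(config@nHC, 28.3, 1.1), 27, 30)
    hc$mci_flag <- FALSE
    hc$ch4_gmd <- .gmdLinearPredictor(hc, config@normingTruth) +
      stats::rnorm(config@nHC, 0, config@normingTruth[["resid_sd"]])
    hc
  })
}

.MILESTONE_TYPES <- c("moca_lt_cutoff", "updrs_1_1", "hallucinations",
                      "apathy", "dementia_clinical", "dementia_composite")

#' Generate a synthetic PD-MCI cohort with longitudinal milestone visits
#'
#' Draws `nPD` PD-MCI subjects. A latent fraction `fracLowCh4` are "low
#' Ch4": their raw GMD is shifted by `gmdShiftLow` and their clinical
#' scores receive the configured shifts (worse motor, autonomic, RBD and
#' olfactory scores, lower MoCA). Time to first cognitive milestone is
#' drawn from an exponential proportional-hazards model with log hazard
#' ratio `logHR_low` for the latent low group plus centred age, sex and
#' MoCA effects; the continuous latent time is mapped onto the discrete
#' 6-month visit grid (event observed at the first visit at or after the
#' latent time), with exponential dropout and administrative censoring at
#' `max_followup`. Visit rows before the event never satisfy any
#' milestone criterion; at and after the event visit the subject's
#' (randomly chosen) milestone type is planted in the visit scores, so
#' [detectMilestones()] recovers the grid event time exactly.
#'
#' The planted truth (latent group, continuous event/dropout times, true
#' coefficients) is returned alongside the data and is never consumed by
#' any analysis function; it exists so tests can compare estimates
#' against it.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements
#'   \describe{
#'     \item{cohort}{baseline table: covariates, `disease_duration`
#'       (years), clinical scores (`moca` in 21–26, `updrs1`, `updrs2`,
#'       `updrs3`, `scopa_aut`, `rbdsq`, `upsit`, items `updrs_1_1`,
#'       `updrs_1_2`, `updrs_1_5`), raw `ch4_gmd`.}
#'     \item{visits}{long-format visit table: `subject_id`,
#'       `visit_month`, `moca`, `updrs_1_1`, `updrs_1_2`, `updrs_1_5`,
#'       `dementia_clinical`, `dementia_composite`.}
#'     \item{truth}{list: `subjects` (latent group, continuous event and
#'       dropout times, observed grid time/status), `normingTruth`,
#'       `gmdShiftLow`, `clinicalShifts`, `survivalTruth`, `seed`.}
#'   }
#' @export
generatePDMCICohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  sv <- config@survivalTruth
  sh <- config@clinicalShifts
  .withSeed(config@seed + 202L, {
    n <- config@nPD
    pd <- .drawCovariates(n, config, "PD")
    nLow <- max(1L, round(config@fracLowCh4 * n))
    low <- integer(n)
    low[sample.int(n, nLow)] <- 1L
    pd$ch4_gmd <- .gmdLinearPredictor(pd, config@normingTruth) +
      stats::rnorm(n, 0, config@normingTruth[["resid_sd"]]) +
      config@gmdShiftLow * low

    pd$disease_duration <- pmin(stats::rlnorm(n, log(0.6), 0.9), 15)
    pd$moca <- .clipRound(stats::rnorm(n, 24.6, 1.4) + sh[["moca"]] * low,
                          21, 26)
    pd$updrs1 <- .clipRound(stats::rnorm(n, 1.6, 1.6) + sh[["updrs1"]] * low,
                            0, 52)
    pd$updrs2 <- .clipRound(stats::rnorm(n, 5.5, 3.6) + sh[["updrs2"]] * low,
                            0, 52)
    pd$updrs3 <- .clipRound(stats::rnorm(n, 23, 8.5) + sh[["updrs3"]] * low,
                            0, 132)
    pd$scopa_aut <- .clipRound(stats::rnorm(n, 14, 9) +
                                 sh[["scopa_aut"]] * low, 0, 69)
    pd$rbdsq <- .clipRound(stats::rnorm(n, 3.5, 2.4) + sh[["rbdsq"]] * low,
                           0, 13)
    pd$upsit <- .clipRound(stats::rnorm(n, 22, 7.5) + sh[["upsit"]] * low,
                           0, 40)
    # baseline Part I items stay below the milestone cutoff (0-2)
    itemProbs <- function(shifted) {
      p <- if (shifted) c(0.55, 0.3, 0.15) else c(0.75, 0.18, 0.07)
      sample(0:2, n, replace = TRUE, prob = p)
    }
    pd$updrs_1_1 <- ifelse(low == 1L, itemProbs(TRUE), itemProbs(FALSE))
    pd$updrs_1_2 <- ifelse(low == 1L, itemProbs(TRUE), itemProbs(FALSE))
    pd$updrs_1_5 <- ifelse(low == 1L, itemProbs(TRUE), itemProbs(FALSE))

    # proportional-hazards latent event time (months), centred covariates
    lp <- sv[["logHR_low"]] * low +
      sv[["b_age"]] * (pd$age - config@ageMean) +
      sv[["b_sex"]] * (pd$sex - config@maleFrac) +
      sv[["b_moca"]] * (pd$moca - 24.5)
    tLatent <- stats::rexp(n, rate = sv[["lambda0"]] * exp(lp))
    tDropout <- if (sv[["dropout_rate"]] > 0)
      stats::rexp(n, sv[["dropout_rate"]]) else rep(Inf, n)

    interval <- sv[["visit_interval"]]
    lastVisit <- pmax(0, floor(pmin(tDropout, sv[["max_followup"]]) /
                                 interval)) * interval
    eventVisit <- ceiling(tLatent / interval) * interval
    hasEvent <- eventVisit <= lastVisit
    obsTime <- ifelse(hasEvent, eventVisit, lastVisit)
    mtype <- sample(.MILESTONE_TYPES, n, replace = TRUE,
                    prob = c(0.35, 0.2, 0.1, 0.15, 0.1, 0.1))

    # long visit table, vectorized over all subject-visit rows
    nv <- as.integer(lastVisit / interval) + 1L
    rowSubj <- rep.int(seq_len(n), nv)
    month <- (sequence(nv) - 1L) * interval
    nr <- length(month)
    post <- hasEvent[rowSubj] & month >= eventVisit[rowSubj]
    type <- mtype[rowSubj]

    moca <- .clipRound(pd$moca[rowSubj] - 0.02 * month +
                         stats::rnorm(nr, 0, 0.8), 21, 30)
    moca[post & type == "moca_lt_cutoff"] <-
      sample(15:20, sum(post & type == "moca_lt_cutoff"), replace = TRUE)
    item <- function(nm) {
      x <- sample(0:2, nr, replace = TRUE, prob = c(0.72, 0.2, 0.08))
      x[post & type == nm] <- sample(3:4, sum(post & type == nm),
                                     replace = TRUE, prob = c(0.8, 0.2))
      x
    }
    visits <- data.frame(
      subject_id = pd$subject_id[rowSubj],
      visit_month = month,
      moca = moca,
      updrs_1_1 = item("updrs_1_1"),
      updrs_1_2 = item("hallucinations"),
      updrs_1_5 = item("apathy"),
      dementia_clinical = post & type == "dementia_clinical",
      dementia_composite = post & type == "dementia_composite",
      stringsAsFactors = FALSE)

    truth <- list(
      subjects = data.frame(subject_id = pd$subject_id,
                            latent_low_ch4 = low,
                            latent_event_time = tLatent,
                            dropout_time = tDropout,
                            observed_time = obsTime,
                            observed_event = hasEvent,
                            milestone_type = ifelse(hasEvent, mtype, "none"),
                            stringsAsFactors = FALSE),
      normingTruth = config@normingTruth,
      gmdShiftLow = config@gmdShiftLow,
      clinicalShifts = config@clinicalShifts,
      survivalTruth = sv,
      seed = config@seed)

    list(cohort = pd, visits = visits, truth = truth)
  })
}

#' Generate a small synthetic GM volume with a known region GMD
#'
#' Builds a compact probabilistic mask (random weights on a central
#' blob) and a grey-matter volume whose mask-weighted mean equals
#' `planted_gmd` to within 1e-10 by construction: random values on the
#' mask support are recentred about `planted_gmd` along the direction
#' orthogonal to the weights, with the perturbation amplitude chosen so
#' all voxel values stay in [0, 1]. Voxels outside the support carry
#' unconstrained background values. Both volumes share a 1.5-mm
#' isotropic grid-centred affine.
#'
#' @param planted_gmd target region GMD, in [0, 1].
#' @param grid_shape integer length-3, each >= 4.
#' @param seed integer seed; different seeds give different voxel
#'   patterns with the same extracted GMD.
#' @return list with elements `map` ([GreyMatterMap-class]) and `mask`
#'   ([ProbabilisticMask-class]).
#' @examples
#' im <- generateGMImage(0.5, c(8, 8, 8), seed = 3)
#' computeRegionGMD(im$map, im$mask)$value
#' @export
generateGMImage <- function(planted_gmd, grid_shape = c(8L, 8L, 8L),
                            seed = 1L) {
  if (!is.numeric(planted_gmd) || length(planted_gmd) != 1L ||
      is.na(planted_gmd) || planted_gmd < 0 || planted_gmd > 1)
    stop("'planted_gmd' must be a single value in [0, 1]", call. = FALSE)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("'grid_shape' must be three integers, each >= 4", call. = FALSE)
  .withSeed(seed, {
    w <- array(0, grid_shape)
    lo <- pmax(2L, floor(grid_shape / 4))
    hi <- pmin(grid_shape - 1L, ceiling(3 * grid_shape / 4))
    w[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      stats::runif(prod(hi - lo + 1L), 0.05, 1)

    g <- 0.8 * stats::runif(prod(grid_shape))  # background
    sup <- which(as.numeric(w) > 0)
    r <- stats::runif(length(sup))
    dev <- r - sum(r * w[sup]) / sum(w[sup])
    span <- max(max(dev), -min(dev), .Machine$double.eps)
    alpha <- 0.9 * min(planted_gmd, 1 - planted_gmd) / span
    g[sup] <- planted_gmd + alpha * dev
    dim(g) <- grid_shape
    list(map = greyMatterMap(g, voxelSize = 1.5),
         mask = probabilisticMask(w, voxelSize = 1.5, regionName = "Ch4"))
  })
}

#' Write generator output to plain files
#'
#' Writes the cohort and visit tables as CSV and the planted truth as
#' JSON (with the seed recorded), the generator's on-disk interchange
#' format used by the pipeline.
#'
#' @param sim a list as returned by [generatePDMCICohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeSyntheticCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "pd_cohort.csv"),
             visits = file.path(dir, "pd_visits.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(sim$cohort, paths[["cohort"]], row.names = FALSE)
  utils::write.csv(sim$visits, paths[["visits"]], row.names = FALSE)
  truth <- sim$truth
  for (nm in c("normingTruth", "clinicalShifts", "survivalTruth"))
    truth[[nm]] <- as.list(truth[[nm]])  # keep names in JSON
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(paths)
}
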