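#' @import methods
NULL

#' GreyMatterMap: a 3D grey-matter probability or modulated-volume image
#'
#' Container for a spatially normalized, modulated grey-matter map as
#' produced by a voxel-based-morphometry pipeline: a 3D voxel array plus
#' the voxel-to-world affine and voxel dimensions. Values are grey-matter
#' fractions (unitless) or modulated volumes per voxel (mm^3); the package
#' is agnostic and carries whatever map is supplied.
#'
#' @slot voxels 3D numeric array of non-negative, finite voxel values.
#' @slot affine 4x4 voxel-to-world transform (must be invertible).
#' @slot voxelSize numeric length-3, voxel edge lengths in mm.
#'
#' @seealso [greyMatterMap()], [computeRegionGMD()], [computeTIV()]
#' @export
setClass("GreyMatterMap",
  representation(voxels = "array", affine = "matrix", voxelSize = "numeric"))

setValidity("GreyMatterMap", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "'voxels' must be a 3D array")
  if (anyNA(object@voxels) || any(!is.finite(object@voxels)))
    msg <- c(msg, "'voxels' must be finite and non-missing")
  else if (any(object@voxels < 0))
    msg <- c(msg, "'voxels' must be non-negative")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "'affine' must be a 4x4 matrix")
  else if (abs(det(object@affine)) < .Machine$double.eps)
    msg <- c(msg, "'affine' must be invertible")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "'voxelSize' must be three positive lengths (mm)")
  if (length(msg)) msg else TRUE
})

#' ProbabilisticMask: voxel weights for a region of interest
#'
#' A probabilistic region mask (for example the Ch4 / nucleus basalis of
#' Meynert map derived from histology) on the same voxel grid as the
#' grey-matter maps it is applied to. Weights are non-negative and need
#' not sum or peak at 1; region grey-matter density normalizes by the
#' total weight.
#'
#' @slot weights 3D numeric array of non-negative voxel weights with
#'   positive total weight.
#' @slot affine 4x4 voxel-to-world transform.
#' @slot voxelSize numeric length-3, voxel edge lengths in mm.
#' @slot regionName single string naming the region (e.g. "Ch4").
#'
#' @seealso [probabilisticMask()], [computeRegionGMD()]
#' @export
setClass("ProbabilisticMask",
  representation(weights = "array", affine = "matrix",
                 voxelSize = "numeric", regionName = "character"))

setValidity("ProbabilisticMask", function(object) {
  msg <- character()
  if (length(dim(object@weights)) != 3L)
    msg <- c(msg, "'weights' must be a 3D array")
  if (anyNA(object@weights) || any(!is.finite(object@weights)))
    msg <- c(msg, "'weights' must be finite and non-missing")
  else {
    if (any(object@weights < 0))
      msg <- c(msg, "'weights' must be non-negative")
    if (sum(object@weights) <= 0)
      msg <- c(msg, "total mask weight must be > 0")
  }
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "'affine' must be a 4x4 matrix")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "'voxelSize' must be three positive lengths (mm)")
  if (length(object@regionName) != 1L || is.na(object@regionName))
    msg <- c(msg, "'regionName' must be a single string")
  if (length(msg)) msg else TRUE
})

#' NormingModel: healthy-control reference model for Ch4 GMD
#'
#' A fitted regression-based norming model. Raw region GMD is first
#' anchored to the healthy-control reference as a scaled score
#' (mean 10, SD 3 in the reference sample); the scaled score is then
#' regressed on age, sex, scanner type (GE and Philips offsets against a
#' Siemens baseline) and total intracranial volume. A subject's adjusted
#' z-score is (observed - predicted scaled score) / RMSE.
#'
#' @slot hcGmdMean reference-sample mean of raw GMD.
#' @slot hcGmdSd reference-sample SD of raw GMD (must be > 0).
#' @slot coefficients named numeric: `constant`, `b_age` (per year),
#'   `b_sex` (per unit sex code, male = 1), `b_GE`, `b_philips`
#'   (scanner offsets), `b_tiv` (per mL), all in scaled-score units.
#' @slot rmse residual standard deviation of the reference fit, in
#'   scaled-score units, denominator n - p - 1.
#' @slot nReference number of reference subjects used in the fit.
#' @slot scannerLevels character, known scanner categories; the first is
#'   the reference level.
#' @slot threshold z threshold for the low-Ch4 label (label is "low"
#'   iff z <= threshold); default -1.
#'
#' @seealso [fitNormingModel()], [adjustedZ()], [toScaledScore()]
#' @export
setClass("NormingModel",
  representation(hcGmdMean = "numeric", hcGmdSd = "numeric",
                 coefficients = "numeric", rmse = "numeric",
                 nReference = "integer", scannerLevels = "character",
                 threshold = "numeric"))

.NORMING_COEF_NAMES <- c("constant", "b_age", "b_sex", "b_GE", "b_philips",
                         "b_tiv")

setValidity("NormingModel", function(object) {
  msg <- character()
  if (length(object@hcGmdSd) != 1L || object@hcGmdSd <= 0)
    msg <- c(msg, "'hcGmdSd' must be a single positive number")
  if (!identical(names(object@coefficients), .NORMING_COEF_NAMES))
    msg <- c(msg, sprintf("'coefficients' must be named %s",
                          paste(.NORMING_COEF_NAMES, collapse = ", ")))
  if (length(object@rmse) != 1L || object@rmse <= 0)
    msg <- c(msg, "'rmse' must be a single positive number")
  # p = 5 predictors + intercept
  if (length(object@nReference) != 1L || object@nReference <= 6L)
    msg <- c(msg, "'nReference' must exceed the number of predictors + 1")
  if (length(object@scannerLevels) < 1L)
    msg <- c(msg, "'scannerLevels' must name at least one scanner")
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    msg <- c(msg, "'threshold' must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' SubtypeThresholds: duration-specific 75th-percentile cut points
#'
#' Per-duration-bin 75th percentiles of the composite motor score
#' (MDS-UPDRS-II + III) and the three non-motor burden axes (SCOPA-AUT,
#' RBDSQ, cognitive burden 30 - MoCA), used by the diffuse-malignant /
#' intermediate / mild-motor-predominant subtype rule.
#'
#' @slot binEdges increasing numeric vector of disease-duration bin
#'   edges in years; bins are [e1, e2), ..., [e_{k}, e_{k+1}) and must
#'   start at 0 and end at Inf.
#' @slot percentiles numeric matrix, one row per bin, columns
#'   `motor`, `scopa_aut`, `rbdsq`, `cog_burden`.
#' @slot nPerBin integer, subjects per bin in the cohort the thresholds
#'   were computed from.
#' @slot method single string recording the quantile definition.
#'
#' @seealso [computeSubtypeThresholds()], [assignSubtype()]
#' @export
setClass("SubtypeThresholds",
  representation(binEdges = "numeric", percentiles = "matrix",
                 nPerBin = "integer", method = "character"))

.SUBTYPE_AXES <- c("motor", "scopa_aut", "rbdsq", "cog_burden")

setValidity("SubtypeThresholds", function(object) {
  msg <- character()
  e <- object@binEdges
  if (length(e) < 2L || any(diff(e) <= 0))
    msg <- c(msg, "'binEdges' must be strictly increasing with >= 2 edges")
  else {
    if (e[1] != 0) msg <- c(msg, "'binEdges' must start at 0")
    if (!is.infinite(e[length(e)]))
      msg <- c(msg, "'binEdges' must end at Inf to cover all durations")
  }
  nb <- length(e) - 1L
  if (!identical(colnames(object@percentiles), .SUBTYPE_AXES))
    msg <- c(msg, sprintf("'percentiles' columns must be %s",
                          paste(.SUBTYPE_AXES, collapse = ", ")))
  if (nrow(object@percentiles) != nb || length(object@nPerBin) != nb)
    msg <- c(msg, "'percentiles' rows and 'nPerBin' must match bin count")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic cohort generator
#'
#' Declares the study conditions the generator emulates: cohort sizes, the
#' latent low-Ch4 fraction, covariate distributions, the planted
#' healthy-control norming truth (a linear model for raw Ch4 GMD), clinical
#' score shifts for the latent low-Ch4 subgroup, and the planted
#' proportional-hazards survival truth for time to first cognitive
#' milestone on a 6-month visit grid.
#'
#' @slot nHC healthy-control cohort size.
#' @slot nPD PD-MCI cohort size.
#' @slot fracLowCh4 latent fraction of PD-MCI subjects with low Ch4,
#'   strictly inside (0, 1).
#' @slot seed integer RNG seed; all outputs are reproducible given the
#'   config (which includes the seed).
#' @slot ageMean,ageSd age distribution in years (truncated normal,
#'   minimum 30).
#' @slot maleFrac proportion of males (sex coded male = 1, female = 0).
#' @slot tivMean,tivSd total intracranial volume in mL.
#' @slot scannerProbs named probabilities over Siemens, GE, Philips.
#' @slot normingTruth named numeric: `constant`, `b_age`, `b_sex`,
#'   `b_GE`, `b_philips`, `b_tiv`, `resid_sd` — the true linear model for
#'   healthy-control raw GMD, residual SD > 0.
#' @slot gmdShiftLow additive shift (GMD units, negative) applied to the
#'   latent low-Ch4 subgroup's raw GMD.
#' @slot clinicalShifts named numeric shifts added to the low subgroup's
#'   clinical scores: `updrs1`, `updrs2`, `updrs3`, `scopa_aut`, `rbdsq`,
#'   `upsit`, `moca`.
#' @slot survivalTruth named numeric: `lambda0` (baseline exponential
#'   hazard per month), `logHR_low`, `b_age`, `b_sex`, `b_moca`
#'   (covariate log hazard ratios), `visit_interval` (months),
#'   `max_followup` (months), `dropout_rate` (exponential dropout hazard
#'   per month; 0 disables dropout).
#'
#' @seealso [simulationConfig()], [generateHCCohort()],
#'   [generatePDMCICohort()]
#' @export
setClass("SimulationConfig",
  representation(nHC = "integer", nPD = "integer", fracLowCh4 = "numeric",
                 seed = "integer", ageMean = "numeric", ageSd = "numeric",
                 maleFrac = "numeric", tivMean = "numeric", tivSd = "numeric",
                 scannerProbs = "numeric", normingTruth = "numeric",
                 gmdShiftLow = "numeric", clinicalShifts = "numeric",
                 survivalTruth = "numeric"))

.NORMING_TRUTH_NAMES <- c(.NORMING_COEF_NAMES, "resid_sd")
.CLINICAL_SHIFT_NAMES <- c("updrs1", "updrs2", "updrs3", "scopa_aut",
                           "rbdsq", "upsit", "moca")
.SURVIVAL_TRUTH_NAMES <- c("lambda0", "logHR_low", "b_age", "b_sex",
                           "b_moca", "visit_interval", "max_followup",
                           "dropout_rate")
.SCANNER_LEVELS <- c("Siemens", "GE", "Philips")

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nHC < 2L) msg <- c(msg, "'nHC' must be >= 2")
  if (object@nPD < 2L) msg <- c(msg, "'nPD' must be >= 2")
  if (object@fracLowCh4 <= 0 || object@fracLowCh4 >= 1)
    msg <- c(msg, "'fracLowCh4' must lie strictly inside (0, 1)")
  if (object@maleFrac < 0 || object@maleFrac > 1)
    msg <- c(msg, "'maleFrac' must lie in [0, 1]")
  if (object@ageSd <= 0) msg <- c(msg, "'ageSd' must be > 0")
  if (object@tivSd <= 0) msg <- c(msg, "'tivSd' must be > 0")
  if (!identical(names(object@scannerProbs), .SCANNER_LEVELS) ||
      any(object@scannerProbs < 0) ||
      abs(sum(object@scannerProbs) - 1) > 1e-8)
    msg <- c(msg, "'scannerProbs' must be probabilities over Siemens, GE, Philips summing to 1")
  if (!identical(names(object@normingTruth), .NORMING_TRUTH_NAMES))
    msg <- c(msg, sprintf("'normingTruth' must be named %s",
                          paste(.NORMING_TRUTH_NAMES, collapse = ", ")))
  else if (object@normingTruth[["resid_sd"]] < 0)
    msg <- c(msg, "'normingTruth[resid_sd]' must be >= 0")
  if (!identical(names(object@clinicalShifts), .CLINICAL_SHIFT_NAMES))
    msg <- c(msg, sprintf("'clinicalShifts' must be named %s",
                          paste(.CLINICAL_SHIFT_NAMES, collapse = ", ")))
  if (!identical(names(object@survivalTruth), .SURVIVAL_TRUTH_NAMES))
    msg <- c(msg, sprintf("'survivalTruth' must be named %s",
                          paste(.SURVIVAL_TRUTH_NAMES, collapse = ", ")))
  else {
    if (object@survivalTruth[["visit_interval"]] <= 0)
      msg <- c(msg, "'survivalTruth[visit_interval]' must be > 0")
    if (object@survivalTruth[["lambda0"]] <= 0)
      msg <- c(msg, "'survivalTruth[lambda0]' must be > 0")
    if (object@survivalTruth[["dropout_rate"]] < 0)
      msg <- c(msg, "'survivalTruth[dropout_rate]' must be >= 0")
    if (object@survivalTruth[["max_followup"]] <= 0)
      msg <- c(msg, "'survivalTruth[max_followup]' must be > 0")
  }
  if (length(msg)) msg else TRUE
})

## show methods ------------------------------------------------------------

#' @describeIn GreyMatterMap-class compact display
#' @param object a `GreyMatterMap`
#' @export
setMethod("show", "GreyMatterMap", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("GreyMatterMap: %d x %d x %d voxels (%.2g x %.2g x %.2g mm)\n",
              d[1], d[2], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

#' @describeIn ProbabilisticMask-class compact display
#' @param object a `ProbabilisticMask`
#' @export
setMethod("show", "ProbabilisticMask", function(object) {
  d <- dim(object@weights)
  cat(sprintf("ProbabilisticMask '%s': %d x %d x %d voxels\n",
              object@regionName, d[1], d[2], d[3]))
  cat(sprintf("  support %d voxels, total weight %.4g\n",
              sum(object@weights > 0), sum(object@weights)))
})

#' @describeIn NormingModel-class compact display
#' @param object a `NormingModel`
#' @export
setMethod("show", "NormingModel", function(object) {
  cat(sprintf("NormingModel (n = %d reference subjects)\n",
              object@nReference))
  cat(sprintf("  reference GMD: mean %.5g, SD %.5g\n",
              object@hcGmdMean, object@hcGmdSd))
  co <- object@coefficients
  cat("  scaled-score regression:\n")
  for (nm in names(co)) cat(sprintf("    %-10s %+.5g\n", nm, co[[nm]]))
  cat(sprintf("  RMSE %.5g; low-Ch4 threshold z <= %g\n",
              object@rmse, object@threshold))
})

#' @describeIn SubtypeThresholds-class compact display
#' @param object a `SubtypeThresholds`
#' @export
setMethod("show", "SubtypeThresholds", function(object) {
  nb <- length(object@binEdges) - 1L
  cat(sprintf("SubtypeThresholds: %d duration bin(s), quantile method '%s'\n",
              nb, object@method))
  for (i in seq_len(nb)) {
    cat(sprintf("  [%g, %g) yr (n = %d):", object@binEdges[i],
                object@binEdges[i + 1L], object@nPerBin[i]))
    cat(sprintf(" %s=%.4g", colnames(object@percentiles),
                object@percentiles[i, ]), "\n")
  }
})

#' @describeIn SimulationConfig-class compact display
#' @param object a `SimulationConfig`
#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d HC, %d PD-MCI (latent low-Ch4 fraction %.3f), seed %d\n",
              object@nHC, object@nPD, object@fracLowCh4, object@seed))
  cat(sprintf("  age %g +/- %g yr (min 30), %.0f%% male, TIV %g +/- %g mL\n",
              object@ageMean, object@ageSd, 100 * object@maleFrac,
              object@tivMean, object@tivSd))
  cat(sprintf("  survival: lambda0 %g/mo, logHR(low) %.3f, visits every %g mo, max %g mo\n",
              object@survivalTruth[["lambda0"]],
              object@survivalTruth[["logHR_low"]],
              object@survivalTruth[["visit_interval"]],
              object@survivalTruth[["max_followup"]]))
})
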