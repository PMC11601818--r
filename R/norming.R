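#' @include AllClasses.R
NULL

.checkScanner <- function(scanner, levels) {
  bad <- setdiff(unique(scanner), levels)
  if (length(bad))
    stop(sprintf("unknown scanner category '%s'; known categories: %s",
                 paste(bad, collapse = "', '"),
                 paste(levels, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Convert raw region GMD to a reference-anchored scaled score
#'
#' Linear standardization of raw GMD against the healthy-control
#' reference to the conventional scaled-score metric (mean 10, SD 3 in
#' the reference sample): `scaled = 10 + 3 * (raw - mean_HC) / sd_HC`.
#' Applied to the full reference sample this yields sample mean 10 and
#' sample SD 3 exactly.
#'
#' @param raw numeric raw GMD value(s).
#' @param model a [NormingModel-class] (supplies the reference mean/SD),
#'   or a list/vector with `hc_gmd_mean` and `hc_gmd_sd`.
#' @return numeric scaled score(s), unrounded.
#' @examples
#' hc_gmd <- rnorm(50, 0.45, 0.03)
#' s <- 10 + 3 * scale(hc_gmd)  # what toScaledScore computes
#' @export
toScaledScore <- function(raw, model) {
  if (is(model, "NormingModel")) {
    m <- model@hcGmdMean; s <- model@hcGmdSd
  } else {
    m <- model[["hc_gmd_mean"]]; s <- model[["hc_gmd_sd"]]
  }
  if (is.null(s) || !is.finite(s) || s <= 0)
    stop("degenerate reference: healthy-control GMD SD must be > 0",
         call. = FALSE)
  10 + 3 * (raw - m) / s
}

.normingDesign <- function(tab) {
  cbind(age = tab$age, sex = tab$sex,
        GE = as.numeric(tab$scanner == "GE"),
        philips = as.numeric(tab$scanner == "Philips"),
        tiv = tab$tiv)
}

#' Fit the healthy-control norming model for Ch4 GMD
#'
#' Converts reference-cohort raw GMD to scaled scores (mean 10, SD 3)
#' and regresses them by ordinary least squares on age, sex, scanner
#' indicators (GE and Philips against a Siemens baseline) and TIV. The
#' residual standard deviation with denominator `n - p - 1` (p = 5
#' predictors) is stored as the RMSE used to standardize deviations into
#' adjusted z-scores.
#'
#' @param hc reference data.frame with complete columns `ch4_gmd`,
#'   `age`, `sex` (male = 1), `scanner` (Siemens/GE/Philips), `tiv`.
#' @param threshold z threshold for the low-Ch4 label (default -1).
#' @return a [NormingModel-class].
#' @examples
#' hc <- generateHCCohort(simulationConfig(seed = 1))
#' fitNormingModel(hc)
#' @export
fitNormingModel <- function(hc, threshold = -1) {
  stopifnot(is.data.frame(hc))
  need <- c("ch4_gmd", "age", "sex", "scanner", "tiv")
  miss <- setdiff(need, names(hc))
  if (length(miss))
    stop(sprintf("reference table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (anyNA(hc[need]))
    stop("reference table has missing covariates; norming requires complete cases",
         call. = FALSE)
  if (nrow(hc) <= 6L)
    stop("need more than 6 reference subjects to fit 5 predictors",
         call. = FALSE)
  .checkScanner(hc$scanner, .SCANNER_LEVELS)

  m <- mean(hc$ch4_gmd)
  s <- stats::sd(hc$ch4_gmd)
  if (s <= 0)
    stop("degenerate reference: healthy-control GMD SD must be > 0",
         call. = FALSE)
  scaled <- 10 + 3 * (hc$ch4_gmd - m) / s
  X <- .normingDesign(hc)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    dropped <- c("(constant)", colnames(X))[-qrX$pivot[seq_len(qrX$rank)]]
    stop(sprintf("collinear reference design; degenerate column(s): %s (e.g. a single scanner type present)",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  fit <- stats::lm(scaled ~ age + sex + GE + philips + tiv,
                   data = data.frame(scaled = scaled, X))
  co <- stats::coef(fit)
  names(co) <- .NORMING_COEF_NAMES
  new("NormingModel",
      hcGmdMean = m, hcGmdSd = s, coefficients = co,
      rmse = sqrt(sum(stats::residuals(fit)^2) / (nrow(hc) - 6)),
      nReference = nrow(hc), scannerLevels = .SCANNER_LEVELS,
      threshold = threshold)
}

.predictScaled <- function(tab, model) {
  co <- model@coefficients
  co[["constant"]] + co[["b_age"]] * tab$age + co[["b_sex"]] * tab$sex +
    co[["b_GE"]] * (tab$scanner == "GE") +
    co[["b_philips"]] * (tab$scanner == "Philips") +
    co[["b_tiv"]] * tab$tiv
}

#' Adjusted Ch4 z-scores and low/normal classification
#'
#' For each subject, converts raw GMD to the reference-anchored scaled
#' score, predicts the expected scaled score from age, sex, scanner and
#' TIV via the fitted reference regression, and standardizes the
#' deviation by the reference RMSE:
#' `z = (scaled_actual - scaled_predicted) / RMSE`. Subjects are labelled
#' `"low"` iff `z <= threshold` (default -1; the boundary is inclusive
#' for low) and `"normal"` otherwise.
#'
#' @param subjects data.frame with columns `ch4_gmd`, `age`, `sex`,
#'   `scanner`, `tiv` (one row per subject).
#' @param model a fitted [NormingModel-class].
#' @return `subjects` with columns `ch4_scaled`, `ch4_z`, `ch4_group`
#'   appended.
#' @examples
#' cfg <- simulationConfig(seed = 1)
#' model <- fitNormingModel(generateHCCohort(cfg))
#' pd <- generatePDMCICohort(cfg)$cohort
#' table(adjustedZ(pd, model)$ch4_group)
#' @export
adjustedZ <- function(subjects, model) {
  stopifnot(is(model, "NormingModel"), is.data.frame(subjects))
  need <- c("ch4_gmd", "age", "sex", "scanner", "tiv")
  miss <- setdiff(need, names(subjects))
  if (length(miss))
    stop(sprintf("subject table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (anyNA(subjects[need]))
    stop("missing covariates; norming requires complete cases", call. = FALSE)
  .checkScanner(subjects$scanner, model@scannerLevels)
  scaled <- toScaledScore(subjects$ch4_gmd, model)
  z <- (scaled - .predictScaled(subjects, model)) / model@rmse
  subjects$ch4_scaled <- scaled
  subjects$ch4_z <- z
  subjects$ch4_group <- ifelse(z <= model@threshold, "low", "normal")
  subjects
}

#' Save / load a norming model as JSON
#'
#' Serializes every model component (reference statistics, named
#' coefficients, RMSE, n, scanner levels, threshold) at full floating
#' point precision so a reloaded model reproduces identical z-scores.
#'
#' @param model a [NormingModel-class].
#' @param path JSON file path.
#' @return `saveNormingModel`: `path` invisibly; `readNormingModel`: a
#'   [NormingModel-class].
#' @export
saveNormingModel <- function(model, path) {
  stopifnot(is(model, "NormingModel"))
  jsonlite::write_json(
    list(hc_gmd_mean = model@hcGmdMean, hc_gmd_sd = model@hcGmdSd,
         coefficients = as.list(model@coefficients), rmse = model@rmse,
         n_reference = model@nReference,
         scanner_levels = model@scannerLevels,
         threshold = model@threshold),
    path, auto_unbox = TRUE, digits = I(17))  # lossless double round-trip
  invisible(path)
}

#' @rdname saveNormingModel
#' @export
readNormingModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- unlist(x$coefficients)[.NORMING_COEF_NAMES]
  new("NormingModel", hcGmdMean = x$hc_gmd_mean, hcGmdSd = x$hc_gmd_sd,
      coefficients = co, rmse = x$rmse,
      nReference = as.integer(x$n_reference),
      scannerLevels = x$scanner_levels, threshold = x$threshold)
}
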