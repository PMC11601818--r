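#' @include AllClasses.R
NULL

#' Composite motor score
#'
#' Sum of the MDS-UPDRS Part II (motor experiences of daily living) and
#' Part III (motor examination) scores.
#'
#' @param updrs2,updrs3 numeric scores (UPDRS-II 0-52, UPDRS-III 0-132).
#' @return numeric composite motor score.
#' @examples
#' compositeMotorScore(5, 22)  # 27
#' @export
compositeMotorScore <- function(updrs2, updrs3) {
  if (anyNA(updrs2) || anyNA(updrs3))
    stop("composite motor score requires both UPDRS-II and UPDRS-III",
         call. = FALSE)
  updrs2 + updrs3
}

.subtypeAxes <- function(tab) {
  need <- c("updrs2", "updrs3", "scopa_aut", "rbdsq", "moca")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("subtype inputs lack column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  # MoCA runs opposite to burden: exceeding the 75th percentile of
  # (30 - MoCA) means worse cognition, i.e. MoCA below its 25th percentile.
  cbind(motor = compositeMotorScore(tab$updrs2, tab$updrs3),
        scopa_aut = tab$scopa_aut, rbdsq = tab$rbdsq,
        cog_burden = 30 - tab$moca)
}

#' Duration-specific 75th-percentile subtype thresholds
#'
#' Computes, within each disease-duration bin, the 75th percentile
#' (linear-interpolation quantile, R type 7) of the composite motor
#' score and of the three non-motor burden axes: SCOPA-AUT, RBDSQ, and
#' cognitive burden (30 - MoCA). Thresholds are duration specific so a
#' subject is compared against peers at a similar disease stage.
#'
#' @param cohort data.frame with columns `updrs2`, `updrs3`,
#'   `scopa_aut`, `rbdsq`, `moca`, `disease_duration` (years).
#' @param durationBins increasing bin edges in years, starting at 0 and
#'   ending at `Inf`; defaults to tertiles of the cohort's durations.
#' @param minPerBin minimum subjects per bin (guards against unstable
#'   percentiles).
#' @return a [SubtypeThresholds-class].
#' @examples
#' pd <- generatePDMCICohort(simulationConfig(seed = 1))$cohort
#' computeSubtypeThresholds(pd)
#' @export
computeSubtypeThresholds <- function(cohort, durationBins = NULL,
                                     minPerBin = 20L) {
  stopifnot(is.data.frame(cohort))
  if (!"disease_duration" %in% names(cohort))
    stop("subtype inputs lack column(s): disease_duration", call. = FALSE)
  if (any(cohort$disease_duration < 0, na.rm = TRUE))
    stop("disease_duration must be >= 0", call. = FALSE)
  axes <- .subtypeAxes(cohort)
  if (is.null(durationBins)) {
    inner <- unique(stats::quantile(cohort$disease_duration, c(1, 2) / 3,
                                    type = 7, names = FALSE))
    durationBins <- c(0, inner[inner > 0], Inf)
  }
  nb <- length(durationBins) - 1L
  bin <- findInterval(cohort$disease_duration, durationBins,
                      rightmost.closed = FALSE)
  perc <- matrix(NA_real_, nb, length(.SUBTYPE_AXES),
                 dimnames = list(NULL, .SUBTYPE_AXES))
  nPerBin <- integer(nb)
  for (i in seq_len(nb)) {
    idx <- which(bin == i)
    nPerBin[i] <- length(idx)
    if (length(idx) < minPerBin)
      stop(sprintf("duration bin [%g, %g) has only %d subject(s) (minimum %d)",
                   durationBins[i], durationBins[i + 1L], length(idx),
                   minPerBin), call. = FALSE)
    perc[i, ] <- apply(axes[idx, , drop = FALSE], 2, stats::quantile,
                       probs = 0.75, type = 7, names = FALSE)
  }
  new("SubtypeThresholds", binEdges = as.numeric(durationBins),
      percentiles = perc, nPerBin = nPerBin,
      method = "75th percentile, linear interpolation (type 7)")
}

#' Assign data-driven PD subtypes
#'
#' Applies the percentile rule within each subject's disease-duration
#' bin. With `T` the bin's 75th percentiles:
#' \itemize{
#'   \item diffuse malignant: composite motor > T_motor AND at least one
#'     non-motor axis > its T, OR all three non-motor axes > their T;
#'   \item mild motor predominant: composite motor < T_motor AND all
#'     three non-motor axes < their T;
#'   \item intermediate: everything else (ties at a threshold satisfy
#'     neither strict inequality and fall here).
#' }
#' The three labels partition all valid inputs.
#'
#' @param cohort data.frame with the subtype input columns (see
#'   [computeSubtypeThresholds()]).
#' @param thresholds a [SubtypeThresholds-class] whose bins cover every
#'   subject's duration.
#' @return `cohort` with columns `subtype` (one of `diffuse_malignant`,
#'   `intermediate`, `mild_motor_predominant`) and audit flags
#'   `exceeds_motor`, `exceeds_scopa_aut`, `exceeds_rbdsq`,
#'   `exceeds_cog` appended.
#' @export
assignSubtype <- function(cohort, thresholds) {
  stopifnot(is.data.frame(cohort), is(thresholds, "SubtypeThresholds"))
  if (!"disease_duration" %in% names(cohort))
    stop("subtype inputs lack column(s): disease_duration", call. = FALSE)
  axes <- .subtypeAxes(cohort)
  edges <- thresholds@binEdges
  bin <- findInterval(cohort$disease_duration, edges,
                      rightmost.closed = FALSE)
  out <- bin < 1L | bin > nrow(thresholds@percentiles) |
    is.na(cohort$disease_duration)
  if (any(out))
    stop(sprintf("disease duration outside threshold bins for subject(s): %s",
                 paste(utils::head(which(out), 5), collapse = ", ")),
         call. = FALSE)
  thr <- thresholds@percentiles[bin, , drop = FALSE]
  above <- axes > thr
  below <- axes < thr
  nmAbove <- rowSums(above[, c("scopa_aut", "rbdsq", "cog_burden"),
                           drop = FALSE])
  nmBelow <- rowSums(below[, c("scopa_aut", "rbdsq", "cog_burden"),
                           drop = FALSE])
  malignant <- (above[, "motor"] & nmAbove >= 1L) | nmAbove == 3L
  mild <- below[, "motor"] & nmBelow == 3L
  cohort$subtype <- ifelse(malignant, "diffuse_malignant",
                           ifelse(mild, "mild_motor_predominant",
                                  "intermediate"))
  cohort$exceeds_motor <- above[, "motor"]
  cohort$exceeds_scopa_aut <- above[, "scopa_aut"]
  cohort$exceeds_rbdsq <- above[, "rbdsq"]
  cohort$exceeds_cog <- above[, "cog_burden"]
  cohort
}

#' Save / load subtype thresholds as JSON
#'
#' @param thresholds a [SubtypeThresholds-class].
#' @param path JSON file path.
#' @return `saveSubtypeThresholds`: `path` invisibly;
#'   `readSubtypeThresholds`: a [SubtypeThresholds-class].
#' @export
saveSubtypeThresholds <- function(thresholds, path) {
  stopifnot(is(thresholds, "SubtypeThresholds"))
  jsonlite::write_json(
    list(bin_edges = thresholds@binEdges,
         percentiles = as.data.frame(thresholds@percentiles),
         n_per_bin = thresholds@nPerBin, method = thresholds@method),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname saveSubtypeThresholds
#' @export
readSubtypeThresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- as.numeric(x$bin_edges)
  edges[is.na(edges)] <- Inf  # JSON has no Inf literal; null maps back
  perc <- as.matrix(x$percentiles)[, .SUBTYPE_AXES, drop = FALSE]
  dimnames(perc) <- list(NULL, .SUBTYPE_AXES)
  new("SubtypeThresholds", binEdges = edges, percentiles = perc,
      nPerBin = as.integer(x$n_per_bin), method = x$method)
}
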