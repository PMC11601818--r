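#' @include AllClasses.R
NULL

#' Select PD-MCI participants
#'
#' Applies the eligibility rule: exclude anyone with MoCA < 21 (dementia
#' risk); retain subjects with MoCA 21-26, or with MoCA >= 21 and two or
#' more neurocognitive test scores more than 1.5 SD below the normative
#' mean (standardized scores supplied in `cog_cols`). Subjects
#' categorized on MoCA alone (no usable test scores) are counted in the
#' `"moca_only"` attribute.
#'
#' @param cohort data.frame with a `moca` column and optionally
#'   standardized neurocognitive score columns.
#' @param cog_cols character vector of standardized (z) test-score
#'   columns; may be empty.
#' @param sd_cutoff impairment cutoff in SD units (default 1.5).
#' @return the retained rows, with attributes `"excluded"` (data.frame
#'   of `subject_id`, `reason`) and `"moca_only"` (count).
#' @export
selectPDMCI <- function(cohort, cog_cols = character(), sd_cutoff = 1.5) {
  stopifnot(is.data.frame(cohort))
  if (!"moca" %in% names(cohort))
    stop("cohort lacks a 'moca' column", call. = FALSE)
  if (anyNA(cohort$moca))
    stop("missing MoCA values; eligibility requires MoCA", call. = FALSE)
  miss <- setdiff(cog_cols, names(cohort))
  if (length(miss))
    stop(sprintf("cohort lacks cognitive score column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  nLow <- if (length(cog_cols)) {
    rowSums(as.matrix(cohort[cog_cols]) < -sd_cutoff, na.rm = TRUE)
  } else rep(0L, nrow(cohort))
  hasTests <- if (length(cog_cols)) {
    rowSums(!is.na(as.matrix(cohort[cog_cols]))) > 0
  } else rep(FALSE, nrow(cohort))

  dementiaRisk <- cohort$moca < 21
  crit1 <- !dementiaRisk & cohort$moca <= 26
  crit2 <- !dementiaRisk & nLow >= 2L
  keep <- crit1 | crit2
  reason <- rep(NA_character_, nrow(cohort))
  reason[dementiaRisk] <- "MoCA < 21 (dementia risk)"
  reason[!dementiaRisk & !keep] <-
    "MoCA > 26 without >= 2 impaired test scores"
  ids <- if ("subject_id" %in% names(cohort)) cohort$subject_id
         else as.character(seq_len(nrow(cohort)))
  out <- cohort[keep, , drop = FALSE]
  attr(out, "excluded") <- data.frame(subject_id = ids[!keep],
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE)
  attr(out, "moca_only") <- sum(keep & crit1 & !hasTests)
  out
}

#' Select healthy controls
#'
#' Retains subjects with MoCA >= 27 whose cognitive status was not
#' determined to be MCI (`mci_flag` FALSE).
#'
#' @param cohort data.frame with `moca` and `mci_flag` columns.
#' @return the retained rows, with an `"excluded"` attribute as in
#'   [selectPDMCI()].
#' @export
selectHealthyControls <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  miss <- setdiff(c("moca", "mci_flag"), names(cohort))
  if (length(miss))
    stop(sprintf("cohort lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  keep <- cohort$moca >= 27 & !cohort$mci_flag
  reason <- ifelse(cohort$moca < 27, "MoCA < 27",
                   ifelse(cohort$mci_flag, "MCI per site investigator", NA))
  ids <- if ("subject_id" %in% names(cohort)) cohort$subject_id
         else as.character(seq_len(nrow(cohort)))
  out <- cohort[keep, , drop = FALSE]
  attr(out, "excluded") <- data.frame(subject_id = ids[!keep],
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE)
  out
}

#' Pipeline configuration
#'
#' Bundles everything a full run needs. In synthetic mode (the default)
#' cohorts come from the generator under `simulation`; otherwise CSV
#' paths must be supplied. GMD is either ingested from the `ch4_gmd`
#' column (`gmd_source = "column"`) or extracted from per-subject NIfTI
#' volumes listed in a `gm_path` column against `mask_path`
#' (`gmd_source = "images"`).
#'
#' @param out_dir output directory for all stage outputs (created fresh;
#'   inputs are never mutated).
#' @param simulation a [SimulationConfig-class], or `NULL` when loading
#'   tables from disk.
#' @param hc_table,pd_table,visits_table CSV paths (ignored in synthetic
#'   mode).
#' @param gmd_source `"column"` or `"images"`.
#' @param mask_path probabilistic mask NIfTI path (required for
#'   `"images"`).
#' @param duration_bins subtype duration-bin edges, or `NULL` for
#'   cohort tertiles.
#' @param criteria a [milestoneCriteria()] list.
#' @param cox_covariates adjustment covariates for the Cox model, in
#'   addition to the low-Ch4 indicator.
#' @return a list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(out_dir,
                           simulation = simulationConfig(),
                           hc_table = NULL, pd_table = NULL,
                           visits_table = NULL,
                           gmd_source = c("column", "images"),
                           mask_path = NULL,
                           duration_bins = NULL,
                           criteria = milestoneCriteria(),
                           cox_covariates = c("age", "sex", "moca")) {
  gmd_source <- match.arg(gmd_source)
  structure(list(out_dir = out_dir, simulation = simulation,
                 hc_table = hc_table, pd_table = pd_table,
                 visits_table = visits_table, gmd_source = gmd_source,
                 mask_path = mask_path, duration_bins = duration_bins,
                 criteria = criteria, cox_covariates = cox_covariates),
            class = "PipelineConfig")
}

.validatePipelineConfig <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(config$simulation)) {
    for (p in c(config$hc_table, config$pd_table, config$visits_table))
      if (is.null(p) || !file.exists(p))
        stop(sprintf("input table missing or not found: %s",
                     if (is.null(p)) "(unset)" else p), call. = FALSE)
  } else {
    validObject(config$simulation)
  }
  if (config$gmd_source == "images" &&
      (is.null(config$mask_path) || !file.exists(config$mask_path)))
    stop(sprintf("mask file not found: %s",
                 if (is.null(config$mask_path)) "(unset)"
                 else config$mask_path), call. = FALSE)
  invisible(TRUE)
}

.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(config, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' Run the full Ch4 subtyping analysis
#'
#' Executes every stage in order — cohort selection, GMD
#' ingestion/extraction, healthy-control norming, z-scoring and
#' low/normal Ch4 classification, data-driven subtyping,
#' cognitive-milestone detection, Kaplan-Meier / log-rank /
#' covariate-adjusted Cox survival analysis, and group-comparison
#' statistics — writing each stage's output plus a run manifest (config
#' hash, package version, per-stage row counts, warnings) to
#' `config$out_dir`. A rerun with an identical config reproduces
#' identical outputs; any stage failure aborts with the stage named.
#'
#' @param config a [pipelineConfig()].
#' @return the manifest, invisibly; all outputs are on disk.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(tempfile("run"), simulationConfig(seed = 1))
#' man <- runFullPipeline(cfg)
#' man$stages
#' }
#' @export
runFullPipeline <- function(config) {
  .validatePipelineConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  warn <- character()
  note <- function(stage, n_in, n_out)
    stages[[stage]] <<- list(n_in = n_in, n_out = n_out)
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  # ingest ----------------------------------------------------------------
  if (!is.null(config$simulation)) {
    hcRaw <- generateHCCohort(config$simulation)
    sim <- generatePDMCICohort(config$simulation)
    pdRaw <- sim$cohort
    visits <- sim$visits
    jsonlite::write_json(sim$truth, file.path(config$out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    hcRaw <- utils::read.csv(config$hc_table)
    pdRaw <- utils::read.csv(config$pd_table)
    visits <- utils::read.csv(config$visits_table)
  }

  # selection -------------------------------------------------------------
  hc <- run("select_healthy_controls", selectHealthyControls(hcRaw))
  note("select_healthy_controls", nrow(hcRaw), nrow(hc))
  pd <- run("select_pd_mci", selectPDMCI(pdRaw))
  note("select_pd_mci", nrow(pdRaw), nrow(pd))
  mocaOnly <- attr(pd, "moca_only")

  # GMD -------------------------------------------------------------------
  if (config$gmd_source == "images") {
    mask <- readProbabilisticMask(config$mask_path)
    hc <- run("extract_gmd", extractCohortGMD(hc, mask))
    pd <- run("extract_gmd", extractCohortGMD(pd, mask))
  } else if (!"ch4_gmd" %in% names(pd)) {
    stop("pipeline stage 'extract_gmd' failed: no 'ch4_gmd' column and gmd_source is 'column'",
         call. = FALSE)
  }
  note("extract_gmd", nrow(hc) + nrow(pd), nrow(hc) + nrow(pd))

  # norming ---------------------------------------------------------------
  model <- run("fit_norming_model", fitNormingModel(hc))
  saveNormingModel(model, file.path(config$out_dir, "norming_model.json"))
  pdScored <- run("adjusted_z", adjustedZ(pd, model))
  utils::write.csv(pdScored, file.path(config$out_dir, "pd_scored.csv"),
                   row.names = FALSE)
  note("classify_ch4", nrow(pd), nrow(pdScored))
  groupN <- table(pdScored$ch4_group)

  # subtyping -------------------------------------------------------------
  thr <- run("compute_thresholds",
             computeSubtypeThresholds(pdScored, config$duration_bins))
  saveSubtypeThresholds(thr, file.path(config$out_dir,
                                       "subtype_thresholds.json"))
  pdSub <- run("assign_subtype", assignSubtype(pdScored, thr))
  utils::write.csv(pdSub, file.path(config$out_dir, "pd_subtyped.csv"),
                   row.names = FALSE)
  note("assign_subtype", nrow(pdScored), nrow(pdSub))

  # milestones ------------------------------------------------------------
  visits <- visits[visits$subject_id %in% pdSub$subject_id, , drop = FALSE]
  events <- run("detect_milestones",
                buildMilestoneEvents(visits, config$criteria))
  if (any(events$baseline_event)) {
    warn <- c(warn, sprintf("%d subject(s) met a milestone at baseline (kept, time 0)",
                            sum(events$baseline_event)))
  }
  events <- merge(events,
                  pdSub[c("subject_id", "ch4_group")], by = "subject_id")
  utils::write.csv(events, file.path(config$out_dir, "milestone_events.csv"),
                   row.names = FALSE)
  note("detect_milestones", nrow(pdSub), nrow(events))

  # survival --------------------------------------------------------------
  events$group <- events$ch4_group
  km <- run("km_estimate", lapply(split(events, events$group), kmEstimate))
  kmTab <- do.call(rbind, Map(cbind, group = names(km), km))
  utils::write.csv(kmTab, file.path(config$out_dir, "km_curves.csv"),
                   row.names = FALSE)
  lr <- run("logrank_test", logrankTest(events))
  covars <- pdSub[c("subject_id", "age", "sex", "moca")]
  covars$low_ch4 <- as.integer(pdSub$ch4_group == "low")
  cox <- run("cox_fit",
             coxMilestones(events, covars,
                           formula_rhs = c("low_ch4",
                                           config$cox_covariates)))
  survOut <- list(logrank = lr, cox = cox)
  jsonlite::write_json(survOut, file.path(config$out_dir, "survival.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  note("survival", nrow(events), nrow(events))

  # group statistics ------------------------------------------------------
  stats_tab <- run("group_stats", compareGroups(
    pdSub, group_col = "ch4_group",
    continuous = intersect(c("age", "updrs1", "updrs2", "updrs3",
                             "scopa_aut", "rbdsq", "upsit", "moca"),
                           names(pdSub)),
    items = intersect(c("updrs_1_1", "updrs_1_2", "updrs_1_5"),
                      names(pdSub))))
  utils::write.csv(stats_tab, file.path(config$out_dir, "group_stats.csv"),
                   row.names = FALSE)
  note("group_stats", nrow(pdSub), nrow(stats_tab))

  manifest <- list(
    config_hash = .configHash(config),
    package_version = as.character(utils::packageVersion("ch4norm")),
    seed = if (!is.null(config$simulation)) config$simulation@seed else NA,
    gmd_source = config$gmd_source,
    n_hc_in = nrow(hcRaw), n_hc = nrow(hc),
    n_pd_in = nrow(pdRaw), n_pd = nrow(pd),
    n_moca_only = mocaOnly,
    ch4_groups = as.list(groupN),
    stages = stages,
    warnings = warn)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
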