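#' @include AllClasses.R
NULL

#' Cognitive milestone criteria
#'
#' The six cognitive progression milestones: MoCA below a cutoff
#' (default 21); MDS-UPDRS Part I item 1.1 (cognitive impairment),
#' item 1.2 (hallucinations) or item 1.5 (apathy) at or above a response
#' cutoff (default 3); a clinical dementia diagnosis flag; and a
#' composite dementia categorization flag (impairment on >= 2 cognitive
#' domains with functional impairment, supplied as a precomputed boolean
#' column since the per-domain thresholds are assessor-dependent).
#'
#' @param moca_cutoff milestone if MoCA < cutoff (0-30).
#' @param updrs_1_1_cutoff,updrs_1_2_cutoff,updrs_1_5_cutoff milestone
#'   if the item response is >= the cutoff (items range 0-4).
#' @return a list of class `"MilestoneCriteria"`.
#' @export
milestoneCriteria <- function(moca_cutoff = 21, updrs_1_1_cutoff = 3,
                              updrs_1_2_cutoff = 3, updrs_1_5_cutoff = 3) {
  stopifnot(moca_cutoff >= 0, moca_cutoff <= 30,
            updrs_1_1_cutoff >= 0, updrs_1_1_cutoff <= 4,
            updrs_1_2_cutoff >= 0, updrs_1_2_cutoff <= 4,
            updrs_1_5_cutoff >= 0, updrs_1_5_cutoff <= 4)
  structure(list(moca_cutoff = moca_cutoff,
                 updrs_1_1_cutoff = updrs_1_1_cutoff,
                 updrs_1_2_cutoff = updrs_1_2_cutoff,
                 updrs_1_5_cutoff = updrs_1_5_cutoff),
            class = "MilestoneCriteria")
}

.milestoneFlags <- function(visits, criteria) {
  cbind(moca_lt_cutoff = visits$moca < criteria$moca_cutoff,
        updrs_1_1 = visits$updrs_1_1 >= criteria$updrs_1_1_cutoff,
        hallucinations = visits$updrs_1_2 >= criteria$updrs_1_2_cutoff,
        apathy = visits$updrs_1_5 >= criteria$updrs_1_5_cutoff,
        dementia_clinical = as.logical(visits$dementia_clinical),
        dementia_composite = as.logical(visits$dementia_composite))
}

#' Detect the first cognitive milestone for one subject
#'
#' Scans the subject's visits in time order and returns the earliest
#' visit month at which any of the six criteria holds (a single
#' qualifying visit triggers the event; persistence is not required, and
#' the baseline visit counts — a subject qualifying at baseline gets
#' time 0 with `baseline_event = TRUE` rather than being dropped). If no
#' visit qualifies the subject is censored at the last visit month.
#'
#' @param visits data.frame of one subject's visits, sorted by
#'   `visit_month`, with columns `visit_month`, `moca`, `updrs_1_1`,
#'   `updrs_1_2`, `updrs_1_5`, `dementia_clinical`, `dementia_composite`.
#' @param criteria a [milestoneCriteria()] list.
#' @return one-row data.frame: `time` (months), `event` (logical),
#'   `first_milestone_type` (one of the six labels or `"none"`),
#'   `baseline_event`.
#' @export
detectMilestones <- function(visits, criteria = milestoneCriteria()) {
  stopifnot(is.data.frame(visits))
  if (nrow(visits) == 0L)
    stop("empty visit record: at least the baseline visit is required",
         call. = FALSE)
  if (is.unsorted(visits$visit_month, strictly = TRUE))
    stop("visit times must be strictly increasing", call. = FALSE)
  flags <- .milestoneFlags(visits, criteria)
  hit <- which(rowSums(flags, na.rm = TRUE) > 0)
  if (length(hit)) {
    i <- hit[1L]
    type <- colnames(flags)[which(flags[i, ])[1L]]  # documented tie order
    data.frame(time = visits$visit_month[i], event = TRUE,
               first_milestone_type = type,
               baseline_event = visits$visit_month[i] == visits$visit_month[1L],
               stringsAsFactors = FALSE)
  } else {
    data.frame(time = visits$visit_month[nrow(visits)], event = FALSE,
               first_milestone_type = "none", baseline_event = FALSE,
               stringsAsFactors = FALSE)
  }
}

#' Build time-to-first-milestone events for a whole cohort
#'
#' Vectorized equivalent of applying [detectMilestones()] per subject on
#' a long-format visit table.
#'
#' @param visits long-format data.frame with `subject_id` plus the
#'   columns required by [detectMilestones()].
#' @param criteria a [milestoneCriteria()] list.
#' @return data.frame with one row per subject: `subject_id`, `time`,
#'   `event`, `first_milestone_type`, `baseline_event`.
#' @export
buildMilestoneEvents <- function(visits, criteria = milestoneCriteria()) {
  stopifnot(is.data.frame(visits), "subject_id" %in% names(visits))
  if (nrow(visits) == 0L) stop("empty visit table", call. = FALSE)
  ord <- order(visits$subject_id, visits$visit_month)
  v <- visits[ord, ]
  dup <- duplicated(v[c("subject_id", "visit_month")])
  if (any(dup))
    stop("non-monotone visit times: duplicated visit_month within subject",
         call. = FALSE)
  flags <- .milestoneFlags(v, criteria)
  any_hit <- rowSums(flags, na.rm = TRUE) > 0
  idx <- seq_len(nrow(v))
  firstHit <- tapply(ifelse(any_hit, idx, NA_integer_), v$subject_id,
                     function(i) if (all(is.na(i))) NA_integer_
                                 else min(i, na.rm = TRUE))
  lastIdx <- tapply(idx, v$subject_id, max)
  subj <- names(lastIdx)
  event <- !is.na(firstHit)
  row <- ifelse(event, firstHit, lastIdx)
  firstRow <- tapply(idx, v$subject_id, min)
  type <- rep("none", length(subj))
  if (any(event)) {
    hitRows <- flags[firstHit[event], , drop = FALSE]
    type[event] <- colnames(flags)[apply(hitRows, 1, function(f)
      which(f)[1L])]
  }
  data.frame(subject_id = subj,
             time = v$visit_month[row],
             event = event,
             first_milestone_type = type,
             baseline_event = event &
               v$visit_month[row] == v$visit_month[firstRow],
             row.names = NULL, stringsAsFactors = FALSE)
}

.checkEvents <- function(events) {
  stopifnot(is.data.frame(events), all(c("time", "event") %in% names(events)))
  if (nrow(events) == 0L) stop("no event records", call. = FALSE)
  if (any(events$time < 0)) stop("negative event times", call. = FALSE)
  invisible(TRUE)
}

#' Kaplan-Meier curve for milestone events
#'
#' Product-limit estimate of the probability of remaining milestone-free,
#' via [survival::survfit()]. With no censoring this equals the
#' empirical survival function.
#'
#' @param events data.frame with `time` (months) and `event` (logical or
#'   0/1) columns, e.g. from [buildMilestoneEvents()].
#' @return data.frame step function: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @export
kmEstimate <- function(events) {
  .checkEvents(events)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = events)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Log-rank test between two milestone groups
#'
#' Standard (unweighted) log-rank test, 1 degree of freedom, via
#' [survival::survdiff()].
#'
#' @param events data.frame with `time`, `event` and a `group` column
#'   with exactly two levels.
#' @return list with `chi2`, `df`, `p_value`, `method`.
#' @export
logrankTest <- function(events) {
  .checkEvents(events)
  if (!"group" %in% names(events))
    stop("'events' must have a 'group' column", call. = FALSE)
  counts <- table(events$group)
  if (length(counts) != 2L || any(counts == 0L))
    stop(sprintf("log-rank needs two non-empty groups; got sizes: %s",
                 paste(sprintf("%s=%d", names(counts), counts),
                       collapse = ", ")), call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = events)
  chi2 <- sd$chisq
  list(chi2 = chi2, df = 1L,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       method = "log-rank (1 df)")
}

#' Covariate-adjusted Cox model for time to cognitive milestones
#'
#' Multivariable Cox proportional-hazards regression of time to first
#' cognitive milestone on a primary group indicator plus adjustment
#' covariates (by default baseline age, sex and MoCA), via
#' [survival::coxph()]. Ties — guaranteed by the 6-month visit grid —
#' are handled with the Efron approximation by default.
#'
#' @param events data.frame with `subject_id`, `time`, `event`.
#' @param covariates data.frame with `subject_id` and the model columns.
#' @param formula_rhs character vector of covariate column names; the
#'   first is conventionally the exposure of interest.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return list with `ties`, `n`, `n_event`, and per-covariate rows in
#'   data.frame `coefficients`: `term`, `coef`, `hr`, `ci_low`,
#'   `ci_high`, `se`, `p_value` (95% Wald intervals).
#' @export
coxMilestones <- function(events, covariates,
                          formula_rhs = c("low_ch4", "age", "sex", "moca"),
                          ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .checkEvents(events)
  stopifnot(is.data.frame(covariates),
            "subject_id" %in% names(covariates))
  miss <- setdiff(formula_rhs, names(covariates))
  if (length(miss))
    stop(sprintf("covariate table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  dat <- merge(events[c("subject_id", "time", "event")], covariates,
               by = "subject_id")
  if (anyNA(dat[formula_rhs]))
    stop("covariates must be complete for all subjects with events data",
         call. = FALSE)
  if (sum(dat$event) < 2L)
    stop("need at least 2 events to fit a Cox model", call. = FALSE)
  degenerate <- formula_rhs[vapply(dat[formula_rhs],
                                   function(x) length(unique(x)) < 2L,
                                   logical(1))]
  if (length(degenerate))
    stop(sprintf("covariate(s) constant across subjects, coefficient unidentifiable: %s",
                 paste(degenerate, collapse = ", ")), call. = FALSE)
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(formula_rhs, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(f, data = dat, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        stop(sprintf("Cox fit did not converge cleanly (%s); possible complete separation",
                     conditionMessage(w)), call. = FALSE)
      suppressWarnings(survival::coxph(f, data = dat, ties = ties))
    })
  s <- summary(fit)
  co <- s$coefficients
  data.frame0 <- data.frame(
    term = rownames(co),
    coef = co[, "coef"],
    hr = exp(co[, "coef"]),
    ci_low = exp(co[, "coef"] - stats::qnorm(0.975) * co[, "se(coef)"]),
    ci_high = exp(co[, "coef"] + stats::qnorm(0.975) * co[, "se(coef)"]),
    se = co[, "se(coef)"],
    p_value = co[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  list(ties = ties, n = s$n, n_event = s$nevent,
       coefficients = data.frame0)
}
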