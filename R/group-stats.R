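#' @include AllClasses.R
NULL

#' Binarize an ordinal symptom item
#'
#' A symptom is counted as present if the subject scores 1 or more on
#' the item (MDS-UPDRS items range 0-4).
#'
#' @param item_score numeric score(s) in 0-4.
#' @return logical, `TRUE` iff score >= 1.
#' @examples
#' binarizeSymptom(c(0, 1, 4))
#' @export
binarizeSymptom <- function(item_score) {
  if (anyNA(item_score) || any(item_score < 0 | item_score > 4))
    stop("item scores must lie in 0-4", call. = FALSE)
  item_score >= 1
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction, no
#' small-count fallback), `chi2 = sum (O - E)^2 / E` with expected
#' counts from the margins, 1 degree of freedom. Fisher's exact test is
#' available behind `method = "fisher"` as an explicit alternative.
#'
#' @param a,b counts of symptom-present subjects in groups 1 and 2.
#' @param n1,n2 group sizes.
#' @param method `"pearson"` (default) or `"fisher"`.
#' @return list with `statistic`, `df`, `p_value`, `method`, `table`.
#' @examples
#' pearsonChi2(15, 116, 9, 32)$p_value  # ~0.039
#' @export
pearsonChi2 <- function(a, n1, b, n2, method = c("pearson", "fisher")) {
  method <- match.arg(method)
  counts <- c(a, n1 - a, b, n2 - b)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers with a <= n1, b <= n2",
         call. = FALSE)
  tab <- matrix(counts, nrow = 2, byrow = TRUE,
                dimnames = list(group = c("group1", "group2"),
                                symptom = c("present", "absent")))
  if (sum(tab) == 0) stop("empty table", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square statistic undefined: a table margin is zero",
         call. = FALSE)
  if (method == "fisher") {
    ft <- stats::fisher.test(tab)
    return(list(statistic = NA_real_, df = NA_integer_,
                p_value = ft$p.value, method = "Fisher exact", table = tab))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, method = "Pearson chi-square (uncorrected)",
       table = tab)
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H statistic with tie correction and chi-square p-value
#' (df = k - 1), via [stats::kruskal.test()]. Used for all continuous
#' group comparisons, including two-group ones.
#'
#' @param ... two or more numeric vectors, one per group (or a single
#'   list of them).
#' @return list with `statistic`, `df`, `p_value`, `method`.
#' @examples
#' kruskalWallis(c(1, 2, 3), c(4, 5, 6))$statistic  # 3.857
#' @export
kruskalWallis <- function(...) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1L]])) groups <- groups[[1L]]
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 1L))
    stop("each group needs at least one observation", call. = FALSE)
  pooled <- unlist(groups)
  if (length(pooled) < 3L) stop("need at least 3 observations in total",
                                call. = FALSE)
  if (length(unique(pooled)) == 1L)
    stop("all values identical: rank statistic degenerate", call. = FALSE)
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, method = "Kruskal-Wallis rank sum test")
}

#' Median and interquartile range
#'
#' @param values numeric vector, n >= 1.
#' @return named numeric: `median`, `q1`, `q3` (25th/75th percentiles,
#'   linear interpolation, R type 7).
#' @examples
#' medianIQR(1:5)  # 3, 2, 4
#' @export
medianIQR <- function(values) {
  if (length(values) < 1L || anyNA(values))
    stop("need at least one non-missing value", call. = FALSE)
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Power of the two-sample t-test
#'
#' Exact power under the noncentral t distribution: with standardized
#' mean difference `d`, the noncentrality is `d / sqrt(1/n1 + 1/n2)` on
#' `n1 + n2 - 2` degrees of freedom, and power is the probability that
#' |T| exceeds the two-sided critical value.
#'
#' @param n1,n2 group sizes (each >= 2).
#' @param d standardized mean difference (Cohen's d).
#' @param alpha two-sided significance level in (0, 1).
#' @return power, a proportion in [0, 1].
#' @examples
#' twoSamplePower(116, 32, 0.56)  # ~0.80
#' @export
twoSamplePower <- function(n1, n2, d, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  df <- n1 + n2 - 2
  ncp <- d / sqrt(1 / n1 + 1 / n2)
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp) + stats::pt(tc, df, ncp, lower.tail = FALSE)
}

#' Group-comparison report for a cohort table
#'
#' Describes each continuous variable as median (IQR) per group with a
#' Kruskal-Wallis p-value, and each 0-4 symptom item as percent present
#' (score >= 1) per group with an uncorrected Pearson chi-square
#' p-value — the format of a clinical baseline-characteristics table.
#' P-values are carried at full precision; `digits` only affects the
#' rendered columns. No multiplicity correction is applied.
#'
#' @param tab cohort data.frame.
#' @param group_col name of a two-level grouping column (e.g.
#'   `ch4_group`).
#' @param continuous character vector of continuous column names.
#' @param items character vector of 0-4 item column names to binarize.
#' @param digits rounding for the rendered columns.
#' @return data.frame with one row per variable: group summaries,
#'   `p_value`, `method`.
#' @export
compareGroups <- function(tab, group_col = "ch4_group",
                          continuous = character(), items = character(),
                          digits = 2) {
  stopifnot(is.data.frame(tab), group_col %in% names(tab))
  g <- factor(tab[[group_col]])
  if (nlevels(g) != 2L)
    stop(sprintf("'%s' must have exactly two levels", group_col),
         call. = FALSE)
  lv <- levels(g)
  rows <- list()
  for (v in continuous) {
    x1 <- tab[[v]][g == lv[1]]; x2 <- tab[[v]][g == lv[2]]
    kw <- kruskalWallis(x1, x2)
    fmt <- function(x) {
      m <- medianIQR(x)
      sprintf("%.*f (%.*f-%.*f)", digits, m["median"], digits, m["q1"],
              digits, m["q3"])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, group1 = fmt(x1), group2 = fmt(x2),
      p_value = kw$p_value, method = kw$method,
      stringsAsFactors = FALSE)
  }
  for (v in items) {
    p1 <- binarizeSymptom(tab[[v]][g == lv[1]])
    p2 <- binarizeSymptom(tab[[v]][g == lv[2]])
    ct <- pearsonChi2(sum(p1), length(p1), sum(p2), length(p2))
    fmt <- function(p) sprintf("%.1f%% (%d/%d)", 100 * mean(p), sum(p),
                               length(p))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, group1 = fmt(p1), group2 = fmt(p2),
      p_value = ct$p_value, method = ct$method,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "groups") <- stats::setNames(as.integer(table(g)), lv)
  out
}
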