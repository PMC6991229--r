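#' Detection-rate tables
#'
#' A detection table holds, per ordered group, the number of men and the
#' number diagnosed (with prostate cancer, or with high-grade disease for
#' the high-grade analysis) during follow-up.
#'
#' @param groups Character vector of group labels, in display/trend order.
#' @param totals Integer vector of group sizes.
#' @param events Integer vector of diagnosed counts per group.
#' @return A data frame of class `detection_table`.
#' @export
detection_table <- function(groups, totals, events) {
  if (length(groups) != length(totals) || length(totals) != length(events))
    stop("groups, totals and events must have equal length")
  if (any(totals <= 0)) stop("group totals must be positive")
  if (any(events < 0) || any(events > totals))
    stop("events must lie in [0, total] per group")
  structure(data.frame(group = as.character(groups), total = as.integer(totals),
                       events = as.integer(events), stringsAsFactors = FALSE),
            class = c("detection_table", "data.frame"))
}

#' Per-group detection rates
#'
#' Adds the detection rate (events / total) for each group, at full
#' precision, plus the integer percentage used for display.
#'
#' @param table A [detection_table()].
#' @return The table with `rate` and `pct` (rounded integer percent) columns.
#' @examples
#' t <- detection_table(c("low", "high"), c(683, 605), c(95, 193))
#' detection_rates(t)$pct  # 14, 32
#' @export
detection_rates <- function(table) {
  stopifnot(inherits(table, "detection_table"))
  table$rate <- table$events / table$total
  table$pct <- as.integer(round(100 * table$rate))
  table
}

#' Pearson chi-square test on a detection table
#'
#' Tests homogeneity of the event rate across groups with the uncorrected
#' Pearson statistic on the groups x (event, no event) contingency table.
#' No continuity correction is applied (so a 2x2 statistic equals the
#' squared two-proportion z statistic).
#'
#' @param table A [detection_table()] with all totals positive.
#' @return A list with `statistic`, `df`, and `p.value`.
#' @examples
#' fh <- detection_table(c("FH+", "FH-"), c(436, 2789), c(116, 598))
#' pearson_chi2(fh)$statistic  # 5.83
#' @export
pearson_chi2 <- function(table) {
  stopifnot(inherits(table, "detection_table"))
  m <- cbind(events = table$events, nonevents = table$total - table$events)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0))
    stop("chi-square test undefined: an expected cell count is zero")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value)
}

#' Cochran-Armitage trend test
#'
#' One-degree-of-freedom chi-square test for a monotone trend in the event
#' rate across ordered groups, using numeric group scores. The statistic is
#' `(T - E[T])^2 / Var(T)` with `T` the score-weighted event count, `E` and
#' `Var` taken under the null of a common rate; it is invariant under affine
#' transformations of the scores.
#'
#' @param table A [detection_table()] with at least two groups, in trend order.
#' @param scores Numeric scores for the ordered groups; default equally
#'   spaced `0, 1, 2, ...`.
#' @return A list with `statistic`, `df` (= 1), and `p.value`.
#' @examples
#' hg <- detection_table(c("low", "average", "high"),
#'                       c(683, 1937, 605), c(34, 143, 60))
#' cochran_armitage_trend(hg)$statistic  # 11.5
#' @export
cochran_armitage_trend <- function(table, scores = NULL) {
  stopifnot(inherits(table, "detection_table"))
  k <- nrow(table)
  if (k < 2L) stop("trend test needs at least two ordered groups")
  if (is.null(scores)) scores <- seq_len(k) - 1
  if (length(scores) != k) stop("scores must match the number of groups")
  if (length(unique(scores)) == 1L) stop("scores must not be constant")
  tt <- suppressWarnings(
    stats::prop.trend.test(table$events, table$total, score = scores))
  list(statistic = unname(tt$statistic), df = 1L, p.value = tt$p.value)
}

#' One-way analysis of variance across groups
#'
#' Standard fixed-effects one-way ANOVA F test for a difference in means of
#' a quantitative variable among groups.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`.
#' @return A list with `statistic` (F), `df1`, `df2`, and `p.value`.
#' @export
anova_oneway <- function(values, groups) {
  if (length(values) != length(groups)) stop("values and groups lengths differ")
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 1L)) stop("every group needs at least one observation")
  fit <- stats::anova(stats::lm(values ~ groups))
  list(statistic = fit[["F value"]][1L],
       df1 = fit[["Df"]][1L], df2 = fit[["Df"]][2L],
       p.value = fit[["Pr(>F)"]][1L])
}
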