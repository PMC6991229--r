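# shared machinery: per-event-age observed/expected/covariance with
# delayed-entry risk sets
logrank_tables <- function(records, group) {
  group <- factor(group)
  keep_levels <- levels(group)
  times <- sort(unique(records$exit_age[records$event == 1L]))
  if (length(times) == 0L) stop("log-rank requires at least one event")
  k <- length(keep_levels)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  seen <- logical(k)
  for (t in times) {
    at_risk <- records$entry_age < t & records$exit_age >= t
    n <- sum(at_risk)
    if (n == 0L) next
    ng <- vapply(keep_levels, function(g) sum(at_risk & group == g), numeric(1L))
    seen <- seen | ng > 0
    ev <- records$event == 1L & records$exit_age == t
    d <- sum(ev)
    dg <- vapply(keep_levels, function(g) sum(ev & group == g), numeric(1L))
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1L) {
      p <- ng / n
      V <- V + d * (n - d) / (n - 1) * (diag(p, nrow = k) - tcrossprod(p))
    }
  }
  if (any(!seen))
    warning("group(s) with empty risk set throughout excluded: ",
            paste(keep_levels[!seen], collapse = ", "))
  list(levels = keep_levels[seen], O = O[seen], E = E[seen],
       V = V[seen, seen, drop = FALSE])
}

#' Log-rank test with delayed entry
#'
#' Compares diagnosis-free survival among groups on the age scale, with
#' risk sets honouring left truncation (a record is at risk at age `t` only
#' if `entry_age < t <= exit_age`). At each distinct event age the observed
#' and expected event counts per group are accumulated together with the
#' hypergeometric covariance; the statistic is the quadratic form of
#' `O - E` on any `k - 1` groups, with `k - 1` degrees of freedom.
#'
#' @param records A `survival_records` data frame.
#' @param group Group label per record.
#' @return A list with `statistic`, `df`, `p.value`, and the per-group
#'   `observed` and `expected` event counts.
#' @export
logrank <- function(records, group) {
  stopifnot(inherits(records, "survival_records"))
  if (length(group) != nrow(records))
    stop("group must have one label per record")
  lt <- logrank_tables(records, group)
  k <- length(lt$levels)
  if (k < 2L) stop("log-rank requires at least two non-empty groups")
  idx <- seq_len(k - 1L)
  u <- (lt$O - lt$E)[idx]
  Vi <- lt$V[idx, idx, drop = FALSE]
  stat <- tryCatch(drop(t(u) %*% solve(Vi, u)),
                   error = function(e) {
                     drop(t(u) %*% MASS_ginv(Vi) %*% u)
                   })
  df <- k - 1L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       observed = stats::setNames(lt$O, lt$levels),
       expected = stats::setNames(lt$E, lt$levels))
}

# Moore-Penrose pseudoinverse via SVD (fallback for singular covariance)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1L], 0)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Trend log-rank test across ordered groups
#'
#' One-degree-of-freedom log-rank test for a dose-response ordering of
#' survival across groups: `U = sum_g s_g (O_g - E_g)` with numeric group
#' scores `s`, and `chi2 = U^2 / (s' V s)` with `V` the log-rank covariance.
#' With two groups and scores 0, 1 this reduces to the ordinary two-group
#' log-rank statistic.
#'
#' @param records A `survival_records` data frame.
#' @param group Ordered group label per record; trend order follows factor
#'   levels (or sort order for character input).
#' @param scores Numeric scores for the ordered groups; default equally
#'   spaced `0, 1, 2, ...`.
#' @return A list with `statistic`, `df` (= 1), `p.value`, and the signed
#'   trend contrast `U`.
#' @export
logrank_trend <- function(records, group, scores = NULL) {
  stopifnot(inherits(records, "survival_records"))
  if (length(group) != nrow(records))
    stop("group must have one label per record")
  lt <- logrank_tables(records, group)
  k <- length(lt$levels)
  if (k < 2L) stop("trend test requires at least two non-empty groups")
  if (is.null(scores)) scores <- seq_len(k) - 1
  if (length(scores) != k)
    stop("scores must match the number of non-empty groups (", k, ")")
  if (length(unique(scores)) == 1L) stop("scores must not be constant")
  U <- sum(scores * (lt$O - lt$E))
  v <- drop(t(scores) %*% lt$V %*% scores)
  if (v <= 0) stop("degenerate trend variance")
  stat <- U^2 / v
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, 1L, lower.tail = FALSE),
       U = U)
}
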