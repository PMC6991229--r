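#' Left-truncated Kaplan-Meier estimate on the age scale
#'
#' Product-limit estimate of diagnosis-free survival with delayed entry.
#' At each distinct event age `t_j` the risk set is
#' `n_j = #{i : entry_age_i < t_j <= exit_age_i}` and the estimate is
#' `S(t) = prod_{t_j <= t} (1 - d_j / n_j)`. Variance is Greenwood's
#' formula; confidence intervals are computed on the complementary
#' log-log scale (`log(-log S)`), which keeps the bounds inside \[0, 1\].
#'
#' With delayed entry the estimate is interpretable only at ages where the
#' risk set has been non-empty; `S` is 1 before the first event age.
#'
#' @param records A `survival_records` data frame (see [survival_records()]).
#' @param conf_level Two-sided confidence level, default 0.95.
#' @return An object of class `km_curve`: a data frame with one row per
#'   distinct event age — `time`, `n_risk`, `n_event`, `survival`, `se`
#'   (Greenwood), `ci_low`, `ci_high` — plus attributes `n` (records) and
#'   `conf_level`.
#' @examples
#' r <- survival_records(c(0, 0, 0), c(5, 8, 10), c(1, 0, 1))
#' km_left_truncated(r)
#' @export
km_left_truncated <- function(records, conf_level = 0.95) {
  stopifnot(inherits(records, "survival_records"))
  if (nrow(records) == 0L) stop("no records")
  event_times <- sort(unique(records$exit_age[records$event == 1L]))
  if (length(event_times) == 0L) {
    warning("no events: survival curve is identically 1")
    curve <- data.frame(time = numeric(0), n_risk = numeric(0),
                        n_event = numeric(0), survival = numeric(0),
                        se = numeric(0), ci_low = numeric(0),
                        ci_high = numeric(0))
    return(structure(curve, class = c("km_curve", "data.frame"),
                     n = nrow(records), conf_level = conf_level))
  }
  n_risk <- risk_set_sizes(records, event_times)
  n_event <- vapply(event_times, function(t) {
    sum(records$exit_age == t & records$event == 1L)
  }, numeric(1L))
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood: Var(S) = S^2 * cumsum(d / (n (n - d)))
  gw <- cumsum(ifelse(n_risk > n_event,
                      n_event / (n_risk * (n_risk - n_event)), Inf))
  se <- surv * sqrt(gw)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  # cloglog CI: S^exp(+-z * se(log(-log S)))
  with_s <- surv > 0 & surv < 1
  ci_low <- ci_high <- rep(NA_real_, length(surv))
  if (any(with_s)) {
    se_cll <- sqrt(gw[with_s]) / abs(log(surv[with_s]))
    ci_low[with_s] <- surv[with_s]^exp(z * se_cll)
    ci_high[with_s] <- surv[with_s]^exp(-z * se_cll)
  }
  ci_low[surv == 0] <- 0
  ci_high[surv == 0] <- 0
  se[!is.finite(se)] <- NA_real_
  curve <- data.frame(time = event_times, n_risk = n_risk, n_event = n_event,
                      survival = surv, se = se,
                      ci_low = ci_low, ci_high = ci_high)
  structure(curve, class = c("km_curve", "data.frame"),
            n = nrow(records), conf_level = conf_level)
}

#' Evaluate a Kaplan-Meier curve at an age
#'
#' Step-function lookup: the estimate is right-continuous, so the value at
#' an event age is the post-jump value, and the value between jumps is the
#' value at the last event age not exceeding `age`.
#'
#' @param curve A `km_curve` object.
#' @param age Age (years) at which to evaluate.
#' @return A list with `estimate`, `ci_low`, `ci_high`.
#' @export
survival_at <- function(curve, age) {
  stopifnot(inherits(curve, "km_curve"))
  if (nrow(curve) == 0L || age < curve$time[1L]) {
    if (nrow(curve) > 0L && age < curve$time[1L])
      warning("age precedes the first event age; survival is 1 by convention")
    return(list(estimate = 1, ci_low = 1, ci_high = 1))
  }
  i <- findInterval(age, curve$time)
  list(estimate = curve$survival[i], ci_low = curve$ci_low[i],
       ci_high = curve$ci_high[i])
}

#' Median diagnosis-free survival age
#'
#' The median is the smallest event age at which the survival estimate
#' drops to 0.5 or below. Screening cohorts followed for a few years rarely
#' observe the median: when `S` never reaches 0.5 within the observed (or
#' capped) range, the sentinel `">cap"` is reported, mirroring how such
#' tables print "more than 80 years". Confidence bounds are located where
#' the confidence envelope for `S` crosses 0.5 (lower bound from the lower
#' band, upper bound from the upper band), with the same sentinel rule.
#'
#' @param curve A `km_curve` object.
#' @param cap Reporting cap in years (default 80).
#' @return A list with numeric `estimate`, `ci_low`, `ci_high` (each `Inf`
#'   when beyond the cap) and their display strings `label`, `ci_label`
#'   using the `">cap"` sentinel.
#' @export
median_survival <- function(curve, cap = 80) {
  stopifnot(inherits(curve, "km_curve"))
  cross <- function(values) {
    hit <- which(!is.na(values) & values <= 0.5 & curve$time <= cap)
    if (length(hit) == 0L) Inf else curve$time[hit[1L]]
  }
  est <- cross(curve$survival)
  lo <- cross(curve$ci_low)
  hi <- cross(curve$ci_high)
  fmt <- function(x) if (is.infinite(x)) paste0(">", cap) else format(x)
  list(estimate = est, ci_low = lo, ci_high = hi,
       label = fmt(est),
       ci_label = paste0("(", fmt(lo), " to ", fmt(hi), ")"))
}

#' Write a Kaplan-Meier curve to a TSV file
#'
#' Exports the step-function data (age, numbers at risk, estimates,
#' standard errors and confidence bounds) for external plotting.
#'
#' @param curve A `km_curve` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  out <- as.data.frame(curve)
  names(out)[names(out) == "time"] <- "age"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
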