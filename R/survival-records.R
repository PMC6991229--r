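#' Delayed-entry survival records
#'
#' Builds the record set used by every survival routine in the package.
#' Follow-up is on the age axis: a man enters observation at his enrollment
#' age already free of disease (left truncation), and exits at his age at
#' diagnosis (event) or censoring. At any age `t` the risk set contains the
#' records with `entry_age < t <= exit_age`: a subject contributes
#' person-time only after his entry, which is what removes the survivorship
#' bias of age-scale analysis in a cohort that excluded prevalent cases.
#'
#' @param entry_age Numeric vector of enrollment ages (years).
#' @param exit_age Numeric vector of event/censoring ages (years); must be
#'   strictly greater than `entry_age`.
#' @param event Logical or 0/1 vector: 1 if `exit_age` is a diagnosis age.
#' @param sample_id Optional character IDs; defaults to `S1, S2, ...`.
#' @param covariates Optional data frame of per-record covariates (e.g.
#'   continuous GRS, family-history indicator), carried along for [cox_fit()].
#' @return A data frame of class `survival_records` with columns
#'   `sample_id`, `entry_age`, `exit_age`, `event`, plus any covariates.
#' @export
survival_records <- function(entry_age, exit_age, event, sample_id = NULL,
                             covariates = NULL) {
  n <- length(entry_age)
  if (length(exit_age) != n || length(event) != n)
    stop("entry_age, exit_age and event must have equal length")
  if (n == 0L) stop("no records supplied")
  if (any(!is.finite(entry_age)) || any(!is.finite(exit_age)))
    stop("ages must be finite")
  if (is.logical(event)) event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1 or logical")
  bad <- which(entry_age >= exit_age)
  if (length(bad) > 0L)
    stop("entry_age must be strictly less than exit_age; offending record(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (is.null(sample_id)) sample_id <- sprintf("S%d", seq_len(n))
  out <- data.frame(sample_id = as.character(sample_id),
                    entry_age = as.numeric(entry_age),
                    exit_age = as.numeric(exit_age),
                    event = as.integer(event),
                    stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per record")
    out <- cbind(out, covariates)
  }
  class(out) <- c("survival_records", "data.frame")
  out
}

#' Convert a phenotype table into survival records
#'
#' @param phenotypes Data frame with columns `sample_id`, `entry_age`,
#'   `exit_age`, `event` and optionally `high_grade`, `fh`, `grs` and others
#'   (as written by [simulate_cohort()] or read with [read_phenotypes()]).
#' @param outcome `"all"` analyses any prostate-cancer diagnosis as the
#'   event; `"high_grade"` counts only high-grade diagnoses as events
#'   (low-grade diagnoses become censorings at the diagnosis age).
#' @return A `survival_records` data frame carrying the remaining phenotype
#'   columns as covariates.
#' @export
as_survival_records <- function(phenotypes, outcome = c("all", "high_grade")) {
  outcome <- match.arg(outcome)
  need <- c("sample_id", "entry_age", "exit_age", "event")
  missing_cols <- setdiff(need, names(phenotypes))
  if (length(missing_cols) > 0L)
    stop("phenotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  event <- phenotypes$event
  if (outcome == "high_grade") {
    if (!"high_grade" %in% names(phenotypes))
      stop("high-grade analysis requires a high_grade column")
    hg <- phenotypes$high_grade
    hg[is.na(hg)] <- 0L
    event <- as.integer(phenotypes$event == 1L & hg == 1L)
  }
  covs <- phenotypes[, setdiff(names(phenotypes), need), drop = FALSE]
  survival_records(phenotypes$entry_age, phenotypes$exit_age, event,
                   sample_id = phenotypes$sample_id,
                   covariates = if (ncol(covs)) covs else NULL)
}

# number at risk at each age in `times`: entry < t <= exit
risk_set_sizes <- function(records, times) {
  vapply(times, function(t) {
    sum(records$entry_age < t & records$exit_age >= t)
  }, numeric(1L))
}
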