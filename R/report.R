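#' Run the full stratified risk report for a cohort
#'
#' Produces the package's standard analysis of a phenotype table with GRS
#' and group assignments: a detection-rate table (GRS groups, family
#' history, and the combined genetic-risk groups, each for all and for
#' high-grade cancer) with chi-square / trend statistics, a survival table
#' (cumulative diagnosis-free probability by a reference age and the
#' median age with a `">80"`-style sentinel), exported Kaplan-Meier step
#' functions per group, and a JSON file gathering every test statistic.
#' All files carry a `#`-comment metadata header with package version and
#' seed.
#'
#' @param phenotypes Phenotype data frame with `grs_group`,
#'   `genetic_group`, `fh` columns (as produced by [simulate_cohort()], or
#'   assembled from [compute_grs()] + [combine_with_fh()]).
#' @param out_dir Output directory, created if needed.
#' @param ref_age Reference age (years) for the cumulative-probability
#'   column (default 75).
#' @param cap Median-reporting cap in years (default 80).
#' @param seed Optional seed recorded in the metadata headers.
#' @return Invisibly, a list with the detection table, survival table, and
#'   the statistics written to JSON.
#' @export
run_report <- function(phenotypes, out_dir, ref_age = 75, cap = 80,
                       seed = NULL) {
  if (nrow(phenotypes) == 0L) stop("empty cohort")
  need <- c("grs_group", "genetic_group", "fh")
  missing_cols <- setdiff(need, names(phenotypes))
  if (length(missing_cols) > 0L)
    stop("phenotype table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  strata <- list(
    grs = factor(phenotypes$grs_group,
                 levels = c("low", "average", "high"), ordered = TRUE),
    fh = factor(ifelse(phenotypes$fh == 1, "positive_fh", "negative_fh"),
                levels = c("negative_fh", "positive_fh"), ordered = TRUE),
    combined = factor(phenotypes$genetic_group,
                      levels = c("low_genetic", "average_genetic",
                                 "high_genetic"), ordered = TRUE)
  )
  has_hg <- "high_grade" %in% names(phenotypes)
  events <- list(all = phenotypes$event == 1L)
  if (has_hg) {
    hg <- phenotypes$high_grade
    hg[is.na(hg)] <- 0L
    events$high_grade <- phenotypes$event == 1L & hg == 1L
  }

  # groups that are empty in this cohort drop out of the tables
  present_levels <- function(g) levels(g)[tabulate(g, nlevels(g)) > 0L]
  make_table <- function(g, ev) {
    lev <- present_levels(g)
    detection_table(lev,
                    as.integer(table(g)[lev]),
                    as.integer(tapply(ev, g, sum, default = 0L)[lev]))
  }

  detection <- do.call(rbind, lapply(names(strata), function(sname) {
    g <- strata[[sname]]
    do.call(rbind, lapply(names(events), function(ename) {
      cbind(stratification = sname, outcome = ename,
            detection_rates(make_table(g, events[[ename]])))
    }))
  }))

  stats_list <- list()
  if (!has_hg)
    stats_list$high_grade <- "MISSING: no high_grade column in input"
  for (sname in names(strata)) {
    g <- strata[[sname]]
    for (ename in names(events)) {
      tab <- make_table(g, events[[ename]])
      key <- paste(sname, ename, sep = "_")
      if (nrow(tab) >= 2L)
        stats_list[[paste0("chi2_", key)]] <- pearson_chi2(tab)
      if (nrow(tab) > 2L)
        stats_list[[paste0("trend_", key)]] <- cochran_armitage_trend(tab)
    }
  }

  surv_rows <- list()
  for (sname in names(strata)) {
    g <- strata[[sname]]
    for (ename in names(events)) {
      rec <- as_survival_records(
        phenotypes, outcome = if (ename == "all") "all" else "high_grade")
      for (lev in levels(g)) {
        sel <- g == lev
        if (!any(sel)) next
        curve <- tryCatch(
          suppressWarnings(km_left_truncated(rec[sel, , drop = FALSE])),
          error = function(e) NULL)
        if (is.null(curve)) next
        s_ref <- survival_at(curve, ref_age)
        med <- median_survival(curve, cap = cap)
        surv_rows[[length(surv_rows) + 1L]] <- data.frame(
          stratification = sname, outcome = ename, group = lev,
          n = sum(sel),
          surv_at_ref = s_ref$estimate,
          surv_at_ref_ci_low = s_ref$ci_low,
          surv_at_ref_ci_high = s_ref$ci_high,
          median_age = med$label,
          median_ci = med$ci_label,
          stringsAsFactors = FALSE
        )
        write_km_curve(curve, file.path(out_dir,
                                        sprintf("km_%s_%s_%s.tsv", sname, ename, lev)))
      }
      # log-rank tests per stratification/outcome
      ok <- levels(g)[table(g) > 0]
      if (length(ok) >= 2L) {
        key <- paste(sname, ename, sep = "_")
        lr <- tryCatch(suppressWarnings(logrank(rec, g)), error = function(e) NULL)
        if (!is.null(lr))
          stats_list[[paste0("logrank_", key)]] <-
          lr[c("statistic", "df", "p.value")]
        if (length(ok) > 2L) {
          lt <- tryCatch(suppressWarnings(logrank_trend(rec, g)),
                         error = function(e) NULL)
          if (!is.null(lt))
            stats_list[[paste0("logrank_trend_", key)]] <-
            lt[c("statistic", "df", "p.value")]
        }
      }
    }
  }
  survival_table <- do.call(rbind, surv_rows)

  header <- metadata_header(seed,
                            sprintf("# config_hash: %s", cohort_hash(phenotypes)))
  write_with_header <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_with_header(detection, file.path(out_dir, "detection_rates.tsv"))
  write_with_header(survival_table, file.path(out_dir, "survival_table.tsv"))
  jsonlite::write_json(
    list(package = "grsurv",
         version = as.character(utils::packageVersion("grsurv")),
         seed = seed, statistics = stats_list),
    file.path(out_dir, "statistics.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(list(detection = detection, survival = survival_table,
                 statistics = stats_list))
}

# order-insensitive fingerprint of the analysed cohort, for report headers
cohort_hash <- function(phenotypes) {
  key <- paste(phenotypes$sample_id, phenotypes$entry_age,
               phenotypes$exit_age, phenotypes$event, collapse = ";")
  v <- utf8ToInt(key)
  sprintf("%08x", as.integer(sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647))
}
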