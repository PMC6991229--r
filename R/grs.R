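#' Population mean relative risk of a SNP panel
#'
#' Under Hardy-Weinberg equilibrium a SNP with risk-allele frequency `f` and
#' per-allele odds ratio `OR` contributes an expected multiplicative risk of
#' `f^2 OR^2 + 2 f (1 - f) OR + (1 - f)^2` — the HWE genotype probabilities
#' weighting the three dosage risks. The population mean risk `W` of a panel
#' of independent SNPs is the product of these per-SNP factors. Dividing an
#' individual's raw multiplicative risk by `W` standardizes the score so its
#' population mean is 1 and values read as relative risk versus the general
#' population.
#'
#' @param panel A validated `snp_panel` data frame (see [load_panel()]).
#' @return A single positive number, `W`. Computed in log space so that
#'   panels of a hundred or more SNPs do not under- or overflow.
#' @examples
#' p <- data.frame(rsid = "rs1", chrom = "1", pos = 1L,
#'                 risk_allele = "A", other_allele = "G",
#'                 odds_ratio = 2, risk_allele_freq = 0.5, source = "genotyped")
#' population_mean_risk(p)  # 0.25*4 + 0.5*2 + 0.25 = 2.25
#' @export
population_mean_risk <- function(panel) {
  validate_panel(panel)
  exp(sum(log_hwe_factors(panel$odds_ratio, panel$risk_allele_freq)))
}

# log of the per-SNP HWE mean-risk factor f^2 OR^2 + 2f(1-f) OR + (1-f)^2
log_hwe_factors <- function(odds_ratio, freq) {
  log(freq^2 * odds_ratio^2 + 2 * freq * (1 - freq) * odds_ratio + (1 - freq)^2)
}

#' Compute population-standardized genetic risk scores
#'
#' For each sample the raw risk is the product over scored (non-missing)
#' SNPs of `OR_i ^ g_i`, where `g_i` is the risk-allele dosage (0, 1 or 2).
#' The score is the raw risk divided by the population mean risk `W`
#' restricted to the same scored SNPs, so a sample missing some genotypes is
#' renormalized against the SNPs it was actually scored on and the score
#' keeps its population mean of 1 under any missingness pattern. Both
#' products are accumulated in log space.
#'
#' A sample with every genotype missing scores exactly 1 (the population
#' average) with `n_scored = 0`; a warning reports how many such samples
#' were neutrally imputed.
#'
#' @param dosages A numeric matrix of risk-allele dosages, samples in rows
#'   and SNPs in columns; columns aligned to `panel` rows (checked against
#'   `colnames` when present). Entries must be 0, 1, 2 or `NA` (missing).
#' @param panel A validated `snp_panel` data frame.
#' @return A data frame with one row per sample: `sample_id`, `raw_risk`,
#'   `norm_constant` (the per-sample `W` over scored SNPs), `grs`,
#'   `n_scored`, and `risk_group` from [classify_grs()].
#' @examples
#' p <- simulate_panel(10, seed = 1)
#' g <- simulate_genotypes(p, 5, seed = 2)
#' compute_grs(g, p)
#' @export
compute_grs <- function(dosages, panel) {
  validate_panel(panel)
  if (is.data.frame(dosages)) dosages <- as.matrix(dosages)
  if (!is.matrix(dosages)) dosages <- matrix(dosages, nrow = 1L)
  if (ncol(dosages) != nrow(panel))
    stop("dosage matrix has ", ncol(dosages), " columns but panel has ",
         nrow(panel), " SNPs")
  if (!is.null(colnames(dosages)) &&
      !identical(colnames(dosages), panel$rsid))
    stop("dosage columns are not aligned to the panel; ",
         "use read_dosage_matrix() to reorder by rsid")
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop("dosage must be 0, 1, 2 or NA; found ",
         dosages[bad[1L], bad[2L]], " at sample ", bad[1L], ", SNP ", bad[2L])
  }
  sample_id <- rownames(dosages)
  if (is.null(sample_id)) sample_id <- sprintf("S%d", seq_len(nrow(dosages)))

  log_or <- log(panel$odds_ratio)
  log_w <- log_hwe_factors(panel$odds_ratio, panel$risk_allele_freq)
  scored <- !is.na(dosages)
  d0 <- dosages
  d0[!scored] <- 0
  log_raw <- as.vector(d0 %*% log_or)
  log_norm <- as.vector(scored %*% log_w)
  n_scored <- as.integer(rowSums(scored))
  if (any(n_scored == 0L))
    warning(sum(n_scored == 0L),
            " sample(s) had no scored genotypes; GRS set to 1 (population average)")
  grs <- exp(log_raw - log_norm)
  data.frame(
    sample_id = sample_id,
    raw_risk = exp(log_raw),
    norm_constant = exp(log_norm),
    grs = grs,
    n_scored = n_scored,
    risk_group = classify_grs(grs),
    stringsAsFactors = FALSE
  )
}

#' Classify genetic risk scores into risk groups
#'
#' Bins a population-standardized score into `low` (< 0.50), `average`
#' (0.50 to just below 1.50) and `high` (>= 1.50). The 1.5 cutoff is
#' benchmarked to the roughly 1.5-fold prostate-cancer risk conferred by a
#' positive family history, so "high GRS" and "positive FH" mark comparable
#' levels of inherited risk. The middle bin is the half-open interval
#' [0.50, 1.50), so there is no undefined gap below the high cutoff.
#'
#' @param grs Numeric vector of positive scores.
#' @return An ordered factor with levels `low < average < high`.
#' @export
classify_grs <- function(grs) {
  if (any(!is.finite(grs) | grs <= 0))
    stop("grs must be positive and finite")
  factor(ifelse(grs < 0.5, "low", ifelse(grs < 1.5, "average", "high")),
         levels = c("low", "average", "high"), ordered = TRUE)
}

#' Combine GRS risk group with family history
#'
#' Joint stratification of inherited risk: a man is `high_genetic` if he has
#' a high GRS *or* a positive family history, `low_genetic` if he has a low
#' GRS *and* a negative family history, and `average_genetic` otherwise.
#'
#' @param risk_group Factor or character vector with values
#'   `low`/`average`/`high` (as produced by [classify_grs()]).
#' @param fh Logical (or 0/1) vector: positive family history of prostate
#'   cancer in a first-degree relative.
#' @return An ordered factor with levels
#'   `low_genetic < average_genetic < high_genetic`.
#' @export
combine_with_fh <- function(risk_group, fh) {
  risk_group <- as.character(risk_group)
  if (!all(risk_group %in% c("low", "average", "high")))
    stop("risk_group values must be low, average or high")
  if (is.numeric(fh)) {
    if (!all(fh %in% c(0, 1))) stop("numeric fh must be 0/1")
    fh <- fh == 1
  }
  if (!is.logical(fh) || anyNA(fh)) stop("fh must be logical (or 0/1) without NA")
  if (length(fh) != length(risk_group))
    stop("risk_group and fh must have the same length")
  out <- ifelse(fh | risk_group == "high", "high_genetic",
                ifelse(risk_group == "low", "low_genetic", "average_genetic"))
  factor(out, levels = c("low_genetic", "average_genetic", "high_genetic"),
         ordered = TRUE)
}

#' Write GRS results to a TSV file, with an optional JSON bin summary
#'
#' @param grs_result Data frame from [compute_grs()].
#' @param path Output TSV path (`sample_id`, `grs`, `n_scored`, `risk_group`).
#' @param json_path Optional path for a JSON summary of bin counts.
#' @return `path`, invisibly.
#' @export
write_grs <- function(grs_result, path, json_path = NULL) {
  out <- grs_result[, c("sample_id", "grs", "n_scored", "risk_group")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    counts <- as.list(table(grs_result$risk_group))
    jsonlite::write_json(list(n = nrow(grs_result), bin_counts = counts),
                         json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
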