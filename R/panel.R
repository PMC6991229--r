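#' SNP risk panel tables
#'
#' A panel is a data frame with one row per risk SNP: `rsid`, `chrom`, `pos`
#' (1-based), `risk_allele`, `other_allele`, per-allele `odds_ratio`,
#' `risk_allele_freq` in the reference population, and `source`
#' (`"genotyped"` or `"imputed"`). Odds ratios and frequencies are taken from
#' external association studies and a reference population; the panel plays
#' the role of the published SNP annotation table in a polygenic-score
#' analysis.
#'
#' @name snp_panel
NULL

PANEL_COLUMNS <- c("rsid", "chrom", "pos", "risk_allele", "other_allele",
                   "odds_ratio", "risk_allele_freq", "source")

#' Validate a SNP panel table
#'
#' Checks the structural invariants a panel must satisfy before it can be
#' used to score genotypes: required columns present, odds ratios positive,
#' risk-allele frequencies strictly inside (0, 1), risk and other alleles
#' distinct, and rsIDs unique.
#'
#' @param panel A data frame with the columns listed in [snp_panel].
#' @return The validated panel (invisibly), with class `"snp_panel"` added.
#' @export
validate_panel <- function(panel) {
  if (!is.data.frame(panel)) stop("panel must be a data frame")
  missing_cols <- setdiff(PANEL_COLUMNS, names(panel))
  if (length(missing_cols) > 0L)
    stop("panel is missing required columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(panel) == 0L) stop("panel is empty")
  bad <- which(!is.finite(panel$odds_ratio) | panel$odds_ratio <= 0)
  if (length(bad) > 0L)
    stop("odds_ratio must be > 0; offending row(s): ", paste(bad, collapse = ", "))
  bad <- which(!is.finite(panel$risk_allele_freq) |
                 panel$risk_allele_freq <= 0 | panel$risk_allele_freq >= 1)
  if (length(bad) > 0L)
    stop("risk_allele_freq must lie strictly in (0, 1); offending row(s): ",
         paste(bad, collapse = ", "))
  bad <- which(panel$risk_allele == panel$other_allele)
  if (length(bad) > 0L)
    stop("risk_allele must differ from other_allele; offending row(s): ",
         paste(bad, collapse = ", "))
  dup <- panel$rsid[duplicated(panel$rsid)]
  if (length(dup) > 0L)
    stop("duplicate rsid(s) in panel: ", paste(unique(dup), collapse = ", "))
  bad_src <- setdiff(unique(panel$source), c("genotyped", "imputed"))
  if (length(bad_src) > 0L)
    stop("source must be 'genotyped' or 'imputed'; found: ",
         paste(bad_src, collapse = ", "))
  class(panel) <- unique(c("snp_panel", class(panel)))
  invisible(panel)
}

#' Read a SNP panel from a TSV file
#'
#' Reads a tab-separated panel table (header row required) and validates it
#' with [validate_panel()]. Rows are kept in file order. Malformed numeric
#' fields are reported with their line number.
#'
#' @param path Path to a tab-separated panel file.
#' @return A validated `snp_panel` data frame.
#' @examples
#' p <- simulate_panel(5, seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' write_panel(p, f)
#' identical(load_panel(f)$rsid, p$rsid)
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           comment.char = "#", check.names = FALSE)
  missing_cols <- setdiff(PANEL_COLUMNS, names(raw))
  if (length(missing_cols) > 0L)
    stop("panel file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  num <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !(is.na(x) | x == ""))
    if (length(bad) > 0L)
      stop("could not parse ", col, " on data line ", bad[1L], " of ", path,
           ": '", x[bad[1L]], "'")
    v
  }
  panel <- data.frame(
    rsid = raw$rsid,
    chrom = raw$chrom,
    pos = as.integer(num(raw$pos, "pos")),
    risk_allele = raw$risk_allele,
    other_allele = raw$other_allele,
    odds_ratio = num(raw$odds_ratio, "odds_ratio"),
    risk_allele_freq = num(raw$risk_allele_freq, "risk_allele_freq"),
    source = raw$source,
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
  class(panel) <- unique(c("snp_panel", class(panel)))
  panel
}

#' Write a SNP panel to a TSV file
#'
#' @param panel A validated panel data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  utils::write.table(panel[, PANEL_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
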