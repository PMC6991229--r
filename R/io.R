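#' Read a dosage matrix TSV aligned to a panel
#'
#' Expects a header row of rsIDs, a `sample_id` column, and one row per
#' sample with risk-allele dosages 0/1/2 (blank cells are missing).
#' Columns are reordered to panel order; columns not in the panel are
#' dropped with a warning; panel SNPs absent from the file become missing
#' for every sample.
#'
#' @param path Path to the TSV file.
#' @param panel A validated `snp_panel` data frame.
#' @return A numeric matrix (samples x panel SNPs), `NA` for missing.
#' @export
read_dosage_matrix <- function(path, panel) {
  validate_panel(panel)
  if (!file.exists(path)) stop("dosage file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (!"sample_id" %in% names(raw)) stop("dosage file needs a sample_id column")
  sample_id <- raw$sample_id
  raw <- raw[, setdiff(names(raw), "sample_id"), drop = FALSE]
  unknown <- setdiff(names(raw), panel$rsid)
  if (length(unknown) > 0L) {
    warning("dropping ", length(unknown), " column(s) not in the panel: ",
            paste(utils::head(unknown, 5L), collapse = ", "))
    raw <- raw[, setdiff(names(raw), unknown), drop = FALSE]
  }
  m <- matrix(NA_real_, nrow = length(sample_id), ncol = nrow(panel),
              dimnames = list(sample_id, panel$rsid))
  for (rs in intersect(panel$rsid, names(raw))) {
    v <- raw[[rs]]
    v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which((is.na(num) & !is.na(v)) | (!is.na(num) & !num %in% c(0, 1, 2)))
    if (length(bad) > 0L)
      stop("invalid dosage '", v[bad[1L]], "' at sample ",
           sample_id[bad[1L]], ", SNP ", rs)
    m[, rs] <- num
  }
  m
}

#' Write a dosage matrix to TSV
#'
#' @param dosages Numeric matrix, samples x SNPs, rsIDs as column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_matrix <- function(dosages, path) {
  df <- data.frame(sample_id = rownames(dosages), dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read risk-allele dosages from a VCF file
#'
#' Matches VCF records to the panel by rsID (the ID column) and converts
#' diploid GT calls into risk-allele dosages against REF/ALT. Orientation
#' is handled: when the risk allele is the REF allele the dosage is the
#' count of reference alleles. A panel SNP absent from the VCF yields a
#' missing dosage for all samples; `./.` calls are missing for that sample.
#'
#' Allele mismatches (risk allele matching neither REF nor ALT) are hard
#' errors rather than silent strand flips — strand ambiguity is a classic
#' way to corrupt a polygenic score. Palindromic SNPs (A/T or C/G panel
#' alleles), where a strand flip cannot be detected from the alleles alone,
#' produce a warning. Multi-allelic records are errors naming the site.
#'
#' @param vcf_path Path to a VCF v4.x file with a GT FORMAT field.
#' @param panel A validated `snp_panel` data frame.
#' @return A numeric matrix (samples x panel SNPs), `NA` for missing.
#' @export
read_vcf_dosages <- function(vcf_path, panel) {
  validate_panel(panel)
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- vcf@gt
  if (is.null(dim(gt_raw)))
    gt_raw <- matrix(gt_raw, nrow = 1L, dimnames = list(NULL, names(gt_raw)))
  if (is.null(gt_raw) || ncol(gt_raw) < 2L)
    stop("VCF has no sample genotype columns")
  fmt <- gt_raw[, "FORMAT"]
  if (anyNA(fmt) || any(!grepl("(^|:)GT(:|$)", fmt)))
    stop("GT missing from FORMAT in one or more VCF records")
  samples <- colnames(gt_raw)[-1L]
  ids <- fix[, "ID"]
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  hit_multi <- which(multi & ids %in% panel$rsid)
  if (length(hit_multi) > 0L)
    stop("multi-allelic VCF record(s) for panel SNP(s): ",
         paste(ids[hit_multi], collapse = ", "))

  pal <- (panel$risk_allele == "A" & panel$other_allele == "T") |
    (panel$risk_allele == "T" & panel$other_allele == "A") |
    (panel$risk_allele == "C" & panel$other_allele == "G") |
    (panel$risk_allele == "G" & panel$other_allele == "C")
  if (any(pal & panel$rsid %in% ids))
    warning("palindromic (A/T or C/G) panel SNP(s) in VCF; strand flips ",
            "cannot be detected from alleles: ",
            paste(panel$rsid[pal & panel$rsid %in% ids], collapse = ", "))

  m <- matrix(NA_real_, nrow = length(samples), ncol = nrow(panel),
              dimnames = list(samples, panel$rsid))
  gt_field <- function(x) sub(":.*$", "", x)
  for (j in seq_len(nrow(panel))) {
    row <- which(ids == panel$rsid[j])
    if (length(row) == 0L) next
    if (length(row) > 1L)
      stop("rsID ", panel$rsid[j], " appears ", length(row), " times in VCF")
    ref <- fix[row, "REF"]
    alt <- fix[row, "ALT"]
    if (panel$risk_allele[j] == alt && panel$other_allele[j] == ref) {
      count_allele <- "1"
    } else if (panel$risk_allele[j] == ref && panel$other_allele[j] == alt) {
      count_allele <- "0"
    } else {
      stop("allele mismatch at ", panel$rsid[j], ": panel ",
           panel$risk_allele[j], "/", panel$other_allele[j],
           " vs VCF ", ref, "/", alt,
           " (no strand flipping is attempted)")
    }
    gts <- gt_field(gt_raw[row, -1L])
    alleles <- strsplit(gts, "[/|]")
    m[, j] <- vapply(alleles, function(a) {
      if (any(a == ".") || length(a) != 2L) return(NA_real_)
      sum(a == count_allele)
    }, numeric(1L))
  }
  m
}

#' Read a phenotype table from TSV
#'
#' Expected columns: `sample_id`, `fh` (0/1), `entry_age`, `exit_age`,
#' `event` (0/1), `high_grade` (0/1, blank allowed when `event` is 0);
#' extra columns (e.g. `grs`, `arm`) pass through.
#'
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  ph <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "fh", "entry_age", "exit_age", "event")
  missing_cols <- setdiff(need, names(ph))
  if (length(missing_cols) > 0L)
    stop("phenotype file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("fh", "event"))
    if (!all(ph[[col]] %in% c(0L, 1L)))
      stop(col, " must be 0/1")
  ph
}

#' Write a phenotype table to TSV
#'
#' @param phenotypes Data frame as produced by [simulate_cohort()].
#' @param path Output path.
#' @param seed Optional seed recorded in a `#`-comment metadata header.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(metadata_header(seed), con)
  utils::write.table(phenotypes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

metadata_header <- function(seed = NULL, extra = character(0)) {
  c(sprintf("# grsurv %s", as.character(utils::packageVersion("grsurv"))),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)),
    extra)
}
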