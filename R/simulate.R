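#' Simulation configuration for a biopsy-monitored screening cohort
#'
#' Bundles the generator's parameters. Defaults emulate a 4-year
#' chemoprevention trial of 3225 men aged 50 to 75 at enrollment, genotyped
#' on a 110-SNP risk panel, with 14% positive family history, per-protocol
#' biopsies every 2 years, and proportional-hazards onset ages on a Weibull
#' baseline (shape 4.5, scale 72 years — a rising hazard with age scaled so
#' roughly a fifth to a quarter of entrants are diagnosed within the 4-year
#' follow-up). The log-hazard coefficients default to 0.28 per GRS unit and
#' 0.516 for positive family history.
#'
#' @param n_samples Cohort size (default 3225).
#' @param n_snps Panel size (default 110).
#' @param fh_prevalence Probability of positive family history (default 0.14).
#' @param entry_age_range Enrollment ages, uniform over this range
#'   (default `c(50, 75)`).
#' @param weibull_shape,weibull_scale Baseline Weibull hazard parameters on
#'   the age axis (defaults 4.5 and 72 years).
#' @param beta_grs Log-hazard ratio per unit of continuous GRS (default 0.28).
#' @param beta_fh Log-hazard ratio for positive family history (default 0.516).
#' @param hg_prob Probability a detected cancer is high grade (default 0.33).
#' @param followup_years Trial follow-up (default 4).
#' @param biopsy_interval_years Per-protocol biopsy spacing (default 2).
#' @param arm_hr Hazard multiplier for the treatment arm (default 1: the arm
#'   label is cosmetic, as in an analysis that pools arms).
#' @param missing_rate Genotype missingness rate injected into the dosage
#'   matrix (default 0).
#' @param seed Integer seed; every run with the same config and seed is
#'   identical.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 3225L, n_snps = 110L,
                       fh_prevalence = 0.14, entry_age_range = c(50, 75),
                       weibull_shape = 4.5, weibull_scale = 72,
                       beta_grs = 0.28, beta_fh = 0.516,
                       hg_prob = 0.33, followup_years = 4,
                       biopsy_interval_years = 2, arm_hr = 1,
                       missing_rate = 0, seed = NULL) {
  stopifnot(n_samples >= 1L, n_snps >= 1L,
            fh_prevalence >= 0, fh_prevalence <= 1,
            hg_prob >= 0, hg_prob <= 1,
            missing_rate >= 0, missing_rate <= 1,
            weibull_shape > 0, weibull_scale > 0,
            followup_years >= 0, biopsy_interval_years > 0, arm_hr > 0,
            length(entry_age_range) == 2L,
            entry_age_range[1L] <= entry_age_range[2L])
  structure(list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
                 fh_prevalence = fh_prevalence,
                 entry_age_range = entry_age_range,
                 weibull_shape = weibull_shape, weibull_scale = weibull_scale,
                 beta_grs = beta_grs, beta_fh = beta_fh, hg_prob = hg_prob,
                 followup_years = followup_years,
                 biopsy_interval_years = biopsy_interval_years,
                 arm_hr = arm_hr, missing_rate = missing_rate, seed = seed),
            class = "sim_config")
}

#' Simulate a SNP risk panel
#'
#' Stands in for a published panel of risk SNPs: risk-allele frequencies
#' are drawn Uniform(0.05, 0.95) and per-allele log odds ratios
#' Normal(0.05, 0.05), redrawn until the OR lies in \[0.8, 1.5\] — the
#' modest effect sizes typical of GWAS-confirmed common variants.
#'
#' @param n_snps Number of SNPs.
#' @param seed Optional integer seed (deterministic panels under a seed).
#' @return A validated `snp_panel` data frame with synthetic rsIDs.
#' @export
simulate_panel <- function(n_snps, seed = NULL) {
  stopifnot(n_snps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  freq <- stats::runif(n_snps, 0.05, 0.95)
  log_or <- stats::rnorm(n_snps, 0.05, 0.05)
  out_of_band <- function(x) x < log(0.8) | x > log(1.5)
  while (any(out_of_band(log_or))) {
    redo <- out_of_band(log_or)
    log_or[redo] <- stats::rnorm(sum(redo), 0.05, 0.05)
  }
  alleles <- c("A", "C", "G", "T")
  risk <- sample(alleles, n_snps, replace = TRUE)
  other <- vapply(risk, function(a) sample(setdiff(alleles, a), 1L), "")
  panel <- data.frame(
    rsid = sprintf("rs%06d", seq_len(n_snps)),
    chrom = as.character(sample(1:22, n_snps, replace = TRUE)),
    pos = sort(sample.int(2.5e8, n_snps)),
    risk_allele = risk, other_allele = unname(other),
    odds_ratio = exp(log_or), risk_allele_freq = freq,
    source = sample(c("genotyped", "imputed"), n_snps, replace = TRUE,
                    prob = c(0.7, 0.3)),
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
  panel
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Draws each sample's risk-allele dosage at SNP `i` as Binomial(2, `f_i`),
#' independently across SNPs and samples.
#'
#' @param panel A validated `snp_panel` data frame.
#' @param n_samples Number of samples.
#' @param seed Optional integer seed.
#' @param missing_rate Fraction of genotype calls set to `NA` at random.
#' @return An integer matrix (samples x SNPs) with rsIDs as column names
#'   and `S1, S2, ...` as row names.
#' @export
simulate_genotypes <- function(panel, n_samples, seed = NULL,
                               missing_rate = 0) {
  validate_panel(panel)
  stopifnot(n_samples >= 1L, missing_rate >= 0, missing_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_snps <- nrow(panel)
  d <- matrix(stats::rbinom(n_samples * n_snps, 2L,
                            rep(panel$risk_allele_freq, each = n_samples)),
              nrow = n_samples, ncol = n_snps)
  if (missing_rate > 0)
    d[stats::runif(length(d)) < missing_rate] <- NA_integer_
  dimnames(d) <- list(sprintf("S%d", seq_len(n_samples)), panel$rsid)
  d
}

#' Simulate a biopsy-monitored screening cohort with known truth
#'
#' Generates a cohort that mimics the structure of a randomized
#' chemoprevention trial analysed on the age scale:
#'
#' 1. a synthetic SNP panel and HWE genotypes give each man a true GRS;
#' 2. family history is Bernoulli(`fh_prevalence`), enrollment age uniform
#'    over `entry_age_range`;
#' 3. a latent age at cancer onset is drawn from the proportional-hazards
#'    model `h(t) = h0(t) exp(beta_grs * GRS + beta_fh * FH)` with Weibull
#'    baseline `h0`, by inverse transform;
#' 4. left truncation is imposed by rejection: a sample whose onset falls
#'    at or before his enrollment age has entry age and onset redrawn
#'    (men already diagnosed would never have enrolled);
#' 5. onsets are detected at the first per-protocol biopsy at or after
#'    onset within the follow-up window; everyone else is censored at
#'    `entry + followup_years`. Detected cancers are high grade with
#'    probability `hg_prob`.
#'
#' Detected event ages therefore lie exactly on the biopsy grid
#' (`entry + 2`, `entry + 4` under the defaults). With
#' `followup_years = 0` every man is censored at his entry age; such rows
#' have `entry_age == exit_age` and are rejected by [survival_records()],
#' which requires positive follow-up.
#'
#' @param config A [sim_config()] object.
#' @return A list with `phenotypes` (data frame: `sample_id`, `fh`,
#'   `entry_age`, `exit_age`, `event`, `high_grade`, `grs`, `grs_group`,
#'   `genetic_group`, `arm`) and `truth` (the config, panel, genotype
#'   matrix, true GRS, latent onset ages, and acceptance rate of the
#'   truncation rejection step).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_samples

  panel <- simulate_panel(config$n_snps)
  dosages <- simulate_genotypes(panel, n, missing_rate = config$missing_rate)
  grs <- compute_grs(dosages, panel)

  fh <- stats::rbinom(n, 1L, config$fh_prevalence)
  arm <- sample(rep(c("placebo", "dutasteride"), length.out = n))
  loghr <- config$beta_grs * grs$grs + config$beta_fh * fh +
    log(config$arm_hr) * (arm == "dutasteride")

  k <- config$weibull_shape
  lam <- config$weibull_scale
  draw_onset <- function(idx) {
    # inverse transform for S(t) = exp(-(t/lam)^k * exp(loghr))
    u <- stats::runif(length(idx))
    lam * (-log(u) / exp(loghr[idx]))^(1 / k)
  }
  entry <- stats::runif(n, config$entry_age_range[1L], config$entry_age_range[2L])
  onset <- draw_onset(seq_len(n))
  # rejection step: enrollees must be cancer-free at entry
  draws <- n
  repeat {
    bad <- which(onset <= entry)
    if (length(bad) == 0L) break
    entry[bad] <- stats::runif(length(bad), config$entry_age_range[1L],
                               config$entry_age_range[2L])
    onset[bad] <- draw_onset(bad)
    draws <- draws + length(bad)
    if (draws > 100 * n && n / draws < 0.01)
      stop("left-truncation rejection accepts < 1% of draws; ",
           "baseline hazard places nearly all onsets before enrollment ",
           "(shape = ", k, ", scale = ", lam, ")")
  }
  acceptance_rate <- n / draws

  n_biopsies <- floor(config$followup_years / config$biopsy_interval_years)
  exit_age <- entry + config$followup_years
  event <- integer(n)
  if (n_biopsies >= 1L) {
    biopsy_offsets <- seq_len(n_biopsies) * config$biopsy_interval_years
    rel <- onset - entry
    # first biopsy offset at/after onset, NA when past the last biopsy
    idx <- findInterval(rel, biopsy_offsets, left.open = TRUE) + 1L
    detected <- rel <= biopsy_offsets[n_biopsies]
    event[detected] <- 1L
    exit_age[detected] <- entry[detected] + biopsy_offsets[idx[detected]]
  }
  high_grade <- rep(NA_integer_, n)
  high_grade[event == 1L] <- stats::rbinom(sum(event), 1L, config$hg_prob)

  phenotypes <- data.frame(
    sample_id = grs$sample_id,
    fh = fh,
    entry_age = entry,
    exit_age = exit_age,
    event = event,
    high_grade = high_grade,
    grs = grs$grs,
    grs_group = grs$risk_group,
    genetic_group = combine_with_fh(grs$risk_group, fh == 1L),
    arm = arm,
    stringsAsFactors = FALSE
  )
  truth <- list(config = config, panel = panel, dosages = dosages,
                grs = grs$grs, onset_age = onset,
                acceptance_rate = acceptance_rate)
  list(phenotypes = phenotypes, truth = truth)
}
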