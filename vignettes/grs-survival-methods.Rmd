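---
title: "Genetic risk scores and left-truncated survival: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic risk scores and left-truncated survival: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Family history (FH) is the standard measure of inherited prostate-cancer
risk, but it is an indirect one: it reflects shared environment as well as
genes, it is often incompletely ascertained, and it labels only a minority
of men as high risk. A polygenic genetic risk score (GRS) built from
GWAS-confirmed risk SNPs measures inherited risk directly from germline
genotypes. `grsurv` implements the full analysis pipeline for studying how
such a score — alone and combined with FH — stratifies both the probability
of a prostate-cancer diagnosis during a biopsy-monitored trial and the
*age* at which that diagnosis arrives.

# The score

For a panel of $m$ independent risk SNPs with per-allele odds ratios
$\mathrm{OR}_i$ and population risk-allele frequencies $f_i$, an individual
with risk-allele dosages $g_i \in \{0,1,2\}$ receives

$$\mathrm{GRS} \;=\; \frac{\prod_{i=1}^{m} \mathrm{OR}_i^{\,g_i}}{W},
\qquad
W \;=\; \prod_{i=1}^{m}\Big( f_i^2\,\mathrm{OR}_i^2
  + 2 f_i (1-f_i)\,\mathrm{OR}_i + (1-f_i)^2 \Big).$$

$W$ is the mean multiplicative risk of a population in Hardy-Weinberg
equilibrium at the panel frequencies, so the score's population mean is
exactly 1 and a value of, say, 1.8 reads as 1.8-fold the population-average
relative risk. The per-SNP factor of $W$ is the HWE expectation
$E[\mathrm{OR}^{g}] = f^2\mathrm{OR}^2 + 2f(1-f)\mathrm{OR} + (1-f)^2$;
the package verifies mean-1 standardization both exactly (by exhaustive
genotype enumeration on small panels) and by simulation on large cohorts.

Numerically both products are accumulated as sums of logs and
exponentiated once: a 110-SNP panel multiplies over a hundred factors, and
log-space accumulation keeps extreme panels away from floating-point
under- and overflow.

**Missing genotypes.** A SNP with a missing dosage is dropped from the
numerator *and* from $W$, i.e. $W$ is renormalized per sample over the
SNPs actually scored. This is the only rule that preserves
$E[\mathrm{GRS}] = 1$ under every missingness pattern. A sample with no
scored genotypes at all scores 1 — the population average — with a
warning, rather than failing the pipeline. Whether the original analyses
renormalized or substituted neutral values is not documented anywhere we
know of; renormalization is the defensible default.

**Risk groups.** Scores are binned as low ($<0.50$), average
($[0.50, 1.50)$) and high ($\ge 1.50$). The 1.5 cutoff is benchmarked to
the roughly 1.5-fold risk conferred by a positive FH, which makes the two
risk markers commensurable. The middle bin is half-open: a printed range
like "0.50–1.49" leaves values such as 1.495 formally unassigned, and the
half-open reading is the only one consistent with a "$\ge 1.50$" high bin.
The combined stratification is *high genetic* = high GRS **or** positive
FH, *low genetic* = low GRS **and** negative FH, *average genetic*
otherwise.

# Association statistics

Detection rates (events / group size) are compared with the uncorrected
Pearson $\chi^2$ test; the package deliberately applies no continuity
correction, which is what reproduces published statistics computed on
these tables (a corrected 2×2 statistic would be visibly smaller). Ordered
risk groups are tested with the Cochran–Armitage trend test with equally
spaced scores $0, 1, 2$ — the conventional choice; the statistic is
invariant to affine score changes, and the package checks it against a
label-permutation null in its test suite. Quantitative baseline variables
use one-way ANOVA. These are standard procedures and are delegated to R's
`stats` primitives (`chisq.test`, `prop.trend.test`, `anova(lm(...))`)
behind the package's table-level interface.

One caution for anyone comparing against published three-group trend
statistics: variant conventions (score choice, finite-population factors)
move the statistic by a percent or so, and an exact match to every printed
value should not be expected.

# Survival on the age scale with delayed entry

Because trial participants enrolled cancer-free at ages 50–75, age-scale
survival is left-truncated: a man entering at 63 tells us nothing about
diagnosis hazards before 63. All survival machinery in `grsurv` therefore
uses delayed-entry risk sets
$$R(t) = \{\,i : \text{entry}_i < t \le \text{exit}_i\,\},$$
(left-open, right-closed; records with entry = exit are rejected at
construction).

* **Kaplan–Meier**: $\hat S(t) = \prod_{t_j \le t}(1 - d_j/n_j)$ with
  $n_j = |R(t_j)|$; Greenwood variance; confidence intervals on the
  complementary log-log scale, which keeps bounds inside $[0,1]$ (the CI
  method behind published curves is typically unstated; cloglog is the
  common conservative choice). Where $\hat S$ reaches 0 the package
  reports a degenerate $[0,0]$ interval.
* **Median age at diagnosis-free survival**: smallest event age with
  $\hat S \le 0.5$; short-follow-up cohorts often never reach 0.5, and the
  median is then reported with a `">80"`-style sentinel at the reporting
  cap (80 years by default). CI bounds are where the confidence envelope
  crosses 0.5, with the same sentinel rule.
* **Log-rank and trend log-rank**: observed-minus-expected accumulation
  over per-event-age hypergeometric tables built on the delayed-entry risk
  sets; the trend version uses scores $0,1,2$ across ordered groups and
  reduces algebraically to the two-group statistic when there are two
  groups.
* **Cox regression**: Breslow partial likelihood with staggered entry,
  maximized by Newton–Raphson with step-halving (tolerance $10^{-8}$ on
  the score max-norm, 50 iterations cap). Risk-set sums are computed by a
  sorted two-prefix-sum sweep ($\{ \text{entry} < t \le \text{exit}\}$ =
  $\{\text{exit} \ge t\} \setminus \{\text{entry} \ge t\}$, valid because
  entry < exit strictly), which makes a full-cohort fit effectively
  instantaneous and keeps repeated-simulation studies cheap. Standard
  errors come from the inverse observed information. Non-convergence and
  separation (runaway coefficients, detected at $|\beta| > 15$) are
  flagged on the returned object, not thrown. Ties are Breslow-handled;
  with continuous simulated ages ties are rare and no jitter is ever
  applied. The classical identity that the score test at $\beta = 0$ for a
  binary covariate equals the log-rank statistic is asserted in the test
  suite, as is exact agreement of coefficients and standard errors with an
  independent Breslow implementation.

The interaction between the score and family history is tested by a
1-df likelihood-ratio test adding the product term to the two-main-effects
model.

# The cohort generator

`simulate_cohort()` produces trial-like cohorts with known truth, used for
all recovery and operating-characteristic tests. Its defaults are the
study conditions of the motivating trial population, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n_samples` | 3225 | genetic subcohort size |
| `n_snps` | 110 | risk-SNP panel width |
| `fh_prevalence` | 0.14 | observed FH-positive fraction |
| `entry_age_range` | 50–75 y | trial eligibility window |
| `followup_years` | 4 | trial duration |
| `biopsy_interval_years` | 2 | per-protocol biopsy schedule |
| `beta_grs` | 0.28 | reported Cox log-hazard per GRS unit |
| `beta_fh` | 0.516 | reported Cox log-hazard for positive FH |
| `hg_prob` | 0.33 | high-grade fraction among diagnoses |
| `weibull_shape` | 4.5 | rising onset hazard with age |
| `weibull_scale` | 72 y | calibrated so ~20–25% of entrants are diagnosed in 4 y |

The baseline hazard is Weibull on the age axis — no published baseline
exists for this population, and a shape well above 1 encodes the
well-established steep age-incidence of prostate cancer. The scale was
calibrated once, a priori, to put the 4-year detection fraction in the
plausible 20–25% band (the default configuration lands near 22%, but the
generator is calibrated, not fitted, so tests assert a 15–30% band).

Left truncation is imposed by **rejection**: entry age and latent onset
age are redrawn for any sample whose onset precedes enrollment. This is
exact and simple; its acceptance rate is high at these incidence levels
(roughly 45% under the defaults), and a configuration whose acceptance
falls below 1% — e.g. a hazard so high that nearly everyone would have
been diagnosed before age 50 — is rejected with a diagnostic error rather
than looping forever.

Detection is grid-snapped: a latent onset is observed at the first
scheduled biopsy at or after it, within follow-up; everyone else is
censored at end of follow-up. The snapped ages are then analysed as exact
right-censored event times — mirroring how per-protocol biopsy diagnoses
are analysed in practice — rather than with an interval-censoring
likelihood. Simulation shows this approximation leaves the Cox
coefficients essentially unbiased at these settings (mean recovered
`beta_grs` within ±0.03 of truth over hundreds of cohorts, CI coverage
near nominal), which the acceptance suite re-verifies on every run.

The treatment-arm label is cosmetic by default (`arm_hr = 1`), with an
optional hazard multiplier for stratified-analysis experiments. The
high-grade flag is an independent Bernoulli among detected cancers;
a GRS-dependent grade model is deliberately out of scope — the
high-grade association in this design flows through incidence.

**What the generator does not emulate**: PSA dynamics and PSA-triggered
(off-protocol) biopsies, imperfect biopsy sensitivity, linkage
disequilibrium between panel SNPs, ancestry structure, and competing
mortality. Passing recovery tests therefore shows the estimators are
correct for the stated sampling model — not that every feature of the real
trial is reproduced.

**A known operating characteristic**: with the default effect size the
low-GRS group is small (~9% of the cohort) and its survival curve is
noisy; the low-versus-average curve ordering at age 75 holds in roughly
four of five simulated cohorts, while both extreme contrasts (low above
high, average above high) are essentially always ordered. The test suite
asserts exactly that, rather than pretending the middle contrast is
deterministic at this sample size.

# Problem sizes used in the shipped tests

The suite favours small, fast, deterministic fixtures: hand-enumerable
survival data of 3–8 records for the oracle checks; cohorts of 400 for
IO/report round-trips; 150–200 replicate cohorts (full 3225-man size for
coefficient recovery); 2000 null replicates of 60 records for test-size
checks; 100 000 HWE samples for the mean-GRS standardization check. These
sizes give Monte-Carlo standard errors comfortably below the asserted
tolerances while keeping the whole suite around a minute.

# Limitations

* The score assumes independent SNPs (the panel concept presumes LD-pruned
  inputs); no LD-aware weighting is provided.
* One reference frequency column: no per-ancestry frequency handling.
* Breslow ties only; with heavily grouped real ages Efron weighting would
  be preferable and is not implemented.
* The VCF reader is deliberately strict: allele mismatches are errors and
  palindromic SNPs only warn — silent strand flipping is a classic way to
  corrupt a polygenic score, so nothing is flipped automatically.
* Interval-censored likelihoods, competing risks and time-varying
  covariates are out of scope.
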