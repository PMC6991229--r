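# grsurv

Stratifying inherited prostate-cancer risk with a polygenic genetic risk
score (GRS) and family history (FH), and analysing **age at diagnosis** in
screening cohorts whose members enter observation late.

`grsurv` is for biostatisticians and genetic epidemiologists working with
biopsy-monitored cohorts (chemoprevention trials, screening studies) who
want to (i) score genotypes against a panel of GWAS-confirmed risk SNPs,
(ii) compare detection rates across GRS/FH risk groups, and (iii) estimate
diagnosis-free survival on the age axis, where enrollment of cancer-free
men at ages 50–75 makes the data left-truncated.

## The score and the survival model

For a panel of independent risk SNPs with per-allele odds ratios
`OR_i` and population risk-allele frequencies `f_i`, a man with risk-allele
dosages `g_i ∈ {0,1,2}` receives

    GRS = Π_i OR_i^g_i / W,
    W   = Π_i [ f_i² OR_i² + 2 f_i (1−f_i) OR_i + (1−f_i)² ]

`W` is the Hardy–Weinberg population mean risk, so the score has mean 1.0
and reads as relative risk versus the general population. Men are binned
as low (< 0.50), average ([0.50, 1.50)) or high (≥ 1.50) GRS — the 1.5
cutoff matching the ~1.5-fold risk of a positive FH — and jointly as
*high genetic* (high GRS **or** positive FH), *low genetic* (low GRS
**and** negative FH), or *average genetic* otherwise.

Survival analysis uses delayed-entry risk sets
`R(t) = {i : entry_i < t ≤ exit_i}` throughout: left-truncated
Kaplan–Meier with Greenwood/cloglog intervals, log-rank and trend
log-rank tests, and Cox proportional-hazards regression (Breslow ties,
Newton–Raphson) — all implemented natively on those risk sets.
Contingency statistics (uncorrected Pearson χ², Cochran–Armitage trend,
one-way ANOVA) reproduce the detection-rate comparisons of published risk
tables. A cohort simulator with known truth (HWE genotypes, Weibull onset
hazards, rejection-sampled left truncation, biennial biopsy detection)
backs every estimator with recovery tests.

## Worked example

```r
library(grsurv)

# Published-style detection table: PCa by family history
fh_tab <- detection_table(c("negative_fh", "positive_fh"),
                          c(2789, 436), c(598, 116))
detection_rates(fh_tab)
#>         group total events      rate pct
#> 1 negative_fh  2789    598 0.2144138  21
#> 2 positive_fh   436    116 0.2660550  27
pearson_chi2(fh_tab)
#> $statistic 5.833292   $df 1   $p.value 0.01573352

# A simulated trial-like cohort with known truth
sim <- simulate_cohort(sim_config(seed = 1))
ph  <- sim$phenotypes
table(ph$genetic_group)
#>     low_genetic average_genetic    high_genetic
#>             249            2196             780

rec <- as_survival_records(ph)
cox_fit(rec, c("grs", "fh"))
#> Cox proportional hazards fit (delayed entry, Breslow ties)
#> n = 3225, events = 627, iterations = 4, converged = TRUE
#>       coef exp(coef)      se     z         p
#> grs 0.3460     1.413 0.08163 4.239 2.249e-05
#> fh  0.5826     1.791 0.09892 5.889 3.887e-09

# Diagnosis-free survival at age 75 by combined genetic risk
g <- ph$genetic_group
sapply(levels(g), function(l)
  round(survival_at(km_left_truncated(rec[g == l, ]), 75)$estimate, 3))
#>     low_genetic average_genetic    high_genetic
#>           0.437           0.305           0.151

logrank_trend(rec, g)
#> trend log-rank chi2 = 29.9, p = 4.65e-08
```

The chi-square of 5.83 on the FH table reproduces the published
comparison (27% vs 21% detection). In the simulated cohort the fitted Cox
coefficients (0.35 per GRS unit, 0.58 for FH) sit within sampling error of
the generator's truth (0.28, 0.516), and diagnosis-free survival at age 75
decreases monotonically across combined risk groups — the dose-response
pattern the stratification is designed to reveal. (Absolute survival
levels depend on the simulated baseline hazard and censoring pattern and
are not calibrated to any particular cohort.)

A thin command-line wrapper over these functions is installed at
`inst/cli/grsurv.R` (subcommands `panel-validate`, `grs`, `simulate`,
`assoc`, `km`, `logrank`, `cox`, `report`).

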