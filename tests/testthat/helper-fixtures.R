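# shared fixtures and independent brute-force oracles

toy_panel <- function(odds_ratio, freq, rsid = NULL) {
  n <- length(odds_ratio)
  if (is.null(rsid)) rsid <- sprintf("rs%d", seq_len(n))
  data.frame(rsid = rsid, chrom = rep("1", n), pos = seq_len(n) * 100L,
             risk_allele = rep("A", n), other_allele = rep("G", n),
             odds_ratio = odds_ratio, risk_allele_freq = freq,
             source = rep("genotyped", n), stringsAsFactors = FALSE)
}

# exhaustive-enumeration GRS oracle: every genotype combination of a small
# panel, with its HWE probability, raw risk and standardized score
enumerate_grs <- function(panel) {
  combos <- expand.grid(rep(list(0:2), nrow(panel)))
  hwe <- function(g, f) ifelse(g == 2, f^2, ifelse(g == 1, 2 * f * (1 - f),
                                                   (1 - f)^2))
  W <- prod(panel$risk_allele_freq^2 * panel$odds_ratio^2 +
              2 * panel$risk_allele_freq * (1 - panel$risk_allele_freq) *
              panel$odds_ratio +
              (1 - panel$risk_allele_freq)^2)
  data.frame(
    combos,
    prob = apply(combos, 1L, function(g)
      prod(hwe(g, panel$risk_allele_freq))),
    raw = apply(combos, 1L, function(g) prod(panel$odds_ratio^g)),
    grs = apply(combos, 1L, function(g) prod(panel$odds_ratio^g)) / W
  )
}

# brute-force left-truncated product-limit oracle: explicit per-record
# risk-set enumeration at each event age
km_oracle <- function(entry, exit, event) {
  times <- sort(unique(exit[event == 1]))
  s <- 1
  out <- data.frame(time = times, n = NA_real_, d = NA_real_, S = NA_real_)
  for (i in seq_along(times)) {
    t <- times[i]
    n <- 0; d <- 0
    for (j in seq_along(entry)) {
      if (entry[j] < t && exit[j] >= t) n <- n + 1
      if (exit[j] == t && event[j] == 1) d <- d + 1
    }
    s <- s * (1 - d / n)
    out$n[i] <- n; out$d[i] <- d; out$S[i] <- s
  }
  out
}

# brute-force log-rank oracle for two groups: per-event-age 2x2 tables
logrank_oracle_2g <- function(entry, exit, event, group) {
  stopifnot(length(unique(group)) == 2L)
  g1 <- sort(unique(group))[1L]
  times <- sort(unique(exit[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- entry < t & exit >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    ev <- event == 1 & exit == t
    d <- sum(ev); d1 <- sum(ev & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n - d) / (n - 1) * (n1 / n) * (1 - n1 / n)
  }
  (O - E)^2 / V
}

# Breslow log partial likelihood written directly from its definition, for
# grid-search maximization on tiny data sets
pl_oracle <- function(entry, exit, event, x, beta) {
  ll <- 0
  for (t in sort(unique(exit[event == 1]))) {
    at_risk <- entry < t & exit >= t
    ev <- which(event == 1 & exit == t)
    ll <- ll + sum(beta * x[ev]) -
      length(ev) * log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# small cohort config used where full trial size is not needed; the panel
# keeps its full width so the GRS spread (hence the risk-group split) stays
# realistic
small_config <- function(seed, ...) {
  sim_config(n_samples = 400L, n_snps = 110L, seed = seed, ...)
}
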