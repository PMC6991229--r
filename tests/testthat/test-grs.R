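test_that("panel loading round-trips and rejects invalid rows", {
  p <- toy_panel(c(1.2, 0.9), c(0.3, 0.6))
  f <- tempfile(fileext = ".tsv")
  write_panel(p, f)
  back <- load_panel(f)
  expect_equal(back$rsid, p$rsid)
  expect_equal(back$odds_ratio, p$odds_ratio)
  expect_equal(back$risk_allele_freq, p$risk_allele_freq)

  bad <- p; bad$odds_ratio[1L] <- 0
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_panel(f), "odds_ratio")

  bad <- p; bad$risk_allele_freq[2L] <- 1.0
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_panel(f), "risk_allele_freq")

  bad <- p; bad$rsid[2L] <- bad$rsid[1L]
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_panel(f), "duplicate")

  # malformed numeric names the offending line
  txt <- readLines({write_panel(p, f); f})
  txt[2L] <- sub("1.2", "not_a_number", txt[2L], fixed = TRUE)
  writeLines(txt, f)
  expect_error(load_panel(f), "line 1")
})

test_that("population mean risk follows the HWE product formula", {
  expect_equal(population_mean_risk(toy_panel(1, 0.37)), 1)
  expect_equal(population_mean_risk(toy_panel(2, 0.5)), 2.25)
  expect_equal(population_mean_risk(toy_panel(c(2, 2), c(0.5, 0.5))), 5.0625)
  expect_error(population_mean_risk(toy_panel(numeric(0), numeric(0))),
               "empty")
})

test_that("GRS matches hand calculation and the null panel scores 1", {
  p <- toy_panel(2, 0.5)
  g <- matrix(2, 1, 1, dimnames = list("a", p$rsid))
  res <- compute_grs(g, p)
  expect_equal(res$grs, 4 / 2.25)
  expect_equal(res$n_scored, 1L)
  expect_equal(as.character(res$risk_group), "high")

  null_p <- toy_panel(rep(1, 6), runif(6, 0.1, 0.9))
  gm <- matrix(sample(0:2, 30, replace = TRUE), 5, 6)
  expect_equal(compute_grs(gm, null_p)$grs, rep(1, 5))

  expect_error(compute_grs(matrix(3, 1, 1), p), "dosage")
})

test_that("missing genotypes renormalize; all-missing scores 1 with warning", {
  p <- toy_panel(c(2, 1.3), c(0.5, 0.2))
  g <- matrix(c(NA, 1), 1, 2)
  res <- compute_grs(g, p)
  # SNP 1 dropped from numerator and denominator
  w2 <- 0.2^2 * 1.3^2 + 2 * 0.2 * 0.8 * 1.3 + 0.8^2
  expect_equal(res$grs, 1.3 / w2)
  expect_equal(res$n_scored, 1L)

  expect_warning(res0 <- compute_grs(matrix(NA_real_, 1, 2), p),
                 "no scored genotypes")
  expect_equal(res0$grs, 1)
  expect_equal(res0$n_scored, 0L)
})

test_that("GRS is multiplicative over panel partitions and monotone in dosage", {
  set.seed(11)
  p <- toy_panel(exp(rnorm(8, 0.05, 0.1)), runif(8, 0.1, 0.9))
  g <- matrix(sample(0:2, 8 * 4, replace = TRUE), 4, 8)
  whole <- compute_grs(g, p)$grs
  split_prod <- compute_grs(g[, 1:3, drop = FALSE], p[1:3, ])$grs *
    compute_grs(g[, 4:8, drop = FALSE], p[4:8, ])$grs
  expect_equal(whole, split_prod)

  p1 <- toy_panel(1.4, 0.3)
  scores <- compute_grs(matrix(0:2, 3, 1), p1)$grs
  expect_true(all(diff(scores) > 0))
})

test_that("GRS matches exhaustive enumeration on a 3-SNP panel", {
  p <- toy_panel(c(1.5, 0.85, 1.2), c(0.2, 0.5, 0.7))
  oracle <- enumerate_grs(p)
  g <- as.matrix(oracle[, 1:3])
  dimnames(g) <- list(NULL, p$rsid)
  expect_equal(compute_grs(g, p)$grs, oracle$grs)
  # population standardization is exact: HWE-weighted mean GRS is 1
  expect_equal(sum(oracle$prob * oracle$grs), 1)
})

test_that("sample mean GRS converges to 1 under HWE genotypes", {
  panel <- simulate_panel(40, seed = 31)
  g <- simulate_genotypes(panel, 20000, seed = 32)
  grs <- compute_grs(g, panel)$grs
  se <- sd(grs) / sqrt(length(grs))
  expect_lt(abs(mean(grs) - 1), 3 * se)
})

test_that("risk-group bins use the half-open [0.5, 1.5) convention", {
  expect_equal(as.character(classify_grs(c(0.499, 0.5, 1.0, 1.495, 1.5, 2))),
               c("low", "average", "average", "average", "high", "high"))
  expect_error(classify_grs(0), "positive")
  expect_error(classify_grs(-1), "positive")
})

test_that("combined GRS x FH groups follow the either-or rule and conserve counts", {
  expect_equal(as.character(combine_with_fh("low", TRUE)), "high_genetic")
  expect_equal(as.character(combine_with_fh("low", FALSE)), "low_genetic")
  expect_equal(as.character(combine_with_fh("average", FALSE)), "average_genetic")
  expect_equal(as.character(combine_with_fh("high", FALSE)), "high_genetic")
  expect_equal(as.character(combine_with_fh("average", TRUE)), "high_genetic")

  set.seed(5)
  grs <- exp(rnorm(500, 0, 0.5))
  fh <- runif(500) < 0.14
  rg <- classify_grs(grs)
  cg <- combine_with_fh(rg, fh)
  expect_equal(sum(table(rg)), 500L)
  expect_equal(sum(table(cg)), 500L)
  # every FH-positive man is high_genetic
  expect_true(all(cg[fh] == "high_genetic"))
})
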