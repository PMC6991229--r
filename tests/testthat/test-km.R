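test_that("KM matches brute-force risk-set enumeration on hand fixtures", {
  # common entry at 0; exits 5 (event), 8 (censored), 10 (event):
  # t=5: n=3,d=1 -> 2/3; t=10: only the third record remains, n=1,d=1 -> 0
  entry <- c(0, 0, 0); exit <- c(5, 8, 10); event <- c(1, 0, 1)
  oracle <- km_oracle(entry, exit, event)
  expect_equal(oracle$S, c(2 / 3, 0))
  km <- km_left_truncated(survival_records(entry, exit, event))
  expect_equal(km$time, oracle$time)
  expect_equal(km$n_risk, oracle$n)
  expect_equal(km$survival, oracle$S)

  # delayed entry: {(4,6,event), (0,6,event), (5,7,censored)}
  # at t=6 all three are at risk (entry < 6 <= exit), d=2 -> S(6) = 1/3
  r2 <- survival_records(c(4, 0, 5), c(6, 6, 7), c(1, 1, 0))
  km2 <- km_left_truncated(r2)
  expect_equal(km2$time, 6)
  expect_equal(km2$n_risk, 3)
  expect_equal(km2$n_event, 2)
  expect_equal(km2$survival, 1 / 3)
})

test_that("without censoring and common entry KM is the ECDF complement", {
  set.seed(8)
  exit <- 1 + rexp(40)
  rec <- survival_records(rep(0, 40), exit, rep(1, 40))
  km <- km_left_truncated(rec)
  ecdf_c <- 1 - ecdf(exit)(km$time)
  expect_equal(km$survival, ecdf_c)
})

test_that("left-truncated KM with its CI matches an independent implementation", {
  skip_if_not_installed("survival")
  set.seed(21)
  n <- 150
  entry <- runif(n, 50, 70)
  exit <- entry + rexp(n, 0.1)
  event <- as.integer(runif(n) < 0.7)
  exit[event == 0] <- entry[event == 0] + runif(sum(event == 0), 0.5, 6)
  rec <- survival_records(entry, exit, event)
  km <- km_left_truncated(rec)
  sf <- survival::survfit(
    survival::Surv(entry, exit, event) ~ 1, conf.type = "log-log")
  i <- sf$n.event > 0
  expect_equal(km$time, sf$time[i])
  expect_equal(km$survival, sf$surv[i], tolerance = 1e-12)
  expect_equal(km$se, sf$std.err[i] * sf$surv[i], tolerance = 1e-12)
  # where S hits 0 this package reports a degenerate [0, 0] interval while
  # survfit reports NA; compare the informative part of the curve
  pos <- km$survival > 0
  expect_equal(km$ci_low[pos], sf$lower[i][pos], tolerance = 1e-10)
  expect_equal(km$ci_high[pos], sf$upper[i][pos], tolerance = 1e-10)
})

test_that("survival estimates are monotone, in [0,1], right-continuous at events", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60
    entry <- runif(n, 0, 5)
    exit <- entry + rexp(n)
    event <- as.integer(runif(n) < 0.6)
    km <- km_left_truncated(survival_records(entry, exit, event))
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(km$survival >= 0 & km$survival <= 1))
    # value at an event age is the post-jump value
    j <- nrow(km) %/% 2 + 1L
    expect_equal(survival_at(km, km$time[j])$estimate, km$survival[j])
  }
})

test_that("survival_at is a right-continuous step lookup with warning before entry", {
  rec <- survival_records(c(4, 0, 5), c(6, 6, 7), c(1, 1, 0))
  km <- km_left_truncated(rec)
  expect_warning(s <- survival_at(km, 2), "precedes")
  expect_equal(s$estimate, 1)
  expect_equal(survival_at(km, 6.5)$estimate, km$survival[1L])
  expect_equal(survival_at(km, 6)$estimate, 1 / 3)
})

test_that("median survival uses <= 0.5 crossing and the >cap sentinel", {
  # drops to 0.4 at 74
  rec <- survival_records(rep(0, 5), c(70, 72, 74, 74, 74), c(0, 0, 1, 1, 1))
  km <- km_left_truncated(rec)
  med <- median_survival(km)
  expect_equal(med$estimate, 74)

  # never reaches 0.5
  rec2 <- survival_records(rep(0, 5), c(70, 75, 78, 79, 80), c(1, 0, 0, 0, 0))
  med2 <- median_survival(km_left_truncated(rec2))
  expect_equal(med2$estimate, Inf)
  expect_equal(med2$label, ">80")

  # hits exactly 0.5
  rec3 <- survival_records(rep(0, 4), c(70, 76, 80, 81), c(1, 1, 0, 0))
  expect_equal(median_survival(km_left_truncated(rec3))$estimate, 76)
})

test_that("all-censored input yields S identically 1 with a warning", {
  rec <- survival_records(c(0, 0), c(3, 4), c(0, 0))
  expect_warning(km <- km_left_truncated(rec), "no events")
  expect_equal(nrow(km), 0L)
  expect_equal(survival_at(km, 10)$estimate, 1)
})

test_that("curve export writes the step-function columns", {
  rec <- survival_records(c(4, 0, 5), c(6, 6, 7), c(1, 1, 0))
  f <- tempfile(fileext = ".tsv")
  write_km_curve(km_left_truncated(rec), f)
  back <- read.delim(f)
  expect_named(back, c("age", "n_risk", "n_event", "survival", "se",
                       "ci_low", "ci_high"))
  expect_equal(back$survival, 1 / 3)
})
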