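test_that("symmetric two-group data gives beta = 0", {
  entry <- c(0, 0, 1); exit <- c(3, 5, 6); event <- c(1, 1, 0)
  rec <- survival_records(rep(entry, 2), rep(exit, 2), rep(event, 2),
                          covariates = data.frame(x = rep(c(0, 1), each = 3)))
  fit <- cox_fit(rec, "x")
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-7)
})

test_that("tiny-data fit matches grid search of the hand-written partial likelihood", {
  entry <- c(0, 0, 1, 0, 2)
  exit <- c(2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 0, 1)
  x <- c(0.5, -1, 2, 0, 1)
  rec <- survival_records(entry, exit, event,
                          covariates = data.frame(x = x))
  fit <- cox_fit(rec, "x")
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, function(b) pl_oracle(entry, exit, event, x, b),
               numeric(1L))
  expect_true(fit$converged)
  # the grid resolves the argmax to half a step
  expect_lt(abs(unname(fit$coefficients) - grid[which.max(ll)]), 1e-4)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-6)
})

test_that("score test at beta = 0 equals the log-rank statistic (no ties)", {
  set.seed(41)
  n <- 60
  entry <- runif(n, 0, 3)
  exit <- entry + rexp(n) + 1e-3
  event <- as.integer(runif(n) < 0.7)
  x <- rbinom(n, 1, 0.5)
  rec <- survival_records(entry, exit, event,
                          covariates = data.frame(x = x))
  pl <- grsurv:::cox_partial(matrix(as.numeric(x)), entry, exit, event, 0)
  score_stat <- pl$gradient^2 / pl$information[1, 1]
  lr <- logrank(rec, x)$statistic
  expect_equal(unname(score_stat), lr, tolerance = 1e-6)
})

test_that("fit agrees with an independent Breslow implementation", {
  skip_if_not_installed("survival")
  sim <- simulate_cohort(small_config(seed = 17))
  ph <- sim$phenotypes
  fit <- cox_fit(as_survival_records(ph), c("grs", "fh"))
  oracle <- survival::coxph(
    survival::Surv(entry_age, exit_age, event) ~ grs + fh,
    data = ph, ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(oracle)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(oracle)))),
               tolerance = 1e-6)
  expect_equal(fit$loglik, oracle$loglik[2L], tolerance = 1e-6)
})

test_that("degenerate designs are rejected and separation is flagged", {
  rec <- survival_records(c(0, 0, 0, 0), c(1, 2, 3, 4), c(1, 1, 1, 0),
                          covariates = data.frame(a = c(1, 0, 1, 0)))
  rec$b <- rec$a
  expect_error(cox_fit(rec, c("a", "b")), "collinear")
  rec$const <- 1
  expect_error(cox_fit(rec, "const"), "constant")
  rec0 <- survival_records(c(0, 0), c(1, 2), c(0, 0),
                           covariates = data.frame(a = c(0, 1)))
  expect_error(cox_fit(rec0, "a"), "no events")

  # perfectly separated: covariate orders the event times monotonically
  n <- 20
  x <- rep(c(0, 1), each = n / 2)
  exit <- ifelse(x == 1, seq(1, 2, length.out = n), seq(3, 4, length.out = n))
  recs <- survival_records(rep(0, n), exit, rep(1, n),
                           covariates = data.frame(x = x))
  expect_warning(fit <- cox_fit(recs, "x"), "separation")
  expect_false(fit$converged)
})

test_that("interaction LRT rejects degenerate input and detects a strong product effect", {
  sim <- simulate_cohort(small_config(seed = 23))
  ph <- sim$phenotypes
  rec <- as_survival_records(ph)
  # fh is binary, so the fh x fh product duplicates fh itself
  expect_error(cox_interaction_lrt(rec, "fh", "fh"), "collinear")

  set.seed(91)
  n <- 3000
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  lp <- 0.2 * x1 + 0.2 * x2 + 0.9 * x1 * x2
  entry <- runif(n, 0, 1)
  u <- runif(n)
  onset <- entry + (-log(u) / (0.08 * exp(lp)))
  event <- as.integer(onset <= entry + 6)
  exit <- pmin(onset, entry + 6)
  exit[exit <= entry] <- entry[exit <= entry] + 1e-6
  recs <- survival_records(entry, exit, event,
                           covariates = data.frame(x1 = x1, x2 = x2))
  res <- cox_interaction_lrt(recs, "x1", "x2")
  expect_lt(res$p.value, 0.01)
  expect_equal(res$df, 1L)
})

test_that("interaction LRT holds its size when no interaction exists", {
  set.seed(303)
  reps <- 200
  pvals <- replicate(reps, {
    n <- 150
    x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
    lp <- 0.3 * x1 + 0.3 * x2
    entry <- runif(n, 0, 1)
    onset <- entry - log(runif(n)) / (0.15 * exp(lp))
    event <- as.integer(onset <= entry + 8)
    exit <- pmin(onset, entry + 8)
    recs <- survival_records(entry, exit, event,
                             covariates = data.frame(x1 = x1, x2 = x2))
    tryCatch(cox_interaction_lrt(recs, "x1", "x2")$p.value,
             error = function(e) NA_real_)
  })
  rej <- mean(pvals < 0.05, na.rm = TRUE)
  expect_gt(rej, 0.005)
  expect_lt(rej, 0.12)
})
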