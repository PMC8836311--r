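test_that("fixed-effect pooling matches hand-computed inverse-variance algebra", {
  # k = 2, z = (0, 1), v = (1, 1): est = 0.5, se = sqrt(0.5), Q = 0.5
  f <- rema(y = c(0, 1), vi = c(1, 1), estimator = "FE", metric = "z")
  expect_equal(f$estimate, 0.5)
  expect_equal(f$se, sqrt(0.5))
  expect_equal(f$Q, 0.5)
  # no dispersion: Q = 0, tau2 = 0, I2 = 0
  g <- rema(y = rep(0.3, 5), vi = rep(0.02, 5), estimator = "DL")
  expect_equal(g$estimate, 0.3)
  expect_equal(g$Q, 0)
  expect_equal(g$tau2, 0)
  expect_equal(g$I2, 0)
})

test_that("DL collapses to FE when Q <= df and estimates ignore record order", {
  set.seed(11)
  y <- rnorm(8, 0.2, 0.01)          # tiny spread relative to vi
  vi <- rep(0.05, 8)
  dl <- rema(y = y, vi = vi, estimator = "DL")
  fe <- rema(y = y, vi = vi, estimator = "FE")
  expect_lte(dl$Q, dl$df)
  expect_equal(dl$tau2, 0)
  expect_equal(dl$estimate, fe$estimate)
  ds <- ri_studies()
  perm <- sample(nrow(ds))
  f1 <- rema(data = ds)
  f2 <- rema(data = ds[perm, ])
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-12)
  expect_equal(f1$tau2, f2$tau2, tolerance = 1e-12)
})

test_that("REML tau2 agrees with a brute-force restricted-likelihood grid", {
  set.seed(21)
  for (k in c(5, 9, 12)) {
    vi <- runif(k, 0.01, 0.08)
    y <- rnorm(k, 0.1, sqrt(0.03 + vi))
    fit <- rema(y = y, vi = vi, estimator = "REML")
    expect_lt(abs(fit$tau2 - reml_grid_oracle(y, vi)), 1e-4)
  }
})

test_that("DL and REML recover simulated truth (rho = -0.15, tau2 = 0.02)", {
  set.seed(31)
  k <- 100
  reps <- 500
  est <- matrix(NA_real_, reps, 4)
  for (i in seq_len(reps)) {
    n <- round(exp(runif(k, log(30), log(5000))))
    vi <- 1 / (n - 3)
    y <- rnorm(k, atanh(-0.15), sqrt(0.02 + vi))
    dl <- rema(y = y, vi = vi, estimator = "DL")
    re <- rema(y = y, vi = vi, estimator = "REML")
    est[i, ] <- c(dl$estimate_r, dl$tau2, re$estimate_r, re$tau2)
  }
  expect_lt(abs(mean(est[, 1]) - (-0.15)), 0.02)
  expect_lt(abs(mean(est[, 3]) - (-0.15)), 0.02)
  expect_lt(abs(mean(est[, 2]) - 0.02), 0.01)   # within 50% of tau2
  expect_lt(abs(mean(est[, 4]) - 0.02), 0.01)
})

test_that("unweighted estimator is the plain mean with sd/sqrt(k) error", {
  y <- c(0.1, 0.2, 0.6)
  f <- rema(y = y, vi = c(1, 1, 1), estimator = "UNWEIGHTED")
  expect_equal(f$estimate, mean(y))
  expect_equal(f$se, sd(y) / sqrt(3))
})

test_that("degenerate and invalid inputs are handled", {
  f1 <- rema(y = 0.4, vi = 0.01)
  expect_equal(f1$k, 1L)
  expect_true(is.na(f1$Q))
  expect_error(rema(y = c(0, 1), vi = c(1, -1)), "positive")
  expect_error(rema(r = c(0.2, 1.0), n = c(50, 60)), "\\|r\\| < 1")
})

test_that("rema methods are coherent", {
  ds <- ri_studies()
  fit <- rema(data = ds)
  expect_equal(unname(coef(fit)["estimate_r"]), fit$estimate_r)
  ci <- confint(fit)
  expect_equal(unname(ci[1, 1]), fit$ci_low_r)
  expect_lte(fit$ci_low_r, fit$estimate_r)
  expect_lte(fit$estimate_r, fit$ci_high_r)
  expect_equal(sum(weights(fit)), 1)
  res <- residuals(fit)
  expect_length(res, fit$k)
  # prediction interval contains the confidence interval
  pr <- predict(fit)
  expect_lte(pr$pi_low_r, pr$ci_low_r)
  expect_gte(pr$pi_high_r, pr$ci_high_r)
  # simulate: reproducible and of the right shape
  s1 <- simulate(fit, nsim = 3, seed = 5)
  s2 <- simulate(fit, nsim = 3, seed = 5)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(fit$k, 3L))
  # I2 consistency: Q-based identity
  expect_equal(fit$I2, max(0, (fit$Q - fit$df) / fit$Q) * 100)
  expect_output(print(summary(fit)), "heterogeneity")
})

test_that("subgroup comparison behaves at its boundary cases", {
  # identical groups -> Q_between = 0
  ds <- make_ds(rep(c(0.2, 0.3), 4), rep(c(80, 120), 4),
                religiosity = rep(c("beliefs", "behavior"), each = 4))
  # construct two groups with identical effect/size profiles
  st <- subgroup_test(ds, "religiosity_type")
  expect_lt(st$Q_between, 1e-10)
  expect_equal(st$df_between, 1L)
  expect_error(subgroup_test(make_ds(c(0.1, 0.2, 0.3), c(50, 60, 70),
                                     religiosity = c("beliefs", "beliefs",
                                                     "behavior")),
                             "religiosity_type"),
               "fewer than 2")
})

test_that("meta-regression interpolates a saturated fit and controls type I error", {
  # two studies, two moderator values: exact interpolation, residual Q = 0
  ds <- make_ds(c(0.1, 0.3), c(200, 200), pct_men = c(20, 80))
  fit <- meta_regress(ds, "pct_men", estimator = "DL")
  pred <- unname(drop(fit$X %*% fit$coefficients))
  expect_equal(pred, fit$y, tolerance = 1e-10)
  expect_lt(fit$QE, 1e-10)
  # constant moderator -> singular
  ds2 <- make_ds(c(0.1, 0.3, 0.2), c(100, 100, 100), pct_men = 50)
  expect_error(meta_regress(ds2, "pct_men"), "singular")
  # null moderator: rejection rate ~ alpha (moment estimator for speed)
  set.seed(41)
  reps <- 2000
  k <- 20
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    n <- round(runif(k, 50, 500))
    x <- runif(k)
    d <- make_ds(tanh(rnorm(k, 0, sqrt(0.01 + 1 / (n - 3)))), n,
                 pct_men = 100 * x)
    m <- meta_regress(d, "pct_men", estimator = "DL")
    rej[i] <- m$p[2] < 0.05
  }
  expect_gt(mean(rej), 0.025)
  expect_lt(mean(rej), 0.085)
})
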