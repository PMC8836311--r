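test_that("rank-correlation test matches exhaustive pair counting at k = 3", {
  # with 3 studies Kendall tau can only be one of {-1, -1/3, 1/3, 1}
  ds <- make_ds(c(0.50, 0.30, 0.10), c(20, 50, 200))
  b <- begg_test(ds, published_only = FALSE)
  expect_true(abs(b$statistic) %in% c(1, 1 / 3) ||
                abs(abs(b$statistic) - 1 / 3) < 1e-10)
  # large effects in small studies -> positive association with variance
  expect_gt(b$statistic, 0)
  expect_error(begg_test(make_ds(0.1, 50), published_only = FALSE), "k >= 3")
})

test_that("egger intercept vanishes for a mirror-symmetric funnel", {
  n <- c(30, 80, 200, 500, 1500)
  z <- c(0.4, 0.25, 0.1, 0.05, 0.02)
  ds <- make_ds(tanh(c(z, -z)), c(n, n))
  e <- egger_test(ds, published_only = FALSE)
  expect_lt(abs(e$details$intercept), 1e-8)
  expect_error(egger_test(make_ds(c(0.1, 0.2, 0.3), c(100, 100, 100)),
                          published_only = FALSE), "singular")
})

test_that("bias tests keep nominal type-I error without selection", {
  set.seed(52)
  reps <- 2000
  k <- 40
  # the excess-significance chi-square is not size-calibrated in this
  # regime (its E approaches k), so only the asymmetry tests are timed here
  rej <- matrix(FALSE, reps, 2,
                dimnames = list(NULL, c("begg", "egger")))
  for (i in seq_len(reps)) {
    n <- round(exp(runif(k, log(30), log(3000))))
    d <- make_ds(tanh(rnorm(k, 0.2, sqrt(1 / (n - 3)))), n)
    rej[i, "begg"] <- begg_test(d, published_only = FALSE)$p < 0.05
    rej[i, "egger"] <- egger_test(d, published_only = FALSE)$p < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(rates > 0.02 & rates < 0.085),
              info = paste(names(rates), round(rates, 3), collapse = "; "))
})

test_that("egger has power against significance-driven selection", {
  set.seed(53)
  reps <- 500
  hits <- 0L
  for (i in seq_len(reps)) {
    rs <- ns <- c()
    while (length(rs) < 100) {
      n <- round(exp(runif(1, log(30), log(600))))
      z <- rnorm(1, 0.1, sqrt(1 / (n - 3)))
      p <- 2 * pnorm(-abs(z) * sqrt(n - 3))
      publish <- if (p < 0.05 && z > 0) runif(1) < 0.9 else runif(1) < 0.05
      if (publish) { rs <- c(rs, tanh(z)); ns <- c(ns, n) }
    }
    hits <- hits + (egger_test(make_ds(rs, ns),
                               published_only = FALSE)$p < 0.05)
  }
  expect_gt(hits / reps, 0.5)
})

test_that("trim-and-fill finds nothing in symmetric funnels and recovers deletions", {
  n <- c(30, 80, 200, 500, 1500)
  z <- c(0.4, 0.25, 0.1, 0.05, 0.02)
  sym <- make_ds(tanh(c(z, -z, 0)), c(n, n, 800))
  tf <- trim_and_fill(sym, side = "right", published_only = FALSE)
  expect_equal(tf$statistic, 0)
  expect_equal(tf$adjusted_estimate_r, tf$details$unadjusted_estimate_r)
  # delete the 5 largest effects from one side of a symmetric cloud
  set.seed(54)
  k0_hat <- replicate(60, {
    nn <- round(exp(runif(40, log(50), log(2000))))
    zz <- rnorm(40, 0.15, sqrt(1 / (nn - 3)))
    drop <- order(zz, decreasing = TRUE)[1:5]   # suppress the right tail
    d <- make_ds(tanh(zz[-drop]), nn[-drop])
    trim_and_fill(d, side = "right", published_only = FALSE)$statistic
  })
  expect_lt(abs(mean(k0_hat) - 5), 2)
})

test_that("excess significance is exact in the saturated case", {
  # every study huge: power ~ 1 and all significant -> E ~ O, p ~ 1
  ds <- make_ds(rep(-0.3, 6), rep(5000, 6))
  tes <- excess_significance(ds)
  expect_equal(tes$details$O, 6)
  expect_equal(tes$details$E, 6, tolerance = 1e-6)
  expect_gt(tes$p, 0.99)
})

test_that("p-curve is null-centered for uniform significant p-values and recovers truth", {
  # construct studies whose one-sided p-values are exactly uniform on the
  # significance region under theta = 0
  k <- 40
  n <- rep(250, k)
  pp <- (seq_len(k) - 0.5) / k
  z <- qnorm(1 - pp * 0.025) / sqrt(n - 3)
  ds0 <- make_ds(tanh(z), n)
  pc0 <- p_curve(ds0, published_only = FALSE)
  expect_lt(abs(pc0$adjusted_estimate_r), 0.01)
  # simulated truth rho = -0.20, tau2 = 0, only significant studies kept
  set.seed(55)
  rs <- ns <- c()
  while (length(rs) < 200) {
    n1 <- round(exp(runif(1, log(50), log(1500))))
    z1 <- rnorm(1, atanh(-0.20), sqrt(1 / (n1 - 3)))
    if (2 * pnorm(-abs(z1) * sqrt(n1 - 3)) < 0.05 && z1 < 0) {
      rs <- c(rs, tanh(z1)); ns <- c(ns, n1)
    }
  }
  pc <- p_curve(make_ds(rs, ns), published_only = FALSE)
  expect_lt(abs(pc$adjusted_estimate_r - (-0.20)), 0.02)
  expect_lt(pc$p, 0.001)   # strong right-skew: evidential value
  expect_error(p_curve(make_ds(c(-0.5, -0.4), c(100, 100)),
                       published_only = FALSE), ">= 5")
})

test_that("p-uniform solves the moment condition and its bias test calibrates", {
  # single-study degenerate case: estimate near the boundary effect
  ds1 <- make_ds(-0.31, 160)
  pu1 <- p_uniform(ds1, published_only = FALSE)
  expect_lt(pu1$adjusted_estimate_r, 0)
  # recovery under pure selection
  set.seed(56)
  rs <- ns <- c()
  while (length(rs) < 150) {
    n1 <- round(exp(runif(1, log(50), log(1500))))
    z1 <- rnorm(1, atanh(-0.20), sqrt(1 / (n1 - 3)))
    if (2 * pnorm(-abs(z1) * sqrt(n1 - 3)) < 0.05 && z1 < 0) {
      rs <- c(rs, tanh(z1)); ns <- c(ns, n1)
    }
  }
  pu <- p_uniform(make_ds(rs, ns), published_only = FALSE)
  expect_lt(abs(pu$adjusted_estimate_r - (-0.20)), 0.02)
  expect_true(pu$details$ci_r[1] < pu$adjusted_estimate_r &&
                pu$adjusted_estimate_r < pu$details$ci_r[2])
  # bias test: non-rejection rate ~ 95% on unselected data
  set.seed(57)
  nonrej <- replicate(400, {
    n <- round(exp(runif(60, log(200), log(3000))))
    d <- make_ds(tanh(rnorm(60, 0.25, sqrt(1 / (n - 3)))), n)
    p_uniform(d, published_only = FALSE)$p >= 0.05
  })
  expect_gt(mean(nonrej), 0.90)
})

test_that("p-uniform* matches unselected truth and handles the null", {
  # tau2 = 0, no selection, large k: estimate ~ FE pooled within 0.01
  set.seed(58)
  n <- round(exp(runif(400, log(50), log(3000))))
  z <- rnorm(400, atanh(0.15), sqrt(1 / (n - 3)))
  ds <- make_ds(tanh(z), n)
  ps <- p_uniform_star(ds, published_only = FALSE)
  fe <- rema(data = ds, estimator = "FE")
  expect_lt(abs(ps$adjusted_estimate_r - fe$estimate_r), 0.01)
  expect_lt(ps$details$tau2, 0.005)
  # all non-significant under a true null: estimate ~ 0
  set.seed(59)
  n0 <- rep(60, 80)
  z0 <- rnorm(80, 0, 0.4 / sqrt(57))          # shrunk so none significant
  ds0 <- make_ds(tanh(z0), n0)
  ps0 <- p_uniform_star(ds0, published_only = FALSE)
  expect_lt(abs(ps0$adjusted_estimate_r), 0.06)
})

test_that("funnel export carries contours for the published subset", {
  ds <- filter_studies(ri_studies(), published_only = TRUE)
  fd <- funnel_data(ds)
  expect_equal(nrow(fd), 88L)
  expect_true(all(fd$contour_99 > fd$contour_95 &
                    fd$contour_95 > fd$contour_90))
})
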