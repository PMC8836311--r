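test_that("pooling identical matrices returns that matrix exactly", {
  mats <- data.frame(study_id = paste0("s", 1:5), n = c(100, 200, 150, 120, 300),
                     r_xy = -0.17, r_xm = 0.40, r_my = -0.10)
  pm <- pool_matrices(mats)
  expect_equal(pm$matrix["x", "y"], -0.17, tolerance = 1e-12)
  expect_equal(pm$matrix["x", "m"], 0.40, tolerance = 1e-12)
  expect_equal(pm$matrix["m", "y"], -0.10, tolerance = 1e-12)
  expect_false(pm$psd_adjusted)
  expect_equal(pm$n_harmonic, 5 / sum(1 / mats$n))
  # aliases accepted; missing cells contribute nothing; empty cell errors
  mats2 <- data.frame(n = c(100, 200, 150),
                      r_ir = c(-0.2, -0.1, NA),
                      r_im = c(0.3, NA, 0.5),
                      r_mr = c(NA, NA, NA))
  expect_error(pool_matrices(mats2), "r_my")
})

test_that("partial correlation follows the closed form", {
  expect_equal(partial_correlation(0.31, 0, 0), 0.31)
  expect_equal(partial_correlation(0.5, 0.5, 0.5), 1 / 3, tolerance = 1e-12)
  expect_error(partial_correlation(0.2, 1, 0.3), "inside")
})

test_that("path algebra is exact: total = direct + indirect", {
  # uncorrelated mediator: indirect 0, direct = total
  M <- diag(3); dimnames(M) <- list(c("x", "m", "y"), c("x", "m", "y"))
  M["x", "y"] <- M["y", "x"] <- -0.3
  fit <- fit_mediation(M)
  expect_equal(fit$paths$indirect, 0)
  expect_equal(fit$paths$direct, fit$paths$total)
  # random PSD matrices: identity holds to 1e-10 and known paths recover
  set.seed(71)
  for (i in 1:25) {
    a <- runif(1, -0.7, 0.7); b <- runif(1, -0.7, 0.7)
    cp <- runif(1, -0.5, 0.5)
    r_xm <- a
    r_xy <- cp + a * b
    r_my <- b + a * cp
    if (abs(r_xy) >= 0.95 || abs(r_my) >= 0.95) next
    M <- matrix(c(1, r_xm, r_xy, r_xm, 1, r_my, r_xy, r_my, 1), 3, 3,
                dimnames = list(c("x", "m", "y"), c("x", "m", "y")))
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < 0.01) next
    f <- fit_mediation(M)
    expect_equal(f$paths$total, f$paths$direct + f$paths$indirect,
                 tolerance = 1e-10)
    expect_equal(f$paths$a, a, tolerance = 1e-10)
    expect_equal(f$paths$b, b, tolerance = 1e-10)
    expect_equal(f$paths$direct, cp, tolerance = 1e-10)
  }
})

test_that("simulated matrices recover a known population structure", {
  truth <- matrix(c(1, 0.5, -0.3, 0.5, 1, -0.35, -0.3, -0.35, 1), 3, 3,
                  dimnames = list(c("x", "m", "y"), c("x", "m", "y")))
  cfg <- sim_config(k = 50, mediation_truth = truth, n_range = c(300, 800),
                    seed = 9)
  mats <- simulate_correlation_matrices(cfg)
  expect_equal(nrow(mats), 50L)
  pm <- pool_matrices(mats)
  expect_lt(abs(pm$matrix["x", "m"] - 0.5), 0.02)
  expect_lt(abs(pm$matrix["x", "y"] - (-0.3)), 0.02)
  expect_lt(abs(pm$matrix["m", "y"] - (-0.35)), 0.02)
  # identity truth: cells near zero
  cfg0 <- sim_config(k = 50, mediation_truth = diag(3),
                     n_range = c(300, 800), seed = 10)
  pm0 <- pool_matrices(simulate_correlation_matrices(cfg0))
  expect_lt(max(abs(pm0$matrix[upper.tri(pm0$matrix)])), 0.02)
  # reproducibility from the seed
  m2 <- simulate_correlation_matrices(cfg)
  expect_identical(mats, m2)
})

test_that("full-mediation truth keeps the direct path inside its CI", {
  # truth: x -> m -> y with no direct path (a = 0.5, b = -0.4)
  truth <- matrix(c(1, 0.5, -0.2, 0.5, 1, -0.4, -0.2, -0.4, 1), 3, 3,
                  dimnames = list(c("x", "m", "y"), c("x", "m", "y")))
  set.seed(72)
  reps <- 200
  cover <- logical(reps)
  type <- character(reps)
  for (i in seq_len(reps)) {
    cfg <- sim_config(k = 30, mediation_truth = truth,
                      n_range = c(150, 600), seed = 1000 + i)
    pm <- pool_matrices(simulate_correlation_matrices(cfg))
    fit <- fit_mediation(pm, draws = 2000, seed = i)
    cover[i] <- fit$ci["direct", 1] <= 0 && fit$ci["direct", 2] >= 0
    type[i] <- fit$mediation_type
  }
  expect_gt(mean(cover), 0.90)
  expect_gt(mean(type == "full"), 0.80)
})

test_that("monte-carlo mediation intervals are seeded and ordered", {
  mats <- data.frame(n = round(runif(20, 100, 500)),
                     r_xy = tanh(rnorm(20, atanh(-0.2), 0.08)),
                     r_xm = tanh(rnorm(20, atanh(0.45), 0.08)),
                     r_my = tanh(rnorm(20, atanh(-0.3), 0.08)))
  pm <- pool_matrices(mats)
  f1 <- fit_mediation(pm, draws = 3000, seed = 3)
  f2 <- fit_mediation(pm, draws = 3000, seed = 3)
  expect_identical(f1$ci, f2$ci)
  expect_true(all(f1$ci[, 1] <= f1$ci[, 2]))
  expect_true(f1$mediation_type %in% c("none", "partial", "full"))
})
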