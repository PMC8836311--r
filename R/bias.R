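# Dissemination-bias methods. Every method operates on a
# direction-normalised scale: effects are flipped so that the summary is
# positive, and reported estimates are flipped back. By convention the
# methods default to the published subset, mirroring how they are used in
# practice.

.bias_report <- function(method, statistic = NA_real_, p = NA_real_,
                         adjusted_estimate_r = NA_real_, k_used = NA_integer_,
                         details = list()) {
  structure(list(method = method, statistic = statistic, p = p,
                 adjusted_estimate_r = adjusted_estimate_r,
                 k_used = k_used, details = details),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("%s (k = %s)\n", x$method, x$k_used))
  if (!is.na(x$statistic)) cat(sprintf("  statistic = %.4f", x$statistic))
  if (!is.na(x$p)) cat(sprintf(", p = %s", format.pval(x$p, digits = 3)))
  if (!is.na(x$statistic) || !is.na(x$p)) cat("\n")
  if (!is.na(x$adjusted_estimate_r)) {
    cat(sprintf("  adjusted estimate r = %.4f\n", x$adjusted_estimate_r))
  }
  keys <- setdiff(names(x$details), c("pp", "curve"))
  for (k in keys) {
    v <- x$details[[k]]
    if (is.numeric(v) && length(v) <= 3) {
      cat(sprintf("  %s = %s\n", k, paste(round(v, 4), collapse = ", ")))
    }
  }
  invisible(x)
}

# direction-normalised z effects for a dataset: flips so the FE summary is
# positive; returns the flip sign so estimates can be mapped back
.normalized_effects <- function(ds) {
  z <- atanh(ds$r)
  vi <- 1 / (ds$n - 3)
  fe <- .fe_fit(z, vi)
  flip <- if (fe$est < 0) -1 else 1
  list(z = flip * z, vi = vi, flip = flip)
}

.default_published <- function(ds, published_only) {
  if (published_only) filter_studies(ds, published_only = TRUE) else ds
}

#' Rank-correlation (Begg-Mazumdar) test for funnel asymmetry
#'
#' Kendall's tau between the variance-stabilised deviates
#' `(z_i - z_FE) / sqrt(v_i - 1/sum(w))` and the sampling variances, with
#' the tie-corrected normal approximation for the p-value. Significance is
#' conventionally judged at alpha = .10.
#'
#' @param ds A `meta_dataset`.
#' @param published_only Restrict to published records (default `TRUE`).
#' @return A `bias_report` with `statistic` = tau.
#' @export
begg_test <- function(ds, published_only = TRUE) {
  d <- .default_published(ds, published_only)
  if (nrow(d) < 3L) stop("begg_test() needs k >= 3", call. = FALSE)
  ne <- .normalized_effects(d)
  fe <- .fe_fit(ne$z, ne$vi)
  dev <- (ne$z - fe$est) / sqrt(ne$vi - 1 / fe$sw)
  ct <- stats::cor.test(dev, ne$vi, method = "kendall", exact = FALSE)
  .bias_report("Begg-Mazumdar rank correlation",
               statistic = unname(ct$estimate), p = ct$p.value,
               k_used = nrow(d), details = list(alpha_convention = 0.10))
}

#' Egger-type regression test for funnel asymmetry
#'
#' Regresses the standard normal deviates `z_i / se_i` on precision
#' `1/se_i` (ordinary least squares) and tests the intercept against zero
#' with a normal reference. A non-zero intercept indicates small-study
#' asymmetry.
#'
#' @inheritParams begg_test
#' @return A `bias_report`; `statistic` is the intercept z-statistic,
#'   `details` carries intercept, slope and their standard errors.
#' @export
egger_test <- function(ds, published_only = TRUE) {
  d <- .default_published(ds, published_only)
  if (nrow(d) < 3L) stop("egger_test() needs k >= 3", call. = FALSE)
  ne <- .normalized_effects(d)
  se <- sqrt(ne$vi)
  if (stats::sd(1 / se) < .Machine$double.eps^0.5) {
    stop("identical precisions: regression design is singular",
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, 1 / se), ne$z / se)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / fit$df.residual
  XtXinv <- chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE])
  se_b <- sqrt(diag(XtXinv) * sigma2)
  zval <- fit$coefficients[1L] / se_b[1L]
  .bias_report("Egger regression test",
               statistic = unname(zval),
               p = 2 * stats::pnorm(-abs(zval)),
               k_used = nrow(d),
               details = list(intercept = unname(fit$coefficients[1L]),
                              intercept_se = se_b[1L],
                              slope = unname(fit$coefficients[2L]),
                              slope_se = se_b[2L]))
}

#' Trim-and-fill estimate of funnel-missing studies
#'
#' Duval-Tweedie iterative rank-based estimation of the number of studies
#' `k0` missing on one side of the funnel plot, followed by imputation of
#' their mirror images and re-pooling. The default `side = "opposite"`
#' places the suspected missing studies opposite the observed summary sign
#' (for a negative summary that is the right-hand, positive side).
#'
#' @param ds A `meta_dataset`.
#' @param side `"opposite"`, `"left"` or `"right"` (in original r units).
#' @param estimator `"L0"` (default) or `"R0"` rank estimator for `k0`.
#' @param pool_estimator Estimator used for re-pooling, default `"DL"`.
#' @param maxiter Iteration cap (convergence is declared when `k0`
#'   stabilises).
#' @param published_only Restrict to published records (default `TRUE`).
#' @return A `bias_report`; `statistic` = `k0`, `adjusted_estimate_r` is the
#'   re-pooled estimate including imputed studies; `details` carries the
#'   imputed effects, the unadjusted estimate and a convergence flag.
#' @export
trim_and_fill <- function(ds, side = c("opposite", "left", "right"),
                          estimator = c("L0", "R0"),
                          pool_estimator = "DL", maxiter = 50L,
                          published_only = TRUE) {
  side <- match.arg(side)
  estimator <- match.arg(estimator)
  d <- .default_published(ds, published_only)
  if (nrow(d) < 3L) stop("trim_and_fill() needs k >= 3", call. = FALSE)
  z <- atanh(d$r)
  vi <- 1 / (d$n - 3)
  fe <- .fe_fit(z, vi)
  if (side == "opposite") side <- if (fe$est < 0) "right" else "left"
  # canonical orientation: missing studies on the left, their extreme
  # counterparts trimmed from the right and mirrored back
  sgn <- if (side == "right") -1 else 1
  y <- sgn * z
  k <- length(y)
  k0 <- 0L
  converged <- FALSE
  for (it in seq_len(maxiter)) {
    use <- seq_len(k)
    if (k0 > 0L) use <- order(y)[seq_len(k - k0)]  # trim the k0 rightmost
    theta <- .fit_est(y[use], vi[use], pool_estimator)$est
    dev <- y - theta
    rk <- rank(abs(dev))
    if (estimator == "L0") {
      Tn <- sum(rk[dev > 0])
      k0_new <- max(0, round((4 * Tn - k * (k + 1)) / (2 * k - 1)))
    } else {
      # R0: length of the run of positive deviates occupying the top ranks
      ord <- order(rk, decreasing = TRUE)
      run <- 0L
      for (j in ord) {
        if (dev[j] > 0) run <- run + 1L else break
      }
      k0_new <- max(0L, run - 1L)
    }
    k0_new <- min(k0_new, k - 2L)
    if (k0_new == k0) { converged <- TRUE; break }
    k0 <- k0_new
  }
  unadj <- .fit_est(y, vi, pool_estimator)
  if (k0 > 0L) {
    use <- order(y)[seq_len(k - k0)]
    theta <- .fit_est(y[use], vi[use], pool_estimator)$est
    imp_idx <- order(y, decreasing = TRUE)[seq_len(k0)]
    y_imp <- 2 * theta - y[imp_idx]
    adj <- .fit_est(c(y, y_imp), c(vi, vi[imp_idx]), pool_estimator)
    imputed_r <- tanh(sgn * y_imp)
  } else {
    adj <- unadj
    imputed_r <- numeric(0)
  }
  .bias_report("Trim-and-fill",
               statistic = k0,
               adjusted_estimate_r = tanh(sgn * adj$est),
               k_used = k,
               details = list(side = side, estimator = estimator,
                              k0 = k0, converged = converged,
                              unadjusted_estimate_r = tanh(sgn * unadj$est),
                              imputed_r = imputed_r))
}

#' Test of excess significance
#'
#' Computes each study's power to detect the pooled summary effect with a
#' two-sided z-test at level `alpha`, counting only the hypothesis-conforming
#' tail: `power_i = pnorm(|theta| * sqrt(n_i - 3) - z_{alpha/2})`. The
#' expected number of significant, direction-conforming studies `E` is the
#' sum of the powers; the observed count `O` uses p-values recomputed from
#' `(r, n)`. `O` and `E` are compared by the chi-square statistic
#' `A = (O-E)^2/E + (O-E)^2/(k-E)`; an excess (`O > E`) indicates bias.
#'
#' @param ds A `meta_dataset` (all records by default; pass the published
#'   subset to restrict).
#' @param alpha Two-sided significance level.
#' @param pooled Optional `rema` fit supplying the summary effect; default
#'   is the DL fit of `ds` itself.
#' @return A `bias_report`; `statistic` = A, `details` carries `O`, `E`,
#'   `mean_power`.
#' @export
excess_significance <- function(ds, alpha = 0.05, pooled = NULL) {
  if (nrow(ds) < 2L) stop("excess_significance() needs k >= 2",
                          call. = FALSE)
  if (is.null(pooled)) pooled <- rema(data = ds, estimator = "DL")
  theta <- abs(pooled$estimate)
  sgn <- sign(pooled$estimate)
  if (sgn == 0) sgn <- 1
  zcrit <- stats::qnorm(1 - alpha / 2)
  pow <- stats::pnorm(theta * sqrt(ds$n - 3) - zcrit)
  E <- sum(pow)
  p2 <- p_value_z(ds$r, ds$n)
  O <- sum(p2 < alpha & sign(ds$r) == sgn)
  k <- nrow(ds)
  # second term vanishes as E -> k (all studies expected significant)
  A <- (O - E)^2 / E + if (k - E > 1e-8) (O - E)^2 / (k - E) else 0
  .bias_report("Test of excess significance",
               statistic = A,
               p = stats::pchisq(A, 1L, lower.tail = FALSE),
               k_used = k,
               details = list(O = O, E = E, mean_power = mean(pow),
                              excess = O > E))
}

# conditional (pp) value machinery, on the direction-normalised z scale:
# pp_i(theta) = P(Z > z_i | Z > c_i) for Z ~ N(theta, v_i), c_i the
# one-tailed critical value at alpha/2. Computed in log space for stability.
.log_pp <- function(z, se, crit, theta) {
  stats::pnorm((z - theta) / se, lower.tail = FALSE, log.p = TRUE) -
    stats::pnorm((crit - theta) / se, lower.tail = FALSE, log.p = TRUE)
}

# significant, direction-conforming subset on the normalised scale
.sig_subset <- function(ds, alpha) {
  ne <- .normalized_effects(ds)
  se <- sqrt(ne$vi)
  crit <- stats::qnorm(1 - alpha / 2) * se
  keep <- ne$z > crit
  list(z = ne$z[keep], se = se[keep], crit = crit[keep], flip = ne$flip,
       k = sum(keep))
}

#' p-curve analysis
#'
#' Works on the significant, direction-conforming studies (two-sided
#' `alpha`, significance recomputed from `(r, n)`). Reports (i) the
#' right-skew (evidential value) test: Stouffer aggregation of the
#' conditional p-values under the null of no effect; (ii) the 33%-power
#' flatness test; and (iii) the effect estimate: the Fisher-z value whose
#' implied conditional-p distribution minimises the Kolmogorov-Smirnov
#' distance from uniform (bounded search, tolerance 1e-6).
#'
#' @param ds A `meta_dataset`; by default the published subset is selected
#'   first.
#' @param alpha Two-sided selection threshold.
#' @param published_only Restrict to published records first.
#' @return A `bias_report`; `adjusted_estimate_r` is the p-curve estimate,
#'   `statistic`/`p` the right-skew Stouffer test; `details` carries the
#'   33%-power test and the KS distance.
#' @export
p_curve <- function(ds, alpha = 0.05, published_only = TRUE) {
  d <- .default_published(ds, published_only)
  ss <- .sig_subset(d, alpha)
  if (ss$k < 5L) {
    stop("p_curve() needs >= 5 significant direction-conforming studies",
         call. = FALSE)
  }
  k <- ss$k
  # right-skew test under theta = 0 (log-scale qnorm avoids underflow for
  # very large samples, whose conditional p-values are astronomically small)
  lpp0 <- .log_pp(ss$z, ss$se, ss$crit, 0)
  zsk <- sum(stats::qnorm(lpp0, log.p = TRUE)) / sqrt(k)
  p_right <- stats::pnorm(zsk)
  # 33%-power test: per-study theta with power 1/3 at this alpha
  th33 <- ss$crit + stats::qnorm(1 / 3) * ss$se
  lpp33 <- .log_pp(ss$z, ss$se, ss$crit, th33)
  z33 <- sum(stats::qnorm(lpp33, log.p = TRUE)) / sqrt(k)
  p_flat <- stats::pnorm(z33, lower.tail = FALSE)
  # KS estimate
  ksd <- function(theta) {
    pp <- sort(exp(.log_pp(ss$z, ss$se, ss$crit, theta)))
    i <- seq_len(k)
    max(pmax(abs(pp - i / k), abs(pp - (i - 1) / k)))
  }
  opt <- stats::optimize(ksd, c(-0.5, 1.5), tol = 1e-6)
  est <- ss$flip * opt$minimum
  .bias_report("p-curve",
               statistic = zsk, p = p_right,
               adjusted_estimate_r = tanh(est),
               k_used = k,
               details = list(z_right_skew = zsk, p_right_skew = p_right,
                              z_33 = z33, p_flatness = p_flat,
                              ks_distance = opt$objective,
                              pp = exp(lpp0)))
}

#' p-uniform effect estimation and publication-bias test
#'
#' The estimate solves the moment condition `sum(pp_i(theta)) = k/2` on the
#' conditional p-values of the significant, direction-conforming studies
#' (method `"P"`, the default); `"LNP"` instead solves
#' `sum(-log pp_i(theta)) = k`. Confidence limits invert the same statistic
#' at the normal approximation to its null quantiles (`k/2 +- z * sqrt(k/12)`
#' for `"P"`, Gamma(k, 1) quantiles for `"LNP"`). The publication-bias test
#' evaluates the conditional p-values at the fixed-effect estimate of the
#' selected studies and reports the one-sided left-skew z-test.
#'
#' @inheritParams p_curve
#' @param method `"P"` (moment, default) or `"LNP"`.
#' @param level Confidence level for the inverted interval.
#' @return A `bias_report`; `adjusted_estimate_r` is the estimate,
#'   `statistic`/`p` the publication-bias test; `details` carries the CI.
#' @export
p_uniform <- function(ds, alpha = 0.05, method = c("P", "LNP"),
                      level = 0.95, published_only = TRUE) {
  method <- match.arg(method)
  d <- .default_published(ds, published_only)
  ss <- .sig_subset(d, alpha)
  if (ss$k < 1L) {
    stop("p_uniform() needs >= 1 significant direction-conforming study",
         call. = FALSE)
  }
  k <- ss$k
  stat <- function(theta) {
    lpp <- .log_pp(ss$z, ss$se, ss$crit, theta)
    if (method == "P") sum(exp(lpp)) else sum(-lpp)
  }
  # target values at the estimate and the CI bounds
  a2 <- (1 - level) / 2
  if (method == "P") {
    targets <- k / 2 + c(0, stats::qnorm(1 - a2), -stats::qnorm(1 - a2)) *
      sqrt(k / 12)
  } else {
    targets <- c(k, stats::qgamma(c(a2, 1 - a2), shape = k))
  }
  solve_one <- function(target) {
    g <- function(th) stat(th) - target
    lo <- -2; hi <- 2
    for (i in 0:4) {
      flo <- g(lo); fhi <- g(hi)
      if (is.finite(flo) && is.finite(fhi) && flo * fhi <= 0) {
        return(stats::uniroot(g, c(lo, hi), tol = 1e-6)$root)
      }
      lo <- lo * 2; hi <- hi * 2
    }
    NA_real_
  }
  est <- solve_one(targets[1L])
  if (is.na(est)) stop("p_uniform(): no root for the moment condition",
                       call. = FALSE)
  b1 <- solve_one(targets[2L])
  b2 <- solve_one(targets[3L])
  ci <- sort(c(b1, b2))
  # bias test at the FE estimate of the selected studies
  thfe <- .fe_fit(ss$z, ss$se^2)$est
  ppfe <- exp(.log_pp(ss$z, ss$se, ss$crit, thfe))
  L <- (sum(ppfe) - k / 2) / sqrt(k / 12)
  .bias_report("p-uniform",
               statistic = L, p = stats::pnorm(L),
               adjusted_estimate_r = tanh(ss$flip * est),
               k_used = k,
               details = list(method = method,
                              ci_r = sort(tanh(ss$flip * ci)),
                              estimate_z = ss$flip * est))
}

#' p-uniform* joint estimation of effect and heterogeneity
#'
#' Extends p-uniform to all (published) studies: each study's Fisher-z
#' effect is modelled as `N(theta, v_i + tau^2)` truncated to its own
#' significance stratum (significant vs non-significant at two-sided
#' `alpha`), under the assumption that the two strata have internally
#' constant publication probabilities. `(theta, tau^2)` maximise the
#' conditional likelihood (bounded 2-D optimisation, `tau^2 >= 0`).
#'
#' @inheritParams p_curve
#' @return A `bias_report`; `adjusted_estimate_r` is the estimate;
#'   `details` carries `tau2`, the stratum counts and a convergence flag
#'   (on failure the last iterate is returned with `converged = FALSE`).
#' @export
p_uniform_star <- function(ds, alpha = 0.05, published_only = TRUE) {
  d <- .default_published(ds, published_only)
  if (nrow(d) < 3L) stop("p_uniform_star() needs k >= 3", call. = FALSE)
  ne <- .normalized_effects(d)
  se <- sqrt(ne$vi)
  crit <- stats::qnorm(1 - alpha / 2) * se
  sig <- abs(ne$z) > crit
  # the conditional likelihood stays identified with a single stratum
  # (e.g. a body of uniformly non-significant studies under a true null)
  nll <- function(par) {
    theta <- par[1L]
    t2 <- par[2L]
    s <- sqrt(ne$vi + t2)
    p_out <- stats::pnorm((crit - theta) / s, lower.tail = FALSE) +
      stats::pnorm((-crit - theta) / s)
    p_strat <- ifelse(sig, p_out, 1 - p_out)
    -sum(stats::dnorm(ne$z, theta, s, log = TRUE) -
           log(pmax(p_strat, 1e-300)))
  }
  start <- c(.fe_fit(ne$z, ne$vi)$est, max(.tau2_dl(ne$z, ne$vi), 1e-4))
  opt <- try(stats::optim(start, nll, method = "L-BFGS-B",
                          lower = c(-3, 0), upper = c(3, 2),
                          control = list(factr = 1e7)), silent = TRUE)
  if (inherits(opt, "try-error")) {
    return(.bias_report("p-uniform*", k_used = nrow(d),
                        details = list(converged = FALSE,
                                       last_iterate = start)))
  }
  .bias_report("p-uniform*",
               adjusted_estimate_r = tanh(ne$flip * opt$par[1L]),
               k_used = nrow(d),
               details = list(tau2 = opt$par[2L],
                              k_significant = sum(sig),
                              k_nonsignificant = sum(!sig),
                              converged = opt$convergence == 0))
}

#' Run the full dissemination-bias battery
#'
#' Applies all seven methods with their conventional defaults (published
#' subset; the excess-significance test is reported for both the full and
#' the published set, since either reading of "the primary studies" is
#' defensible).
#'
#' @param ds A `meta_dataset`.
#' @param alpha Two-sided significance level for selection-based methods.
#' @return Named list of `bias_report` objects.
#' @export
bias_battery <- function(ds, alpha = 0.05) {
  pub <- filter_studies(ds, published_only = TRUE)
  list(
    begg = begg_test(ds),
    egger = egger_test(ds),
    trim_and_fill = trim_and_fill(ds),
    tes_all = excess_significance(ds, alpha = alpha),
    tes_published = excess_significance(pub, alpha = alpha,
                                        pooled = rema(data = ds)),
    p_curve = p_curve(ds, alpha = alpha),
    p_uniform = p_uniform(ds, alpha = alpha),
    p_uniform_star = p_uniform_star(ds, alpha = alpha)
  )
}

#' Funnel-plot data with significance contours
#'
#' One row per study: correlation, Fisher-z effect, standard error, plus the
#' two-sided significance contour half-widths at the .10/.05/.01 levels.
#'
#' @param ds A `meta_dataset`.
#' @return A `data.frame` suitable for contour-enhanced funnel plotting.
#' @export
funnel_data <- function(ds) {
  z <- atanh(ds$r)
  se <- sqrt(1 / (ds$n - 3))
  data.frame(study_id = ds$study_id, r = ds$r, z = z, se = se,
             contour_90 = stats::qnorm(0.95) * se,
             contour_95 = stats::qnorm(0.975) * se,
             contour_99 = stats::qnorm(0.995) * se)
}
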