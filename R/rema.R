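#' Random-effects meta-analysis of correlations
#'
#' Pools per-study Pearson correlations (or pre-computed effects) under one
#' of four estimators. The default pipeline transforms correlations to
#' Fisher z, pools with inverse-variance weights `1/(v_i + tau^2)`, and
#' back-transforms the summary and its Wald confidence limits to the
#' correlation scale.
#'
#' Estimators:
#' \describe{
#'   \item{`DL`}{DerSimonian-Laird: `tau^2 = max(0, (Q - df) / (S1 - S2/S1))`
#'     with `S1 = sum(w)`, `S2 = sum(w^2)` under fixed-effect weights.}
#'   \item{`REML`}{restricted maximum likelihood, bounded one-dimensional
#'     optimisation of the restricted log-likelihood (tolerance 1e-10,
#'     `tau^2` clipped at zero).}
#'   \item{`FE`}{fixed effect, `tau^2 = 0`.}
#'   \item{`UNWEIGHTED`}{arithmetic mean with `SE = sd/sqrt(k)`.}
#' }
#'
#' Cochran's Q is always computed under fixed-effect weights. Two flavours
#' of I-squared are reported: `I2` (the Q-based
#' `max(0, (Q - df)/Q) * 100`) and `I2_tau2`
#' (`100 * tau^2 / (tau^2 + s^2)` with `s^2` the "typical" within-study
#' variance `(k-1) S1 / (S1^2 - S2)`); the latter is what mixed-effects
#' meta-analysis software prints and is the one quoted alongside
#' REML summaries.
#'
#' @param r Correlations, or `NULL` when `y`/`vi` are given directly.
#' @param n Sample sizes matching `r`.
#' @param data Optional `meta_dataset`; when supplied, `r` and `n` are taken
#'   from its columns.
#' @param y,vi Pre-computed effects and sampling variances (overrides
#'   `r`/`n`; no transformation is applied beyond `metric` bookkeeping).
#' @param estimator `"DL"`, `"REML"`, `"FE"` or `"UNWEIGHTED"`.
#' @param metric `"z"` (Fisher z, variance `1/(n-3)`), `"r"` (raw
#'   correlation, variance `(1-r^2)^2/(n-1)`) or `"nw"` (raw correlation,
#'   n-proportional weights).
#' @param level Confidence level, default 0.95.
#' @param labels Optional study labels.
#' @return An object of class `"rema"` with components `estimate` (pooled
#'   value on the analysis metric), `estimate_r`, `se`, `ci_low_r`,
#'   `ci_high_r`, `k`, `Q`, `df`, `p_Q`, `I2`, `I2_tau2`, `tau2`, `p`
#'   (two-sided test of a null summary), `estimator`, `metric`, and the
#'   per-study `y`, `vi`, `labels`.
#' @examples
#' fit <- rema(data = ri_studies())
#' fit
#' coef(fit)
#' confint(fit)
#' @export
rema <- function(r = NULL, n = NULL, data = NULL, y = NULL, vi = NULL,
                 estimator = c("DL", "REML", "FE", "UNWEIGHTED"),
                 metric = c("z", "r", "nw"), level = 0.95, labels = NULL) {
  estimator <- match.arg(estimator)
  metric <- match.arg(metric)
  .check_level(level)
  if (!is.null(data)) {
    r <- data$r
    n <- data$n
    if (is.null(labels)) labels <- data$study_id
  }
  if (is.null(y)) {
    stopifnot(!is.null(r), !is.null(n), length(r) == length(n))
    if (any(abs(r) >= 1)) stop("|r| < 1 required", call. = FALSE)
    if (any(n < 4)) stop("n >= 4 required", call. = FALSE)
    me <- .metric_effects(r, n, metric)
    y <- me$y
    vi <- me$vi
  } else {
    stopifnot(!is.null(vi), length(vi) == length(y))
  }
  if (any(vi <= 0)) stop("sampling variances must be positive", call. = FALSE)
  k <- length(y)
  if (is.null(labels)) labels <- paste0("study_", seq_len(k))

  f <- .fit_est(y, vi, estimator)
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  ci <- f$est + c(-1, 1) * zcrit * f$se
  df <- k - 1L
  I2 <- if (k > 1L && is.finite(f$Q) && f$Q > 0) {
    max(0, (f$Q - df) / f$Q) * 100
  } else if (k > 1L) 0 else NA_real_
  I2_tau2 <- NA_real_
  if (k > 1L && !is.na(f$tau2)) {
    fe <- .fe_fit(y, vi)
    s2 <- df * fe$sw / (fe$sw^2 - fe$sw2)
    I2_tau2 <- 100 * f$tau2 / (f$tau2 + s2)
  }
  structure(list(
    estimate = f$est,
    estimate_r = .to_r(f$est, metric),
    se = f$se,
    ci_low_r = .to_r(ci[1L], metric),
    ci_high_r = .to_r(ci[2L], metric),
    k = k, Q = f$Q, df = df,
    p_Q = if (k > 1L && is.finite(f$Q)) {
      stats::pchisq(f$Q, df, lower.tail = FALSE)
    } else NA_real_,
    I2 = I2, I2_tau2 = I2_tau2, tau2 = f$tau2,
    p = 2 * stats::pnorm(-abs(f$est / f$se)),
    estimator = estimator, metric = metric, level = level,
    y = y, vi = vi, labels = labels
  ), class = "rema")
}

#' Verbal label for an I-squared value
#'
#' Conventional bands: 0-25\% trivial, 25-50\% small, 50-75\% moderate,
#' 75-100\% large.
#'
#' @param I2 I-squared percentage(s).
#' @return Character vector of labels.
#' @export
i2_label <- function(I2) {
  cut(I2, c(-Inf, 25, 50, 75, Inf),
      labels = c("trivial", "small", "moderate", "large"))
}

#' @export
print.rema <- function(x, digits = 4, ...) {
  cat(sprintf("Random-effects meta-analysis (%s estimator, %s metric)\n",
              x$estimator, x$metric))
  cat(sprintf("k = %d  r = %.*f  %g%% CI [%.*f, %.*f]  p = %s\n",
              x$k, 3, x$estimate_r, 100 * x$level, 3, x$ci_low_r, 3,
              x$ci_high_r, format.pval(x$p, digits = 3)))
  if (!is.na(x$Q)) {
    cat(sprintf("Q(df = %d) = %.3f, p = %s;  I2 = %.2f%%;  tau2 = %s\n",
                x$df, x$Q, format.pval(x$p_Q, digits = 3), x$I2,
                if (is.na(x$tau2)) "n/a" else formatC(x$tau2, digits = 4,
                                                     format = "f")))
  }
  invisible(x)
}

#' @export
summary.rema <- function(object, ...) {
  out <- object
  class(out) <- c("summary.rema", "rema")
  out
}

#' @export
print.summary.rema <- function(x, ...) {
  print.rema(x)
  if (!is.na(x$I2_tau2)) {
    cat(sprintf("I2 (tau2-based) = %.2f%% (%s heterogeneity)\n",
                x$I2_tau2, i2_label(x$I2_tau2)))
  }
  res <- residuals.rema(x, type = "standardized")
  cat(sprintf("largest |standardized residual|: %.2f (%s)\n",
              max(abs(res)), x$labels[which.max(abs(res))]))
  invisible(x)
}

#' @export
coef.rema <- function(object, ...) {
  c(estimate = object$estimate, estimate_r = object$estimate_r)
}

#' @export
confint.rema <- function(object, parm, level = NULL, ...) {
  level <- if (is.null(level)) object$level else .check_level(level)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  ci <- object$estimate + c(-1, 1) * zc * object$se
  out <- matrix(.to_r(ci, object$metric), nrow = 1,
                dimnames = list("estimate_r",
                                sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                           1 - (1 - level) / 2))))
  out
}

#' @export
weights.rema <- function(object, ...) {
  t2 <- if (is.na(object$tau2)) 0 else object$tau2
  w <- if (object$estimator == "UNWEIGHTED") {
    rep(1 / object$k, object$k)
  } else {
    wi <- 1 / (object$vi + t2)
    wi / sum(wi)
  }
  stats::setNames(w, object$labels)
}

#' Residuals of a pooled meta-analysis
#'
#' @param object A `rema` fit.
#' @param type `"raw"` (`y_i - theta`) or `"standardized"`
#'   (`(y_i - theta)/sqrt(v_i + tau^2)`).
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
residuals.rema <- function(object, type = c("standardized", "raw"), ...) {
  type <- match.arg(type)
  res <- object$y - object$estimate
  if (type == "standardized") {
    t2 <- if (is.na(object$tau2)) 0 else object$tau2
    res <- res / sqrt(object$vi + t2)
  }
  stats::setNames(res, object$labels)
}

#' Predicted summary correlation (and prediction interval)
#'
#' `predict()` returns the pooled correlation with its confidence interval
#' and, for random-effects fits, the prediction interval for the true effect
#' of a new study (`theta +- z * sqrt(se^2 + tau^2)`), all on the r scale.
#'
#' @param object A `rema` fit.
#' @param level Confidence level (defaults to the fit's).
#' @param ... Unused.
#' @return A one-row `data.frame`.
#' @export
predict.rema <- function(object, level = NULL, ...) {
  level <- if (is.null(level)) object$level else .check_level(level)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  t2 <- if (is.na(object$tau2)) 0 else object$tau2
  ci <- object$estimate + c(-1, 1) * zc * object$se
  pi <- object$estimate + c(-1, 1) * zc * sqrt(object$se^2 + t2)
  data.frame(
    estimate_r = object$estimate_r,
    ci_low_r = .to_r(ci[1L], object$metric),
    ci_high_r = .to_r(ci[2L], object$metric),
    pi_low_r = .to_r(pi[1L], object$metric),
    pi_high_r = .to_r(pi[2L], object$metric)
  )
}

#' Parametric simulation from a fitted meta-analysis
#'
#' Draws new per-study effects on the analysis metric. Under `null = FALSE`
#' each study's effect is `N(theta, v_i + tau^2)`; under `null = TRUE` the
#' expected value is zero and the standard deviation is the study's
#' fixed-effect sampling standard error `sqrt(v_i)` - the resampling scheme
#' of the specification-curve null test.
#'
#' @param object A `rema` fit.
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed.
#' @param null Simulate under the no-effect hypothesis.
#' @param ... Unused.
#' @return A `k x nsim` matrix of simulated effects.
#' @export
simulate.rema <- function(object, nsim = 1, seed = NULL, null = FALSE, ...) {
  if (!is.null(seed)) set.seed(seed)
  t2 <- if (is.na(object$tau2)) 0 else object$tau2
  mu <- if (null) 0 else object$estimate
  sdv <- if (null) sqrt(object$vi) else sqrt(object$vi + t2)
  matrix(stats::rnorm(object$k * nsim, mean = mu, sd = rep(sdv, nsim)),
         nrow = object$k, ncol = nsim,
         dimnames = list(object$labels, NULL))
}

#' Forest-style plot of a pooled meta-analysis
#'
#' Base-graphics forest plot: per-study effects with confidence whiskers,
#' ordered as supplied, and the pooled summary at the bottom.
#'
#' @param x A `rema` fit.
#' @param max_studies Studies beyond this count are thinned for legibility.
#' @param ... Passed to `plot.default`.
#' @export
plot.rema <- function(x, max_studies = 60L, ...) {
  ord <- seq_len(x$k)
  if (x$k > max_studies) ord <- round(seq(1, x$k, length.out = max_studies))
  y <- x$y[ord]
  se <- sqrt(x$vi[ord])
  zc <- stats::qnorm(1 - (1 - x$level) / 2)
  yy <- rev(seq_along(ord))
  xlim <- range(c(y - zc * se, y + zc * se, 0))
  graphics::plot(y, yy, pch = 15, xlim = xlim, yaxt = "n",
                 xlab = sprintf("effect (%s metric)", x$metric),
                 ylab = "", ...)
  graphics::segments(y - zc * se, yy, y + zc * se, yy)
  graphics::abline(v = 0, lty = 3)
  graphics::abline(v = x$estimate, col = 2, lty = 2)
  graphics::points(x$estimate, 0, pch = 18, col = 2, cex = 1.5)
  invisible(x)
}
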