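# Internal fitting engines shared by rema(), the multiverse, GOSH and the
# bootstrap. Deliberately free of S3 overhead: these run hundreds of
# thousands of times inside resampling loops.

# Fixed-effect (inverse-variance) summary plus Cochran Q.
.fe_fit <- function(y, vi) {
  w <- 1 / vi
  sw <- sum(w)
  est <- sum(w * y) / sw
  Q <- sum(w * (y - est)^2)
  list(est = est, se = sqrt(1 / sw), Q = Q, sw = sw, sw2 = sum(w^2))
}

# DerSimonian-Laird moment estimator of the between-study variance.
.tau2_dl <- function(y, vi) {
  k <- length(y)
  if (k < 2L) return(0)
  fe <- .fe_fit(y, vi)
  denom <- fe$sw - fe$sw2 / fe$sw
  if (denom <= 0) return(0)
  max(0, (fe$Q - (k - 1)) / denom)
}

# Restricted maximum-likelihood estimator of tau2 (intercept-only model),
# by bounded 1-D minimisation of the restricted negative log-likelihood.
.tau2_reml <- function(y, vi, tol = 1e-10) {
  k <- length(y)
  if (k < 2L) return(0)
  nll <- function(t2) {
    wi <- 1 / (vi + t2)
    mu <- sum(wi * y) / sum(wi)
    0.5 * (sum(log(vi + t2)) + sum(wi * (y - mu)^2) + log(sum(wi)))
  }
  upper <- max(10 * stats::var(y), 10 * mean(vi), 1e-3)
  opt <- stats::optimize(nll, c(0, upper), tol = tol)
  # the optimum can sit on the boundary; prefer exact zero when flat there
  if (opt$minimum < sqrt(tol) && nll(0) <= opt$objective + tol) return(0)
  opt$minimum
}

# One-stop estimator dispatch. Returns the pooled location, its standard
# error, tau2, and FE-weight heterogeneity statistics. `estimator` is one of
# FE, DL, REML, UNWEIGHTED.
.fit_est <- function(y, vi, estimator = "DL") {
  k <- length(y)
  if (k == 1L) {
    est <- y
    se <- if (estimator == "UNWEIGHTED") NA_real_ else sqrt(vi)
    return(list(est = est, se = se, k = 1L, Q = NA_real_, tau2 = 0))
  }
  fe <- .fe_fit(y, vi)
  if (estimator == "FE") {
    return(list(est = fe$est, se = fe$se, k = k, Q = fe$Q, tau2 = 0))
  }
  if (estimator == "UNWEIGHTED") {
    return(list(est = mean(y), se = stats::sd(y) / sqrt(k), k = k,
                Q = fe$Q, tau2 = NA_real_))
  }
  t2 <- switch(estimator,
    DL = .tau2_dl(y, vi),
    REML = .tau2_reml(y, vi),
    stop("unknown estimator: ", estimator)
  )
  wi <- 1 / (vi + t2)
  list(est = sum(wi * y) / sum(wi), se = sqrt(1 / sum(wi)), k = k,
       Q = fe$Q, tau2 = t2)
}

# Effect/variance pair for a given metric.
#   z  : Fisher z, vi = 1/(n-3)
#   r  : raw correlation, vi = (1-r^2)^2/(n-1)
#   nw : raw correlation with n-proportional weights (vi = 1/n), the
#        Hunter-Schmidt-style "bare bones" synthesis
.metric_effects <- function(r, n, metric = "z") {
  switch(metric,
    z  = list(y = atanh(r), vi = 1 / (n - 3)),
    r  = list(y = r, vi = (1 - r^2)^2 / (n - 1)),
    nw = list(y = r, vi = 1 / n),
    stop("unknown metric: ", metric)
  )
}

# Back-transform a pooled location to the correlation scale.
.to_r <- function(est, metric) if (metric == "z") tanh(est) else est

.check_level <- function(level) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  level
}
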