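#' Precision-weighted meta-regression
#'
#' Mixed-effects weighted least squares of per-study effects (Fisher-z
#' scale by default) on one or more numeric moderators. Residual
#' between-study variance is estimated either by the DerSimonian-Laird-type
#' moment estimator on the weighted residuals
#' (`tau2 = max(0, (Q_E - (k - p)) / tr(P))`) or by REML (the default);
#' coefficients are then re-estimated with weights `1/(v_i + tau^2)`.
#' `R^2` is the proportional reduction in `tau^2` relative to the
#' intercept-only model fitted with the same estimator.
#'
#' Records with a missing moderator value are dropped; the count of dropped
#' rows is recorded on the result.
#'
#' @param ds A `meta_dataset`.
#' @param moderators Character vector of moderator column names, or a named
#'   list/data.frame of numeric vectors. `pct_men` is already stored as a
#'   proportion in \[0, 1\], so its slope is on the proportion scale.
#' @param estimator `"REML"` (default) or `"DL"` for the residual
#'   heterogeneity.
#' @param metric Effect metric (see [rema()]).
#' @return Object of class `"rema_reg"`: `coefficients`, `se`, `zval`, `p`,
#'   `QM` (omnibus moderator chi-square), `df_M`, `p_M`, `QE` (residual
#'   heterogeneity), `tau2`, `tau2_null`, `R2`, `k`, `n_dropped`.
#' @examples
#' meta_regress(ri_studies(), "pct_men")
#' @export
meta_regress <- function(ds, moderators, estimator = c("REML", "DL"),
                         metric = "z") {
  estimator <- match.arg(estimator)
  if (is.character(moderators)) {
    bad <- setdiff(moderators, names(ds))
    if (length(bad)) stop("no moderator column(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    X0 <- as.data.frame(ds)[, moderators, drop = FALSE]
  } else {
    X0 <- as.data.frame(moderators)
  }
  keep <- stats::complete.cases(X0)
  n_dropped <- sum(!keep)
  d <- ds[keep, , drop = FALSE]
  X <- cbind(intercept = 1, as.matrix(X0[keep, , drop = FALSE]))
  k <- nrow(X)
  p <- ncol(X)
  if (k < p) stop("more coefficients than studies", call. = FALSE)
  if (qr(X)$rank < p) stop("singular moderator matrix (constant moderator?)",
                           call. = FALSE)
  me <- .metric_effects(d$r, d$n, metric)
  y <- me$y
  vi <- me$vi

  tau2_for <- function(Xm) .metareg_tau2(y, vi, Xm, estimator)
  t2 <- tau2_for(X)
  t2_null <- tau2_for(X[, 1, drop = FALSE])
  wi <- 1 / (vi + t2)
  XtW <- t(X * wi)
  V <- solve(XtW %*% X)
  b <- drop(V %*% XtW %*% y)
  se <- sqrt(diag(V))
  zval <- b / se
  # omnibus test of all non-intercept coefficients
  sel <- -1L
  Vb <- V[sel, sel, drop = FALSE]
  bb <- b[sel]
  QM <- drop(t(bb) %*% solve(Vb) %*% bb)
  resid <- y - drop(X %*% b)
  QE <- sum((resid^2) / vi)
  structure(list(
    coefficients = stats::setNames(b, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    zval = zval, p = 2 * stats::pnorm(-abs(zval)),
    QM = QM, df_M = p - 1L,
    p_M = stats::pchisq(QM, p - 1L, lower.tail = FALSE),
    QE = QE, df_E = k - p,
    tau2 = t2, tau2_null = t2_null,
    R2 = if (t2_null > 0) max(0, 1 - t2 / t2_null) else 0,
    k = k, n_dropped = n_dropped, estimator = estimator, metric = metric,
    y = y, vi = vi, X = X
  ), class = "rema_reg")
}

# residual-heterogeneity estimators for the meta-regression design Xm
.metareg_tau2 <- function(y, vi, Xm, estimator) {
  k <- length(y)
  p <- ncol(Xm)
  if (k == p) return(0)   # saturated: no residual information
  if (estimator == "DL") {
    W <- diag(1 / vi, k)
    P <- W - W %*% Xm %*% solve(t(Xm) %*% W %*% Xm) %*% t(Xm) %*% W
    Qe <- drop(t(y) %*% P %*% y)
    return(max(0, (Qe - (k - p)) / sum(diag(P))))
  }
  nll <- function(t2) {
    wi <- 1 / (vi + t2)
    XtW <- t(Xm * wi)
    M <- XtW %*% Xm
    b <- solve(M, XtW %*% y)
    r <- y - drop(Xm %*% b)
    0.5 * (sum(log(vi + t2)) + determinant(M)$modulus + sum(wi * r^2))
  }
  upper <- max(10 * stats::var(y), 10 * mean(vi), 1e-3)
  stats::optimize(nll, c(0, upper), tol = 1e-10)$minimum
}

#' @export
print.rema_reg <- function(x, ...) {
  cat(sprintf("Meta-regression (%s residual tau2, %s metric), k = %d",
              x$estimator, x$metric, x$k))
  if (x$n_dropped) cat(sprintf(" (%d rows dropped: missing moderator)",
                               x$n_dropped))
  cat("\n")
  tab <- cbind(estimate = x$coefficients, se = x$se, z = x$zval, p = x$p)
  print(round(tab, 4))
  cat(sprintf("QM(df = %d) = %.3f, p = %s;  tau2 = %.4f (null %.4f);  R2 = %.3f\n",
              x$df_M, x$QM, format.pval(x$p_M, digits = 3), x$tau2,
              x$tau2_null, x$R2))
  invisible(x)
}

#' @export
coef.rema_reg <- function(object, ...) object$coefficients
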