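# Two-stage meta-analytic mediation: stage 1 pools the per-study 3x3
# correlation matrices cellwise (random effects on Fisher z); stage 2
# solves the standardised path model on the pooled matrix.

.MED_CELLS <- c("r_xy", "r_xm", "r_my")
.MED_ALIASES <- c(r_ir = "r_xy", r_im = "r_xm", r_mr = "r_my")

#' Pool per-study correlation matrices
#'
#' Each study contributes up to three correlations among a predictor (x),
#' a mediator (m) and an outcome (y): `r_xy`, `r_xm`, `r_my` (the aliases
#' `r_ir`, `r_im`, `r_mr` - intelligence, mediator, religiosity - are
#' accepted). Cells are pooled independently by DerSimonian-Laird on the
#' Fisher-z scale; missing cells simply do not contribute. The pooled 3x3
#' matrix is projected to the positive semi-definite cone if needed
#' (eigenvalues clipped at 1e-6, unit diagonal restored) and flagged.
#'
#' @param mats A `data.frame` with columns `study_id` (optional), `n`, and
#'   the three correlation columns.
#' @return Object of class `pooled_cormat`: `matrix` (3x3, dimnames
#'   x/m/y), `cells` (per-cell pooled r, z, se, k, tau2), `n_harmonic`,
#'   `k`, `psd_adjusted`.
#' @export
pool_matrices <- function(mats) {
  mats <- as.data.frame(mats)
  for (al in names(.MED_ALIASES)) {
    if (al %in% names(mats) && !(.MED_ALIASES[[al]] %in% names(mats))) {
      names(mats)[names(mats) == al] <- .MED_ALIASES[[al]]
    }
  }
  need <- c("n", .MED_CELLS)
  miss <- setdiff(need, names(mats))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (nrow(mats) < 2L) stop("pool_matrices() needs k >= 2", call. = FALSE)
  cells <- data.frame(cell = .MED_CELLS, r = NA_real_, z = NA_real_,
                      se = NA_real_, k = NA_integer_, tau2 = NA_real_)
  for (i in seq_along(.MED_CELLS)) {
    cl <- .MED_CELLS[i]
    ok <- !is.na(mats[[cl]])
    if (!any(ok)) stop("cell '", cl, "' has no contributing studies",
                       call. = FALSE)
    y <- atanh(mats[[cl]][ok])
    vi <- 1 / (mats$n[ok] - 3)
    f <- .fit_est(y, vi, "DL")
    cells$r[i] <- tanh(f$est)
    cells$z[i] <- f$est
    cells$se[i] <- f$se
    cells$k[i] <- f$k
    cells$tau2[i] <- f$tau2
  }
  M <- diag(3)
  dimnames(M) <- list(c("x", "m", "y"), c("x", "m", "y"))
  M["x", "y"] <- M["y", "x"] <- cells$r[cells$cell == "r_xy"]
  M["x", "m"] <- M["m", "x"] <- cells$r[cells$cell == "r_xm"]
  M["m", "y"] <- M["y", "m"] <- cells$r[cells$cell == "r_my"]
  psd <- .project_psd(M)
  structure(list(
    matrix = psd$M, cells = cells,
    n_harmonic = nrow(mats) / sum(1 / mats$n),
    k = nrow(mats), psd_adjusted = psd$adjusted
  ), class = "pooled_cormat")
}

.project_psd <- function(M, floor = 1e-6) {
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= floor) return(list(M = M, adjusted = FALSE))
  v <- pmax(e$values, floor)
  M2 <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(M2))
  M2 <- M2 / (d %o% d)
  dimnames(M2) <- dimnames(M)
  list(M = M2, adjusted = TRUE)
}

#' @export
print.pooled_cormat <- function(x, ...) {
  cat(sprintf("Pooled correlation matrix (k = %d, harmonic-mean n = %.1f%s)\n",
              x$k, x$n_harmonic,
              if (x$psd_adjusted) ", PSD-projected" else ""))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Partial correlation
#'
#' Correlation of x and y with z held constant:
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#'
#' @param rxy,rxz,ryz Zero-order correlations, all inside (-1, 1); `rxz`
#'   and `ryz` must be strictly inside.
#' @return The partial correlation.
#' @export
partial_correlation <- function(rxy, rxz, ryz) {
  if (any(abs(c(rxz, ryz)) >= 1)) {
    stop("control correlations must lie strictly inside (-1, 1)",
         call. = FALSE)
  }
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Fit a standardized mediation model to a pooled correlation matrix
#'
#' Stage 2 of the two-stage approach. With predictor x, mediator m and
#' outcome y, the standardized paths are `a = r_xm`,
#' `b = (r_my - r_xm r_xy) / (1 - r_xm^2)` and the direct path
#' `c' = (r_xy - r_xm r_my) / (1 - r_xm^2)`; the indirect effect is `a*b`
#' and `total = c' + a*b = r_xy` exactly. Confidence intervals come from
#' Monte-Carlo resampling of the stage-1 cell estimates from their
#' asymptotic normal distributions on the z scale (cells treated as
#' independent), with the delta-method interval for the indirect effect
#' reported alongside.
#'
#' @param pooled A [pool_matrices()] result (or a plain 3x3 correlation
#'   matrix with dimnames x/m/y, in which case no sampling CIs are
#'   available).
#' @param draws Monte-Carlo draws, default 10,000.
#' @param seed Integer seed for the Monte-Carlo interval.
#' @param level Confidence level.
#' @return Object of class `meta_mediation`: `paths` (a, b, direct,
#'   indirect, total with CIs), `mediation_type`
#'   (`"none"`/`"partial"`/`"full"`), `pooled`.
#' @export
fit_mediation <- function(pooled, draws = 10000L, seed = 1L, level = 0.95) {
  .check_level(level)
  plain <- !inherits(pooled, "pooled_cormat")
  M <- if (plain) pooled else pooled$matrix
  paths <- .solve_paths(M["x", "y"], M["x", "m"], M["m", "y"])
  ci <- NULL
  if (!plain) {
    set.seed(seed)
    ce <- pooled$cells
    zs <- matrix(stats::rnorm(3L * draws, mean = ce$z, sd = ce$se),
                 nrow = 3L)
    rs <- tanh(zs)
    sim <- vapply(seq_len(draws), function(j) {
      unlist(.solve_paths(rs[1L, j], rs[2L, j], rs[3L, j]))
    }, numeric(5L))
    a2 <- (1 - level) / 2
    ci <- t(apply(sim, 1L, stats::quantile, probs = c(a2, 1 - a2)))
  }
  ind_ci <- if (is.null(ci)) c(NA_real_, NA_real_) else ci["indirect", ]
  dir_ci <- if (is.null(ci)) c(NA_real_, NA_real_) else ci["direct", ]
  med_type <- if (anyNA(ind_ci)) {
    NA_character_
  } else if (ind_ci[1L] <= 0 && ind_ci[2L] >= 0) {
    "none"
  } else if (dir_ci[1L] <= 0 && dir_ci[2L] >= 0) {
    "full"
  } else "partial"
  structure(list(
    paths = paths, ci = ci, mediation_type = med_type,
    pooled = if (plain) NULL else pooled, level = level, draws = draws
  ), class = "meta_mediation")
}

# standardized path algebra for the 3x3 system
.solve_paths <- function(r_xy, r_xm, r_my) {
  den <- 1 - r_xm^2
  if (den < .Machine$double.eps) stop("singular path system (|r_xm| = 1)",
                                      call. = FALSE)
  b <- (r_my - r_xm * r_xy) / den
  direct <- (r_xy - r_xm * r_my) / den
  list(a = r_xm, b = b, direct = direct, indirect = r_xm * b,
       total = r_xy)
}

#' @export
print.meta_mediation <- function(x, ...) {
  p <- x$paths
  fmt <- function(nm) {
    v <- p[[nm]]
    if (!is.null(x$ci)) {
      sprintf("%8.4f  [%7.4f, %7.4f]", v, x$ci[nm, 1L], x$ci[nm, 2L])
    } else sprintf("%8.4f", v)
  }
  cat("Two-stage meta-analytic mediation (standardized paths)\n")
  for (nm in c("a", "b", "direct", "indirect", "total")) {
    cat(sprintf("  %-9s %s\n", nm, fmt(nm)))
  }
  if (!is.na(x$mediation_type)) {
    cat("  mediation:", x$mediation_type, "\n")
  }
  invisible(x)
}
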