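#' Mixed-effects subgroup comparison
#'
#' Pools each subgroup with a random-effects model (its own between-study
#' variance) and compares the subgroup summaries with a fixed-effect model:
#' `Q_between = sum(w_g (theta_g - theta_bar)^2)` with `w_g = 1/se_g^2` and
#' `theta_bar` the `w_g`-weighted mean, referred to a chi-square with
#' `(#groups - 1)` degrees of freedom. This is the classic
#' "random effects within, fixed effect between" recipe.
#'
#' Records whose grouping value is `"mixed"` are excluded when grouping by
#' `sample_type` unless `"mixed"` is requested explicitly in `levels`, so
#' that the three substantive sample types are compared among themselves.
#'
#' @param ds A `meta_dataset`.
#' @param by Moderator column name (e.g. `"intelligence_type"`).
#' @param levels Levels to compare (default: all levels present, minus
#'   `"mixed"` for `sample_type`).
#' @param estimator Within-group estimator, default `"REML"`.
#' @param metric Effect metric passed to [rema()].
#' @return An object of class `"rema_subgroup"`: list of per-level `rema`
#'   fits plus `Q_between`, `df_between`, `p_between`.
#' @examples
#' subgroup_test(ri_studies(), "intelligence_type", c("iq", "gpa"))
#' @export
subgroup_test <- function(ds, by, levels = NULL,
                          estimator = c("REML", "DL", "FE", "UNWEIGHTED"),
                          metric = "z") {
  estimator <- match.arg(estimator)
  if (!by %in% names(ds)) stop("no moderator column '", by, "'", call. = FALSE)
  g <- ds[[by]]
  if (is.null(levels)) {
    levels <- sort(unique(g))
    if (by == "sample_type") levels <- setdiff(levels, "mixed")
  }
  fits <- list()
  for (lv in levels) {
    idx <- which(g == lv)
    if (length(idx) < 2L) {
      stop("subgroup level '", lv, "' has fewer than 2 studies",
           call. = FALSE)
    }
    fits[[lv]] <- rema(data = ds[idx, , drop = FALSE], estimator = estimator,
                       metric = metric)
  }
  th <- vapply(fits, function(f) f$estimate, 0)
  wg <- vapply(fits, function(f) 1 / f$se^2, 0)
  tb <- sum(wg * th) / sum(wg)
  Qb <- sum(wg * (th - tb)^2)
  dfb <- length(fits) - 1L
  structure(list(
    group_results = fits, by = by, levels = levels,
    Q_between = Qb, df_between = dfb,
    p_between = stats::pchisq(Qb, dfb, lower.tail = FALSE),
    estimator = estimator
  ), class = "rema_subgroup")
}

#' @export
print.rema_subgroup <- function(x, ...) {
  cat(sprintf("Subgroup comparison on '%s' (%s within, FE between)\n",
              x$by, x$estimator))
  for (lv in x$levels) {
    f <- x$group_results[[lv]]
    cat(sprintf("  %-12s k = %3d  r = %7.3f  [%7.3f, %7.3f]  I2 = %5.1f%%\n",
                lv, f$k, f$estimate_r, f$ci_low_r, f$ci_high_r,
                ifelse(is.na(f$I2_tau2), f$I2, f$I2_tau2)))
  }
  cat(sprintf("Q_between = %.3f (df = %d), p = %s\n", x$Q_between,
              x$df_between, format.pval(x$p_between, digits = 3)))
  invisible(x)
}

#' Pairwise subgroup contrasts
#'
#' Convenience wrapper running [subgroup_test()] for every pair of levels.
#'
#' @inheritParams subgroup_test
#' @return A `data.frame` with one row per pair: `level1`, `level2`, `Q`,
#'   `p`.
#' @export
subgroup_pairs <- function(ds, by, levels = NULL, estimator = "REML",
                           metric = "z") {
  if (is.null(levels)) {
    levels <- sort(unique(ds[[by]]))
    if (by == "sample_type") levels <- setdiff(levels, "mixed")
  }
  cmb <- utils::combn(levels, 2L)
  out <- data.frame(level1 = cmb[1L, ], level2 = cmb[2L, ],
                    Q = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(cmb))) {
    st <- subgroup_test(ds, by, cmb[, i], estimator = estimator,
                        metric = metric)
    out$Q[i] <- st$Q_between
    out$p[i] <- st$p_between
  }
  out
}
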