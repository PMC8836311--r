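#' Define a specification grid for multiverse analysis
#'
#' The "Which" factors select the data (religiosity assessment, sample
#' type, publication status); the "How" factors select the analysis (effect
#' metric and pooling estimator). The level `"all"` imposes no filter; note
#' that mixed-type samples are only reachable through `"all"` (they belong
#' to none of the three substantive sample-type levels).
#'
#' The default grid enumerates `4 * 4 * 3 = 48` data specifications crossed
#' with `3 * 4 = 12` analysis specifications, i.e. 576 cells. The third
#' effect-size metric `"nw"` (n-weighted raw correlations) complements the
#' conventional Fisher-z and raw-r syntheses.
#'
#' @param religiosity,sample,publication Character vectors of Which levels.
#' @param metric,estimator Character vectors of How levels.
#' @return An object of class `spec_grid`.
#' @export
spec_grid <- function(religiosity = c("beliefs", "behavior", "mixed", "all"),
                      sample = c("precollege", "college", "noncollege", "all"),
                      publication = c("published", "unpublished", "all"),
                      metric = c("z", "r", "nw"),
                      estimator = c("FE", "DL", "REML", "UNWEIGHTED")) {
  g <- list(religiosity = religiosity, sample = sample,
            publication = publication, metric = metric,
            estimator = estimator)
  for (nm in names(g)) {
    if (length(g[[nm]]) < 1L) stop("factor '", nm, "' has no levels",
                                   call. = FALSE)
  }
  structure(g, class = "spec_grid")
}

#' Enumerate all specifications of a grid
#'
#' Full Cartesian product in deterministic order (religiosity varying
#' slowest, then sample, publication, metric, estimator).
#'
#' @param grid A [spec_grid()].
#' @return A `data.frame` with one row per specification.
#' @examples
#' nrow(enumerate_specifications(spec_grid()))  # 576
#' @export
enumerate_specifications <- function(grid) {
  stopifnot(inherits(grid, "spec_grid"))
  e <- expand.grid(estimator = grid$estimator, metric = grid$metric,
                   publication = grid$publication, sample = grid$sample,
                   religiosity = grid$religiosity,
                   stringsAsFactors = FALSE)
  e[, c("religiosity", "sample", "publication", "metric", "estimator")]
}

# record indices selected by a Which triple
.spec_subset <- function(ds, religiosity, sample, publication) {
  keep <- rep(TRUE, nrow(ds))
  if (religiosity != "all") keep <- keep & ds$religiosity_type == religiosity
  if (sample != "all") keep <- keep & ds$sample_type == sample
  if (publication != "all") keep <- keep & ds$publication_status == publication
  which(keep)
}

# fit one specification from raw (r, n); returns est (analysis metric),
# est_r, se, p
.fit_spec <- function(r, n, metric, estimator) {
  me <- .metric_effects(r, n, metric)
  f <- .fit_est(me$y, me$vi, estimator)
  p <- 2 * stats::pnorm(-abs(f$est / f$se))
  c(est = f$est, est_r = .to_r(f$est, metric), se = f$se, p = p)
}

#' Run a multiverse of meta-analytic specifications
#'
#' Fits every admissible specification of `grid` (those whose data subset
#' holds at least `min_k` records) and assembles the descriptive
#' specification curve, sorted by the pooled correlation with deterministic
#' lexicographic tie-breaking.
#'
#' @param ds A `meta_dataset`.
#' @param grid A [spec_grid()]; default is the full 576-cell grid.
#' @param min_k Minimum records per specification (default 2).
#' @param alpha Two-sided significance level for counting significant
#'   specifications.
#' @return Object of class `spec_curve` with `results` (one row per
#'   admissible specification, sorted), `n_total`, `n_admissible`,
#'   `n_sig_negative`, `n_sig_positive`, and (after
#'   [bootstrap_null_test()]) `null_bands` and `decision`.
#' @export
run_multiverse <- function(ds, grid = spec_grid(), min_k = 2L,
                           alpha = 0.05) {
  specs <- enumerate_specifications(grid)
  n_total <- nrow(specs)
  # subsets depend only on the Which triple: compute once
  wh <- unique(specs[, c("religiosity", "sample", "publication")])
  wh$key <- paste(wh$religiosity, wh$sample, wh$publication, sep = "|")
  subsets <- lapply(seq_len(nrow(wh)), function(i) {
    .spec_subset(ds, wh$religiosity[i], wh$sample[i], wh$publication[i])
  })
  names(subsets) <- wh$key
  key <- paste(specs$religiosity, specs$sample, specs$publication, sep = "|")
  k_vec <- lengths(subsets)[key]
  adm <- which(k_vec >= min_k)
  res <- specs[adm, , drop = FALSE]
  res$k <- as.integer(k_vec[adm])
  stats_m <- matrix(NA_real_, nrow(res), 4L,
                    dimnames = list(NULL, c("est", "est_r", "se", "p")))
  for (i in seq_len(nrow(res))) {
    idx <- subsets[[key[adm[i]]]]
    stats_m[i, ] <- .fit_spec(ds$r[idx], ds$n[idx], res$metric[i],
                              res$estimator[i])
  }
  res$estimate <- stats_m[, "est"]
  res$estimate_r <- stats_m[, "est_r"]
  res$se <- stats_m[, "se"]
  res$p <- stats_m[, "p"]
  res$significant <- res$p < alpha
  ord <- order(res$estimate_r, res$religiosity, res$sample,
               res$publication, res$metric, res$estimator)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  structure(list(
    results = res,
    n_total = n_total,
    n_admissible = nrow(res),
    n_sig_negative = sum(res$significant & res$estimate_r < 0),
    n_sig_positive = sum(res$significant & res$estimate_r > 0),
    min_k = min_k, alpha = alpha, grid = grid,
    null_bands = NULL, decision = NA_character_
  ), class = "spec_curve")
}

#' Parametric-bootstrap null test for a specification curve
#'
#' Study features are held fixed; under the null each study's Fisher-z
#' effect is redrawn from `N(0, sqrt(v_i))` with `v_i = 1/(n_i - 3)` (the
#' fixed-effect sampling standard error), the full multiverse is re-run,
#' and each replicate's curve is sorted. The pointwise 2.5%/97.5% (for
#' `level = 0.95`) quantiles over the `B + 1` curves (B simulated plus the
#' observed one) form the null band at each curve rank. The summary is
#' judged non-nill when the observed curve escapes the null band at more
#' than `1 - level` of the ranks.
#'
#' @inheritParams run_multiverse
#' @param B Number of bootstrap replicates (999 in the canonical analysis).
#' @param seed Integer seed (required: the test is stochastic).
#' @param level Band level, default 0.95.
#' @return The `spec_curve` with `null_bands` (per-rank `lower`/`upper`),
#'   `outside_share` and `decision` (`"non-nill"` or `"indeterminate"`).
#' @export
bootstrap_null_test <- function(ds, grid = spec_grid(), B = 999L, seed,
                                min_k = 2L, alpha = 0.05, level = 0.95) {
  if (missing(seed)) stop("bootstrap_null_test() requires a seed",
                          call. = FALSE)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  .check_level(level)
  observed <- run_multiverse(ds, grid, min_k = min_k, alpha = alpha)
  m <- observed$n_admissible
  if (m == 0L) stop("no admissible specifications", call. = FALSE)
  sim_ds <- ds
  se_z <- sqrt(1 / (ds$n - 3))
  curves <- matrix(NA_real_, B + 1L, m)
  curves[1L, ] <- observed$results$estimate_r
  set.seed(seed)
  for (b in seq_len(B)) {
    sim_ds$r <- tanh(stats::rnorm(nrow(ds), 0, se_z))
    sc <- run_multiverse(sim_ds, grid, min_k = min_k, alpha = alpha)
    curves[b + 1L, ] <- sc$results$estimate_r
  }
  a2 <- (1 - level) / 2
  bands <- data.frame(
    rank = seq_len(m),
    lower = apply(curves, 2L, stats::quantile, probs = a2, type = 7),
    upper = apply(curves, 2L, stats::quantile, probs = 1 - a2, type = 7)
  )
  obs <- observed$results$estimate_r
  outside <- obs < bands$lower | obs > bands$upper
  observed$null_bands <- bands
  observed$outside_share <- mean(outside)
  observed$B <- B
  observed$decision <- if (mean(outside) > (1 - level)) "non-nill" else
    "indeterminate"
  observed
}

#' @export
print.spec_curve <- function(x, ...) {
  cat(sprintf(
    "Specification curve: %d/%d admissible specifications (min k = %d)\n",
    x$n_admissible, x$n_total, x$min_k))
  cat(sprintf("  significant negative: %d (%.1f%%);  significant positive: %d\n",
              x$n_sig_negative,
              100 * x$n_sig_negative / max(1L, x$n_admissible),
              x$n_sig_positive))
  rng <- range(x$results$estimate_r)
  cat(sprintf("  summary range: [%.3f, %.3f]\n", rng[1L], rng[2L]))
  if (!is.null(x$null_bands)) {
    cat(sprintf("  bootstrap null (B = %d): %.1f%% of ranks outside the band -> %s\n",
                x$B, 100 * x$outside_share, x$decision))
  }
  invisible(x)
}

#' @export
as.data.frame.spec_curve <- function(x, ...) x$results

#' Histogram data of specification p-values
#'
#' @param x A `spec_curve`.
#' @param breaks Histogram breaks on the p scale.
#' @return A `data.frame` of bin edges and counts, with the significant
#'   fraction as an attribute.
#' @export
spec_p_histogram <- function(x, breaks = seq(0, 1, by = 0.05)) {
  h <- graphics::hist(x$results$p, breaks = breaks, plot = FALSE)
  out <- data.frame(bin_low = utils::head(h$breaks, -1L),
                    bin_high = utils::tail(h$breaks, -1L),
                    count = h$counts)
  attr(out, "frac_significant") <- mean(x$results$p < x$alpha)
  out
}

#' Plot a specification curve
#'
#' Sorted summary correlations with pointwise confidence whiskers and, when
#' present, the bootstrap null band.
#'
#' @param x A `spec_curve`.
#' @param ... Passed to `plot.default`.
#' @export
plot.spec_curve <- function(x, ...) {
  r <- x$results
  zc <- stats::qnorm(1 - x$alpha / 2)
  lo <- tanh(atanh(r$estimate_r) - zc * r$se)
  hi <- tanh(atanh(r$estimate_r) + zc * r$se)
  graphics::plot(r$rank, r$estimate_r, pch = 16, cex = 0.5,
                 ylim = range(c(lo, hi, 0)),
                 xlab = "specification rank", ylab = "summary r", ...)
  graphics::segments(r$rank, lo, r$rank, hi, col = "grey70")
  graphics::points(r$rank, r$estimate_r, pch = 16, cex = 0.5,
                   col = ifelse(r$significant, 2, 1))
  graphics::abline(h = 0, lty = 3)
  if (!is.null(x$null_bands)) {
    graphics::lines(x$null_bands$rank, x$null_bands$lower, lty = 2)
    graphics::lines(x$null_bands$rank, x$null_bands$upper, lty = 2)
  }
  invisible(x)
}
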