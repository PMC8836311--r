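# Combinatorial (GOSH-style) meta-analysis: summary effects over a large
# random sample of study subsets, with optional oversampling of the most
# extreme effects so outlier influence is visible in the subset cloud.

# leave-one-out influence on the pooled estimate; returns |delta estimate|
.loo_influence <- function(y, vi, estimator = "DL") {
  full <- .fit_est(y, vi, estimator)$est
  vapply(seq_along(y), function(i) {
    abs(.fit_est(y[-i], vi[-i], estimator)$est - full)
  }, 0)
}

#' Combinatorial meta-analysis over random study subsets
#'
#' Draws `n_subsets` distinct subsets of the studies (sizes uniform on
#' `[2, K]`, members uniform without replacement; duplicates rejected by
#' hashing) and pools each with the requested estimator on the Fisher-z
#' scale. With `oversample_extremes = TRUE` half of the draws are forced to
#' contain at least one of the two most extreme observed correlations.
#' When the number of feasible subsets does not exceed `n_subsets` (and
#' `K <= 24`) the enumeration is exhaustive instead.
#'
#' Two leverage studies are designated by leave-one-out influence (largest
#' displacement of the pooled estimate) and flagged per subset.
#'
#' @param ds A `meta_dataset`.
#' @param n_subsets Number of subsets to draw (100,000 in the canonical
#'   analysis).
#' @param estimator Pooling estimator, default `"DL"`.
#' @param seed Integer seed (required).
#' @param oversample_extremes Force half the draws to include an extreme
#'   study.
#' @param alpha Two-sided level used for the share of subsets whose CI
#'   excludes zero.
#' @return Object of class `gosh`: `samples` (one row per subset: `k`,
#'   `estimate_r`, `I2`, leverage flags), `share_negative`,
#'   `share_ci_excludes_zero`, `leverage_ids`, `exhaustive`.
#' @export
gosh <- function(ds, n_subsets = 100000L, estimator = "DL", seed,
                 oversample_extremes = TRUE, alpha = 0.05) {
  if (missing(seed)) stop("gosh() requires a seed", call. = FALSE)
  K <- nrow(ds)
  if (K < 2L) stop("gosh() needs at least 2 studies", call. = FALSE)
  if (n_subsets < 1L) stop("n_subsets must be >= 1", call. = FALSE)
  y <- atanh(ds$r)
  vi <- 1 / (ds$n - 3)
  infl <- .loo_influence(y, vi, estimator)
  lev <- order(infl, decreasing = TRUE)[1:min(2L, K)]
  extremes <- c(which.min(ds$r), which.max(ds$r))

  feasible <- if (K <= 24L) 2^K - 1 - K else Inf
  exhaustive <- is.finite(feasible) && n_subsets >= feasible
  subsets <- list()
  if (exhaustive) {
    for (m in 2:K) {
      cm <- utils::combn(K, m)
      subsets <- c(subsets, lapply(seq_len(ncol(cm)), function(j) cm[, j]))
    }
  } else {
    set.seed(seed)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    n_got <- 0L
    max_tries <- 50L * n_subsets
    tries <- 0L
    subsets <- vector("list", n_subsets)
    while (n_got < n_subsets && tries < max_tries) {
      tries <- tries + 1L
      m <- sample.int(K - 1L, 1L) + 1L  # uniform on 2..K
      force_extreme <- oversample_extremes && (n_got %% 2L == 0L)
      if (force_extreme) {
        e <- extremes[sample.int(length(extremes), 1L)]
        idx <- c(e, sample(setdiff(seq_len(K), e), m - 1L))
      } else {
        idx <- sample.int(K, m)
      }
      idx <- sort(idx)
      key <- paste(idx, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      n_got <- n_got + 1L
      subsets[[n_got]] <- idx
    }
    subsets <- subsets[seq_len(n_got)]
    if (n_got < n_subsets) {
      warning("only ", n_got, " distinct subsets available; capped")
    }
  }
  ns <- length(subsets)
  est <- se <- I2 <- numeric(ns)
  kk <- integer(ns)
  has_lev <- matrix(FALSE, ns, length(lev))
  for (i in seq_len(ns)) {
    idx <- subsets[[i]]
    f <- .fit_est(y[idx], vi[idx], estimator)
    est[i] <- f$est
    se[i] <- f$se
    kk[i] <- f$k
    df <- f$k - 1L
    I2[i] <- if (is.finite(f$Q) && f$Q > 0) max(0, (f$Q - df) / f$Q) * 100 else 0
    has_lev[i, ] <- lev %in% idx
  }
  zc <- stats::qnorm(1 - alpha / 2)
  excl0 <- abs(est) > zc * se
  samples <- data.frame(k = kk, estimate_r = tanh(est), I2 = I2,
                        ci_excludes_zero = excl0)
  for (j in seq_along(lev)) {
    samples[[paste0("contains_", ds$study_id[lev[j]])]] <- has_lev[, j]
  }
  structure(list(
    samples = samples,
    share_negative = mean(samples$estimate_r < 0),
    share_ci_excludes_zero = mean(excl0),
    leverage_ids = ds$study_id[lev],
    exhaustive = exhaustive, estimator = estimator, K = K
  ), class = "gosh")
}

#' @export
print.gosh <- function(x, ...) {
  cat(sprintf("GOSH combinatorial meta-analysis: %d subsets of K = %d (%s)\n",
              nrow(x$samples), x$K,
              if (x$exhaustive) "exhaustive" else "random"))
  q <- stats::quantile(x$samples$estimate_r, c(0.025, 0.5, 0.975))
  cat(sprintf("  subset summary r: median %.3f [2.5%%: %.3f, 97.5%%: %.3f]\n",
              q[2L], q[1L], q[3L]))
  cat(sprintf("  share negative: %.1f%%;  share CI excluding 0: %.1f%%\n",
              100 * x$share_negative, 100 * x$share_ci_excludes_zero))
  cat(sprintf("  leverage studies: %s\n",
              paste(x$leverage_ids, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.gosh <- function(x, ...) x$samples
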