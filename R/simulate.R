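# Synthetic meta-analytic datasets with the statistical structure the
# analysis pipeline assumes: Fisher-z effects around a true correlation
# with between-study variance, study sizes spanning orders of magnitude,
# categorical moderators with level-specific shifts, and a
# significance-driven publication-selection mechanism.

#' Configure a synthetic meta-analysis
#'
#' Defaults emulate the packaged study table: k = 105 samples, a true
#' correlation of -0.15, between-study variance 0.018 on the z scale, study
#' sizes log-uniform between 20 and 40,000, and moderator level
#' probabilities matching the observed composition with no level shifts.
#' Selection is off by default (every study is "published").
#'
#' @param k Number of studies.
#' @param rho True correlation, |rho| < 1.
#' @param tau2 Between-study variance on the Fisher-z scale, >= 0.
#' @param n_range Bounds of the log-uniform study-size distribution.
#' @param moderator_spec List with elements `religiosity`, `sample`,
#'   `intelligence`: each a list of `probs` (named level probabilities) and
#'   `shifts` (named z-scale effect shifts). Defaults mirror the packaged
#'   table's composition with zero shifts.
#' @param selection List describing the publication mechanism:
#'   `prob_sig`/`prob_nonsig` publication probabilities, `alpha` the
#'   two-sided threshold, and `sign` (`NULL`: any significant study counts;
#'   `-1`/`+1`: only that direction counts as significant).
#' @param mediation_truth Optional population 3x3 correlation matrix
#'   (dimnames x/m/y) for [simulate_correlation_matrices()].
#' @param seed Integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(k = 105L, rho = -0.15, tau2 = 0.018,
                       n_range = c(20, 40000), moderator_spec = NULL,
                       selection = NULL, mediation_truth = NULL,
                       seed = 1L) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (abs(rho) >= 1) stop("|rho| < 1 required", call. = FALSE)
  if (tau2 < 0) stop("tau2 must be >= 0", call. = FALSE)
  stopifnot(length(n_range) == 2L, n_range[1L] >= 4, diff(n_range) >= 0)
  if (is.null(moderator_spec)) {
    moderator_spec <- list(
      religiosity = list(probs = c(beliefs = 67, behavior = 11,
                                   mixed = 27) / 105,
                         shifts = c(beliefs = 0, behavior = 0, mixed = 0)),
      sample = list(probs = c(precollege = 13, college = 49,
                              noncollege = 39, mixed = 4) / 105,
                    shifts = c(precollege = 0, college = 0,
                               noncollege = 0, mixed = 0)),
      intelligence = list(probs = c(iq = 93, gpa = 8, mixed = 4) / 105,
                          shifts = c(iq = 0, gpa = 0, mixed = 0))
    )
  }
  for (f in moderator_spec) {
    if (any(f$probs < 0) || abs(sum(f$probs) - 1) > 1e-8) {
      stop("moderator probabilities must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  if (is.null(selection)) {
    selection <- list(prob_sig = 1, prob_nonsig = 1, alpha = 0.05,
                      sign = NULL)
  }
  if (!is.null(mediation_truth)) {
    ev <- eigen(mediation_truth, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 0) stop("mediation_truth must be positive semi-definite",
                          call. = FALSE)
  }
  structure(list(k = as.integer(k), rho = rho, tau2 = tau2,
                 n_range = n_range, moderator_spec = moderator_spec,
                 selection = selection, mediation_truth = mediation_truth,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# one RNG substream per study, derived once from the master seed, so that
# increasing k leaves the first studies' draws unchanged
.study_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Simulate a meta-analytic dataset
#'
#' Per study: `n` is drawn log-uniformly from `n_range`; the true effect is
#' `atanh(rho)` plus the moderator shifts plus a `N(0, tau2)` deviation;
#' the observed Fisher-z effect adds `N(0, 1/(n-3))` sampling noise and is
#' back-transformed to `r`; the two-sided p-value comes from the z-test;
#' the publication label is assigned by the selection mechanism. The
#' result has the same schema as the packaged study table and is fully
#' reproducible from the seed (per-study substreams: adding studies does
#' not change earlier ones).
#'
#' @param cfg A [sim_config()].
#' @return A `meta_dataset` of `cfg$k` records.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  k <- cfg$k
  seeds <- .study_seeds(cfg$seed, k)
  ms <- cfg$moderator_spec
  sel <- cfg$selection
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    set.seed(seeds[i])
    n <- round(exp(stats::runif(1, log(cfg$n_range[1L]),
                                log(cfg$n_range[2L]))))
    rel <- sample(names(ms$religiosity$probs), 1L,
                  prob = ms$religiosity$probs)
    sam <- sample(names(ms$sample$probs), 1L, prob = ms$sample$probs)
    int <- sample(names(ms$intelligence$probs), 1L,
                  prob = ms$intelligence$probs)
    theta <- atanh(cfg$rho) + ms$religiosity$shifts[[rel]] +
      ms$sample$shifts[[sam]] + stats::rnorm(1, 0, sqrt(cfg$tau2))
    z <- stats::rnorm(1, theta, sqrt(1 / (n - 3)))
    r <- tanh(z)
    p <- 2 * stats::pnorm(-abs(z) * sqrt(n - 3))
    sig <- p < sel$alpha &&
      (is.null(sel$sign) || sign(r) == sel$sign)
    prob_pub <- if (sig) sel$prob_sig else sel$prob_nonsig
    published <- stats::runif(1) < prob_pub
    pct <- if (stats::runif(1) < 0.28) NA_real_ else
      round(stats::runif(1, 20, 80))
    rows[[i]] <- data.frame(
      study_id = sprintf("sim%04d", i), author = "simulated",
      year = sample(1928:2020, 1L), n = n,
      r = round(r, 6), p_value = formatC(p, digits = 4, format = "g"),
      sample_type = sam, pct_men = pct / 100,
      religiosity_type = rel, intelligence_type = int,
      publication_status = if (published) "published" else "unpublished",
      quality = NA_integer_, stringsAsFactors = FALSE
    )
  }
  as_meta_dataset(do.call(rbind, rows), provenance = "simulated")
}

#' Simulate per-study correlation matrices for mediation
#'
#' For each study, a sample of size `n` is drawn from the trivariate normal
#' distribution with correlation `cfg$mediation_truth`, and the sample
#' correlations among predictor, mediator and outcome are returned.
#'
#' @param cfg A [sim_config()] with `mediation_truth` set.
#' @param n_range Optional override of the study-size bounds (mediation
#'   primary studies are typically far smaller than the full range).
#' @return A `data.frame` with columns `study_id`, `n`, `r_xy`, `r_xm`,
#'   `r_my` and a logical `psd` flag (sample matrices from complete data
#'   are PSD by construction; the flag marks near-singular cases).
#' @export
simulate_correlation_matrices <- function(cfg, n_range = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$mediation_truth)) {
    stop("sim_config has no mediation_truth matrix", call. = FALSE)
  }
  if (is.null(n_range)) n_range <- cfg$n_range
  R <- cfg$mediation_truth
  # sampling from a singular truth still works through the eigen square root
  e <- eigen(R, symmetric = TRUE)
  sq <- e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
  seeds <- .study_seeds(cfg$seed + 1L, cfg$k)
  rows <- vector("list", cfg$k)
  for (i in seq_len(cfg$k)) {
    set.seed(seeds[i])
    n <- round(exp(stats::runif(1, log(n_range[1L]), log(n_range[2L]))))
    X <- matrix(stats::rnorm(n * 3L), n, 3L) %*% sq
    C <- stats::cor(X)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    rows[[i]] <- data.frame(
      study_id = sprintf("med%04d", i), n = n,
      r_xy = C[1L, 3L], r_xm = C[1L, 2L], r_my = C[2L, 3L],
      psd = min(ev) > 1e-6
    )
  }
  do.call(rbind, rows)
}
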