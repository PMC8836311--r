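# Orchestration: run the enabled analysis stages in dependency order and
# export tidy per-stage tables plus a single summary JSON. The package's
# functions (and this driver) are the command-line surface; a shell user
# can invoke `Rscript -e 'specmeta::run_pipeline(...)'` with a JSON config.

#' Run the full analysis pipeline
#'
#' Stages (in dependency order): `overall`, `subgroups`, `metaregression`,
#' `bias`, `multiverse`, `gosh`, `mediation`. Stochastic stages require a
#' seed; re-running with an identical config reproduces every output file.
#'
#' @param config Either a path to a JSON file or a list with elements
#'   `input` (CSV path; `NULL` uses the packaged table), `stages`
#'   (character vector; default all non-stochastic stages plus any for
#'   which parameters are supplied), `out_dir` (`NULL`: no files written),
#'   `alpha`, `B` (bootstrap replicates; enables the multiverse null test),
#'   `n_subsets` (GOSH draws), `seed`, `mediation_input` (CSV of
#'   correlation triplets).
#' @return Invisibly, a named list ("report bundle") with one element per
#'   executed stage plus `summary` and `counts` (the record counts flowing
#'   through each filter).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- utils::modifyList(list(
    input = NULL, stages = c("overall", "subgroups", "metaregression",
                             "bias", "multiverse"),
    out_dir = NULL, alpha = 0.05, B = NULL, n_subsets = NULL, seed = NULL,
    mediation_input = NULL
  ), config)
  stochastic <- c(!is.null(cfg$B), !is.null(cfg$n_subsets))
  if (any(stochastic) && is.null(cfg$seed)) {
    stop("a seed is required when stochastic stages are enabled",
         call. = FALSE)
  }
  ds <- if (is.null(cfg$input)) ri_studies() else read_studies(cfg$input)
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(stage, k) {
    message(sprintf("[%6.1fs] %-14s k = %s", proc.time()[["elapsed"]] - t0,
                    stage, paste(k, collapse = " / ")))
  }
  bundle <- list()
  counts <- list(total = nrow(ds),
                 published = nrow(filter_studies(ds, published_only = TRUE)),
                 published_significant_negative = nrow(
                   filter_studies(ds, published_only = TRUE,
                                  significant_only = TRUE, direction = -1)))
  if ("overall" %in% cfg$stages) {
    bundle$overall <- rema(data = ds, estimator = "DL")
    bundle$overall_reml <- rema(data = ds, estimator = "REML")
    log_stage("overall", bundle$overall$k)
  }
  if ("subgroups" %in% cfg$stages) {
    bundle$subgroups <- list(
      intelligence = subgroup_test(ds, "intelligence_type"),
      religiosity = subgroup_test(ds, "religiosity_type"),
      sample = subgroup_test(ds, "sample_type"),
      publication = subgroup_test(ds, "publication_status")
    )
    log_stage("subgroups", vapply(bundle$subgroups,
                                  function(s) length(s$levels), 0L))
  }
  if ("metaregression" %in% cfg$stages) {
    bundle$metaregression <- list(
      pct_men = meta_regress(ds, "pct_men"),
      year = meta_regress(ds, "year")
    )
    if (!all(is.na(ds$quality))) {
      bundle$metaregression$quality <- meta_regress(ds, "quality")
    }
    log_stage("metaregression", bundle$metaregression$pct_men$k)
  }
  if ("bias" %in% cfg$stages) {
    bundle$bias <- bias_battery(ds, alpha = cfg$alpha)
    log_stage("bias", bundle$bias$p_curve$k_used)
  }
  if ("multiverse" %in% cfg$stages) {
    if (!is.null(cfg$B)) {
      bundle$multiverse <- bootstrap_null_test(ds, B = cfg$B,
                                               seed = cfg$seed,
                                               alpha = cfg$alpha)
    } else {
      bundle$multiverse <- run_multiverse(ds, alpha = cfg$alpha)
    }
    log_stage("multiverse", bundle$multiverse$n_admissible)
  }
  if ("gosh" %in% cfg$stages || !is.null(cfg$n_subsets)) {
    bundle$gosh <- gosh(ds, n_subsets = cfg$n_subsets %||% 10000L,
                        seed = cfg$seed %||% 1L)
    log_stage("gosh", nrow(bundle$gosh$samples))
  }
  if ("mediation" %in% cfg$stages && !is.null(cfg$mediation_input)) {
    mats <- utils::read.csv(cfg$mediation_input)
    pooled <- pool_matrices(mats)
    bundle$mediation <- fit_mediation(pooled, seed = cfg$seed %||% 1L)
    log_stage("mediation", pooled$k)
  }
  bundle$counts <- counts
  bundle$summary <- .bundle_summary(bundle)
  if (!is.null(cfg$out_dir)) .write_bundle(bundle, ds, cfg$out_dir)
  invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.bundle_summary <- function(bundle) {
  s <- list(counts = bundle$counts)
  if (!is.null(bundle$overall)) {
    o <- bundle$overall
    s$overall <- list(estimate_r = o$estimate_r, ci = c(o$ci_low_r,
                                                        o$ci_high_r),
                      k = o$k, Q = o$Q, I2 = o$I2, I2_tau2 = o$I2_tau2,
                      tau2 = o$tau2)
  }
  if (!is.null(bundle$multiverse)) {
    m <- bundle$multiverse
    s$multiverse <- list(n_total = m$n_total, n_admissible = m$n_admissible,
                         n_sig_negative = m$n_sig_negative,
                         n_sig_positive = m$n_sig_positive,
                         decision = m$decision)
  }
  if (!is.null(bundle$bias)) {
    s$bias <- lapply(bundle$bias, function(b) {
      list(statistic = b$statistic, p = b$p,
           adjusted_estimate_r = b$adjusted_estimate_r, k = b$k_used)
    })
  }
  if (!is.null(bundle$gosh)) {
    s$gosh <- list(share_negative = bundle$gosh$share_negative,
                   leverage = bundle$gosh$leverage_ids)
  }
  s
}

.write_bundle <- function(bundle, ds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(bundle$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  export_plot_data("forest", rema(data = ds), out_dir)
  export_plot_data("funnel", filter_studies(ds, published_only = TRUE),
                   out_dir)
  if (!is.null(bundle$multiverse)) {
    export_plot_data("spec_curve", bundle$multiverse, out_dir)
    export_plot_data("p_histogram", bundle$multiverse, out_dir)
  }
  if (!is.null(bundle$gosh)) export_plot_data("gosh", bundle$gosh, out_dir)
  invisible(out_dir)
}

#' Export tidy plot data for one analysis stage
#'
#' Writes (and returns) the tidy table behind each figure-equivalent:
#' study-level rows for `"forest"` and `"funnel"`, one row per
#' specification for `"spec_curve"` (plus one per rank for its null bands),
#' bin rows for `"p_histogram"`, subset rows for `"gosh"`, and study rows
#' with the fitted line for `"metareg"`.
#'
#' @param stage One of `"forest"`, `"funnel"`, `"spec_curve"`,
#'   `"p_histogram"`, `"gosh"`, `"metareg"`.
#' @param results The stage's result object (see Details above).
#' @param dir Output directory; `NULL` returns the table without writing.
#' @return The tidy `data.frame`, invisibly when written.
#' @export
export_plot_data <- function(stage, results, dir = NULL) {
  tab <- switch(stage,
    forest = {
      stopifnot(inherits(results, "rema"))
      zc <- stats::qnorm(1 - (1 - results$level) / 2)
      data.frame(study = results$labels, y = results$y,
                 se = sqrt(results$vi),
                 ci_low = results$y - zc * sqrt(results$vi),
                 ci_high = results$y + zc * sqrt(results$vi),
                 weight = as.numeric(stats::weights(results)))
    },
    funnel = funnel_data(results),
    spec_curve = {
      out <- as.data.frame(results)
      if (!is.null(results$null_bands)) {
        out <- merge(out, results$null_bands, by = "rank")
      }
      out
    },
    p_histogram = spec_p_histogram(results),
    gosh = as.data.frame(results),
    metareg = {
      stopifnot(inherits(results, "rema_reg"))
      x <- results$X[, 2L]
      data.frame(moderator = x, y = results$y, vi = results$vi,
                 fitted = drop(results$X %*% results$coefficients))
    },
    stop("unknown stage: ", stage, call. = FALSE)
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(dir, paste0(stage, ".csv")),
                     row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
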