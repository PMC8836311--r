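# Small in-code fixtures and independent oracles shared across tests.

make_ds <- function(r, n, religiosity = "beliefs", sample = "college",
                    publication = "published", intelligence = "iq",
                    pct_men = NA_real_, p_value = NA_character_) {
  k <- length(r)
  as_meta_dataset(data.frame(
    study_id = sprintf("t%03d", seq_len(k)),
    author = "test", year = 2000L, n = n, r = r,
    p_value = rep_len(p_value, k),
    sample_type = rep_len(sample, k),
    pct_men = rep_len(pct_men, k) / 100,   # stored as proportion
    religiosity_type = rep_len(religiosity, k),
    intelligence_type = rep_len(intelligence, k),
    publication_status = rep_len(publication, k),
    quality = NA_integer_,
    stringsAsFactors = FALSE
  ), provenance = "test")
}

# brute-force restricted-likelihood grid search, the REML oracle
reml_grid_oracle <- function(y, vi, grid = seq(0, 1, by = 1e-4)) {
  nll <- vapply(grid, function(t2) {
    wi <- 1 / (vi + t2)
    mu <- sum(wi * y) / sum(wi)
    0.5 * (sum(log(vi + t2)) + sum(wi * (y - mu)^2) + log(sum(wi)))
  }, 0)
  grid[which.min(nll)]
}

# direct DL pooling used as an independent check (written from the formula,
# not shared with package internals)
dl_oracle <- function(y, vi) {
  w <- 1 / vi
  yb <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yb)^2)
  t2 <- max(0, (Q - (length(y) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wi <- 1 / (vi + t2)
  list(est = sum(wi * y) / sum(wi), se = sqrt(1 / sum(wi)), Q = Q, tau2 = t2)
}
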