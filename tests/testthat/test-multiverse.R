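test_that("specification enumeration is the full Cartesian product", {
  expect_equal(nrow(enumerate_specifications(spec_grid())), 576L)
  g1 <- spec_grid(religiosity = "all", sample = "all", publication = "all",
                  metric = "z", estimator = "DL")
  expect_equal(nrow(enumerate_specifications(g1)), 1L)
  g8 <- spec_grid(religiosity = c("beliefs", "behavior"),
                  sample = c("college", "all"), publication = "all",
                  metric = "z", estimator = c("DL", "FE"))
  expect_equal(nrow(enumerate_specifications(g8)), 8L)
  expect_error(spec_grid(metric = character(0)), "no levels")
  # deterministic order: religiosity varies slowest
  e <- enumerate_specifications(spec_grid())
  expect_equal(e$religiosity[1], "beliefs")
  expect_equal(unique(e$religiosity),
               c("beliefs", "behavior", "mixed", "all"))
})

test_that("a single-cell multiverse reproduces the direct fit bit for bit", {
  ds <- ri_studies()
  g1 <- spec_grid(religiosity = "all", sample = "all", publication = "all",
                  metric = "z", estimator = "DL")
  sc <- run_multiverse(ds, g1)
  direct <- rema(data = ds, estimator = "DL", metric = "z")
  expect_identical(sc$results$estimate_r[1], direct$estimate_r)
  expect_identical(sc$results$se[1], direct$se)
  # two identical studies, one cell: curve of length 1 at the study effect
  ds2 <- make_ds(c(0.25, 0.25), c(100, 100))
  sc2 <- run_multiverse(ds2, g1)
  expect_equal(sc2$n_admissible, 1L)
  expect_equal(sc2$results$estimate_r, 0.25, tolerance = 1e-12)
})

test_that("admissibility counts factorize over Which and How factors", {
  ds <- ri_studies()
  sc <- run_multiverse(ds)
  # brute-force subset counting per Which cell (independent reimplementation)
  rel_l <- list(beliefs = "beliefs", behavior = "behavior", mixed = "mixed",
                all = c("beliefs", "behavior", "mixed"))
  sam_l <- list(precollege = "precollege", college = "college",
                noncollege = "noncollege",
                all = c("precollege", "college", "noncollege", "mixed"))
  pub_l <- list(published = "published", unpublished = "unpublished",
                all = c("published", "unpublished"))
  n_which <- 0L
  ks <- c()
  for (a in names(rel_l)) for (b in names(sam_l)) for (cc in names(pub_l)) {
    k <- sum(ds$religiosity_type %in% rel_l[[a]] &
               ds$sample_type %in% sam_l[[b]] &
               ds$publication_status %in% pub_l[[cc]])
    if (k >= 2) {
      n_which <- n_which + 1L
      ks[paste(a, b, cc, sep = "|")] <- k
    }
  }
  expect_equal(sc$n_admissible, n_which * 12L)
  # every admissible specification's k equals the brute-force subset size
  got <- sc$results
  key <- paste(got$religiosity, got$sample, got$publication, sep = "|")
  expect_true(all(got$k == ks[key]))
  # counts are coherent
  expect_lte(sc$n_sig_negative + sc$n_sig_positive, sc$n_admissible)
  # curve sorted with deterministic tie-break
  expect_true(!is.unsorted(got$estimate_r))
})

test_that("bootstrap bands degenerate correctly at B = 1 and detect the fixture signal", {
  ds <- ri_studies()
  g <- spec_grid(religiosity = c("beliefs", "all"), sample = "all",
                 publication = "all", metric = "z", estimator = "DL")
  b1 <- bootstrap_null_test(ds, g, B = 1L, seed = 7)
  # reconstruct the single null replicate and check the type-7 band
  set.seed(7)
  ds_sim <- ds
  ds_sim$r <- tanh(rnorm(nrow(ds), 0, sqrt(1 / (ds$n - 3))))
  sim_curve <- run_multiverse(ds_sim, g)$results$estimate_r
  both <- rbind(b1$results$estimate_r, sim_curve)
  expect_equal(unname(b1$null_bands$lower),
               unname(apply(both, 2, quantile, probs = 0.025, type = 7)),
               tolerance = 1e-12)
  expect_equal(unname(b1$null_bands$upper),
               unname(apply(both, 2, quantile, probs = 0.975, type = 7)),
               tolerance = 1e-12)
  b <- bootstrap_null_test(ds, g, B = 99L, seed = 7)
  # the fixture's negative summary escapes a null band at every rank
  expect_equal(b$outside_share, 1)
  expect_equal(b$decision, "non-nill")
  # reproducibility
  b2 <- bootstrap_null_test(ds, g, B = 99L, seed = 7)
  expect_identical(b$null_bands, b2$null_bands)
  expect_error(bootstrap_null_test(ds, g, B = 99L), "seed")
})

test_that("p-value histogram export sums to the admissible count", {
  sc <- run_multiverse(ri_studies())
  h <- spec_p_histogram(sc)
  expect_equal(sum(h$count), sc$n_admissible)
  expect_equal(attr(h, "frac_significant"),
               (sc$n_sig_negative + sc$n_sig_positive) / sc$n_admissible)
})
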