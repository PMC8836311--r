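Package: specmeta
Title: Multiverse and Specification-Curve Meta-Analysis of Correlations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Random-effects meta-analysis of Pearson correlations on the
    Fisher-z scale with DerSimonian-Laird, restricted maximum-likelihood,
    fixed-effect and unweighted estimators; mixed-effects subgroup
    comparisons and precision-weighted meta-regression; seven dissemination
    bias methods (rank correlation, regression test, trim-and-fill, test of
    excess significance, p-curve, p-uniform, p-uniform*); range-restriction
    correction; combinatorial (GOSH) subset meta-analysis; multiverse /
    specification-curve analysis with a parametric bootstrap null; and
    two-stage meta-analytic mediation from pooled correlation matrices.
    Ships a packaged table of 105 independent samples relating intelligence
    and religiosity, plus a synthetic-data generator emulating the
    statistical structure the methods assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
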