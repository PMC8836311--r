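# specmeta

Multiverse and specification-curve meta-analysis of Pearson correlations,
built around the question of how robust a pooled correlation is to every
reasonable way of selecting and analyzing the data.

The motivating application is the century-old literature correlating
intelligence with religiosity: 105 independent samples (N = 201,181
participants, 1928–2020) are packaged as `ri_studies()`, each with its
sample size, correlation, reported p-value, sample type
(pre-college/college/non-college), religiosity assessment
(beliefs/behavior/mixed), intelligence assessment (IQ/GPA/mixed) and
publication status. Everything the package does, however, is generic to
correlation meta-analysis.

## The model

Per-study correlations are variance-stabilised, `z_i = atanh(r_i)` with
sampling variance `v_i = 1/(n_i − 3)`, and pooled under the random-effects
model

    z_i ~ N(θ, v_i + τ²)

with inverse-variance weights `w_i = 1/(v_i + τ̂²)`. `rema()` estimates τ²
by DerSimonian–Laird moments (`DL`), restricted maximum likelihood
(`REML`), fixes it at zero (`FE`), or ignores weighting entirely
(`UNWEIGHTED`); heterogeneity is summarised by Cochran's
`Q = Σ w_i^FE (z_i − ẑ_FE)²` and two I² conventions (the Q-based
`(Q − df)/Q` and the τ²-based `τ²/(τ² + s²)`). Around that core sit:

* **moderation** — mixed-effects subgroup contrasts (`subgroup_test()`:
  random effects within groups, fixed-effect `Q_between` across them) and
  precision-weighted meta-regression (`meta_regress()`);
* **dissemination bias** — `begg_test()`, `egger_test()`,
  `trim_and_fill()`, `excess_significance()`, `p_curve()`, `p_uniform()`,
  `p_uniform_star()` (all seven in `bias_battery()`);
* **selection-robustness** — `correct_range_restriction()` (Thorndike
  case 2), `gosh()` (summary effects over up to 100,000 random study
  subsets), and `run_multiverse()` / `bootstrap_null_test()` (the
  specification curve over a Which × How grid of data-selection and
  analysis choices, with a parametric bootstrap null band);
* **mediation** — two-stage meta-analytic path models from cellwise-pooled
  3×3 correlation matrices (`pool_matrices()`, `fit_mediation()`);
* **synthetic data** — `sim_config()` / `simulate_dataset()` generate
  datasets with the same structure (true ρ, between-study τ², log-uniform
  study sizes, moderator shifts, significance-driven publication
  selection) so every stage is testable against known truths.

## Worked example

```r
library(specmeta)
ds <- ri_studies()

rema(data = ds)
#> Random-effects meta-analysis (DL estimator, z metric)
#> k = 105  r = -0.141  95% CI [-0.161, -0.120]  p = <2e-16
#> Q(df = 104) = 1537.739, p = <2e-16;  I2 = 93.24%;  tau2 = 0.0078
```

The pooled correlation is small, negative, and extremely heterogeneous
(I² > 90%: most of the observed spread is true between-study variation,
not sampling error). Moderators explain some of it — psychometric IQ
tests correlate more strongly with religiosity than grade-point averages
do:

```r
subgroup_test(ds, "intelligence_type", c("iq", "gpa"))
#> Subgroup comparison on 'intelligence_type' (REML within, FE between)
#>   iq           k =  93  r =  -0.155  [ -0.181,  -0.128]  I2 =  96.4%
#>   gpa          k =   8  r =   0.011  [ -0.084,   0.106]  I2 =  73.9%
#> Q_between = 10.985 (df = 1), p = 0.000918
```

Selection-robustness: the p-uniform estimate, which uses only the 55
published significant direction-consistent studies and corrects for the
fact that they were selected on significance, lands on the same effect —
evidence against publication bias driving the result:

```r
p_uniform(ds)
#> p-uniform (k = 55)
#>   statistic = -0.1590, p = 0.437
#>   adjusted estimate r = -0.1716
#>   ci_r = -0.1935, -0.151
```

And the multiverse: across every admissible combination of data-selection
and analysis choices, not one specification yields a significantly
positive summary:

```r
run_multiverse(ds)
#> Specification curve: 480/576 admissible specifications (min k = 2)
#>   significant negative: 348 (72.5%);  significant positive: 0
#>   summary range: [-0.308, 0.051]
```

`bootstrap_null_test(ds, B = 999, seed = 1)` adds pointwise 2.5%/97.5%
null bands (study features fixed, effects redrawn from
`N(0, sqrt(v_i))`) and judges the curve against them.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the headline quantities from scratch with the installed
package — the overall pooled correlation and its heterogeneity, the
subgroup estimates, the p-curve/p-uniform selection-corrected estimates,
the per-study power summary of the excess-significance test, the
range-restriction-corrected college estimate, and the count of multiverse
specifications with more than one study — and writes them as a JSON map
of `{"<id>": {"value": ..., "n": ...}}`.
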