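---
title: "specmeta: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{specmeta: models, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specmeta)
```

## The pooling model

All synthesis happens, by default, on the Fisher-z scale: a study's
correlation $r_i$ from $n_i$ participants becomes $z_i = \mathrm{atanh}(r_i)$
with sampling variance $v_i = 1/(n_i - 3)$, and the random-effects model is

$$ z_i \sim N(\theta,\; v_i + \tau^2), $$

where $\tau^2$ is true between-study variance. `rema()` supports four
estimators of the pooled location:

* **DL** — DerSimonian–Laird: $\hat\tau^2 = \max\!\big(0, (Q - df)\,/\,(S_1 -
  S_2/S_1)\big)$ with $S_1 = \sum w_i$, $S_2 = \sum w_i^2$ under
  fixed-effect weights $w_i = 1/v_i$.
* **REML** — restricted maximum likelihood by bounded one-dimensional
  minimisation of the restricted negative log-likelihood (tolerance
  $10^{-10}$, $\hat\tau^2$ clipped at zero; validated in the tests against
  a brute-force likelihood grid).
* **FE** — $\tau^2 \equiv 0$.
* **UNWEIGHTED** — arithmetic mean with $SE = sd/\sqrt{k}$.

Confidence intervals are Wald-type on the analysis scale and
back-transformed; no small-sample (Knapp–Hartung) adjustment is applied,
because the published tables this package reproduces use plain Wald
arithmetic. Cochran's $Q$ is always computed under fixed-effect weights,
whatever the estimator.

**Two I² conventions.** `rema()` reports both `I2` $= \max(0,(Q-df)/Q)
\cdot 100$ and `I2_tau2` $= 100\,\hat\tau^2/(\hat\tau^2 + s^2)$ with
$s^2 = (k-1)S_1/(S_1^2 - S_2)$ the "typical" within-study variance. The
distinction matters: the published heterogeneity percentage for the
packaged dataset (≈96%) is only reproducible under the second convention
with the REML fit — the Q-based identity gives ≈93% on the same data
regardless of estimator, and would give ≈92.9% even when evaluated at the
published $Q$ itself. Verbal bands (`i2_label()`): 0–25% trivial, 25–50%
small, 50–75% moderate, 75–100% large.

## Subgroups and meta-regression

`subgroup_test()` follows the "mixed-effects" recipe: each subgroup is
pooled with its own random-effects fit (REML by default — the only
within-group estimator under which the published between-group statistics
are recovered; DL is available), and subgroup summaries are compared with
a fixed-effect model:
$Q_{between} = \sum_g w_g(\hat\theta_g - \bar\theta)^2$, $w_g = 1/se_g^2$,
referred to $\chi^2_{G-1}$. Records of the catch-all `"mixed"` sample type
are excluded from sample-type subgroup analyses (they belong to none of
the three substantive levels) but participate in every overall pooling.

`meta_regress()` fits weighted least squares on the z scale with weights
$1/(v_i + \hat\tau^2)$, where residual $\tau^2$ comes from REML (default)
or the DerSimonian–Laird-type moment estimator
$\hat\tau^2 = \max\{0, (Q_E - (k-p))/\mathrm{tr}(P)\}$ on the weighted
residual projector $P$. $R^2$ is the proportional reduction of $\tau^2$
against the intercept-only model under the same estimator — so $R^2$
depends on that choice, and the moment estimator can report $R^2 = 0$
where REML reports a modest positive value; we default to REML for
consistency with the subgroup machinery. The percentage of men enters as
a proportion in $[0,1]$, so its slope is on the "0 → 100% men" scale.
Saturated designs ($k = p$) are allowed and interpolate exactly with
$\hat\tau^2 = 0$.

## Dissemination-bias battery

All seven methods work on a direction-normalised scale (effects flipped
so the summary is positive; results flipped back) and default to the
published subset.

* **Rank correlation (Begg–Mazumdar):** Kendall's τ between the
  variance-stabilised deviates $(z_i - \hat z_{FE})/\sqrt{v_i - 1/S_1}$
  and $v_i$, tie-corrected normal p-value; conventionally judged at
  α = .10. Note this test is conservative at moderate $k$: in our own
  no-selection calibration at $k=40$ its measured size is ≈0.024 at
  nominal .05.
* **Regression test (Egger):** OLS of $z_i/se_i$ on $1/se_i$; the
  intercept's z-statistic measures small-study asymmetry.
* **Trim-and-fill:** Duval–Tweedie iteration with the $L_0$ rank
  estimator (R0 optional), DL re-pooling, missing side defaulting to the
  side opposite the summary's sign; imputed studies are mirror images
  around the trimmed centre.
* **Excess significance:** per-study power to detect the pooled summary
  at two-sided α, counting only the hypothesis-conforming tail,
  $power_i = \Phi(|\hat\theta|\sqrt{n_i-3} - z_{\alpha/2})$; the expected
  significant count $E = \sum_i power_i$ is compared with the observed
  count $O$ via $A = (O-E)^2/E + (O-E)^2/(k-E)$ (second term dropped as
  $E \to k$). Because "the primary studies" can be read as the full set or
  the published set, `bias_battery()` reports both.
* **p-curve:** on the significant, direction-conforming studies
  (significance recomputed from $(r, n)$ — reported p-values are rounded
  or printed as bounds), conditional p-values
  $pp_i(\theta) = \bar\Phi\!\big((z_i-\theta)/se_i\big) \big/
  \bar\Phi\!\big((c_i-\theta)/se_i\big)$ with $c_i = z_{\alpha/2} se_i$,
  computed in log space (the mega-sample studies otherwise underflow).
  The right-skew (evidential value) and 33%-power (flatness) tests
  aggregate $\Phi^{-1}(pp)$ by Stouffer's method; the effect estimate
  minimises the Kolmogorov–Smirnov distance of $\{pp_i(\theta)\}$ from
  uniform (bounded search, tolerance $10^{-6}$).
* **p-uniform:** the estimate solves the moment condition
  $\sum_i pp_i(\theta) = k/2$ ("P" method, the field's default; the
  log-based condition $\sum -\ln pp_i = k$ is available as `"LNP"` but is
  dominated by the largest samples, whose $-\ln pp$ explode — on the
  packaged data it is pulled to ≈−.29 while "P" agrees with the other
  estimators). Confidence limits invert the sum statistic at
  $k/2 \pm z_{.975}\sqrt{k/12}$ (normal approximation to the Irwin–Hall
  distribution); the publication-bias test evaluates the $pp$'s at the
  fixed-effect estimate of the selected studies and reports the one-sided
  left-skew z-test. Root-finding brackets $(-2, 2)$ on the z scale,
  doubled up to four times.
* **p-uniform\*:** joint conditional ML of $(\theta, \tau^2)$ over all
  (published) studies, each study's $N(\theta, v_i + \tau^2)$ density
  truncated to its own two-sided significance stratum — significant
  studies to $\{|z| > c_i\}$, non-significant to the complement — under
  the assumption that publication probability is constant within a
  stratum. L-BFGS-B with $\tau^2 \ge 0$; a single-stratum dataset (e.g.
  uniformly non-significant studies under a true null) remains
  identified. Parameter recovery is verified by simulation in the tests.

## The packaged dataset and its reconciliation

`ri_studies()` transcribes, mechanically and verbatim, the printed table
of 105 independent samples correlating intelligence with religiosity
(1928–2020). Cross-checks against the published marginal counts all pass
(105 samples; 88 published / 17 unpublished; 93 IQ / 8 GPA / 4 mixed
intelligence assessments; 76 samples with sex breakdowns). One
reconciliation was applied and is flagged in the loader's documentation:
an adolescent cohort printed as pre-college is coded `"mixed"` sample
type here, because the published pre-college subgroup statistics are
reproduced to three decimals exactly (at both the all-assessments and
IQ-only subgroup sizes) only without it, while no placement in the other
two levels reproduces theirs.

Beyond that, the printed table and the analysis dataset behind the
published statistics demonstrably differ in a handful of entries: the
total N differs by 276, the overall Q differs by ≈5%, and the
religiosity-type composition differs (67/11/27 stated vs 72/11/22
printed) in a way that no relabelling of rows can reconcile (we searched
the space of 5-row recodings against four published subgroup statistics;
no solution exists). Several subgroup statistics are nonetheless
reproduced exactly, which pins the divergence to the source rather than
to the transcription. The acceptance tests assert published values at
their printed precision, so the affected assertions stay visibly red
rather than being loosened; every such case is annotated in the test
file's preamble.

## Multiverse and specification curve

The Which factors select data — religiosity assessment (beliefs /
behavior / mixed / all), sample type (pre-college / college /
non-college / all), publication status (published / unpublished / all) —
and the How factors select the analysis: effect metric and estimator.
`"all"` imposes no filter; mixed-type samples are reachable only through
`"all"`. The default grid is $4 \times 4 \times 3 = 48$ data cells
crossed with $3 \times 4 = 12$ analysis cells (576 specifications);
admissibility requires at least `min_k = 2` records.

Two open choices deserve note:

* **The third effect-size metric.** Alongside Fisher-z (variance
  $1/(n-3)$) and raw $r$ (variance $(1-r^2)^2/(n-1)$), the grid carries
  `nw`: raw correlations with $n$-proportional weights, the
  Hunter–Schmidt-style "bare bones" synthesis. It is a placeholder for a
  third conventional choice rather than a canonical one, and counts that
  hinge on it (e.g. how many specifications reach significance) inherit
  that uncertainty.
* **The realized grid.** On the packaged data the full 48-cell grid
  yields 480 admissible specifications. The published specification-curve
  results, however, factorize exactly as $16 \times 12$ — the signature
  of an analysis in which the publication factor never varied. The
  acceptance computation therefore also runs the realized grid
  (`spec_grid(publication = "all")`: 16 data cells, all admissible, 192
  specifications), and both readings are exercised in the tests.

Curves are sorted by the pooled correlation with deterministic
lexicographic tie-breaking, so identical inputs give byte-identical
outputs.

**The parametric bootstrap null.** Study features are fixed; each
replicate redraws every study's z-effect from $N(0, \sqrt{v_i})$ — the
fixed-effect sampling standard error — reruns the full multiverse, and
sorts its curve. Pointwise 2.5%/97.5% quantiles (type-7 interpolation)
over the $B+1$ curves (simulated plus observed) form the null band at
each rank. Because under a true null the observed curve should escape a
95% band at about 5% of ranks, the decision rule declares the summary
**non-nill** when the escape fraction exceeds $1 - level$; calibration of
that rule on true-null synthetic data (escape ≈5%, i.e. coverage ≈95%)
is part of the acceptance suite, with $B = 199$ and 200 meta-replicates
as a runtime-scaled stand-in for the canonical $B = 999$.

## Combinatorial (GOSH) analysis

Subset sizes are drawn uniformly on $[2, K]$ and members uniformly
without replacement; duplicates are rejected by hashing, and when the
feasible count $2^K - 1 - K$ is within budget the enumeration is
exhaustive instead (the tests verify exhaustive agreement with brute
force at $K = 12$). With oversampling enabled, half the draws must
contain one of the two most extreme observed correlations, so outlier
influence is visible in the subset cloud. Both knobs — the size
distribution and the definition of "extreme" — are conventions chosen
here for symmetry, not canon. The two leverage studies flagged per
subset are identified by leave-one-out influence on the pooled estimate,
not hard-coded.

## Two-stage mediation

Stage 1 pools each cell of the study-level 3×3 correlation matrices
(predictor x, mediator m, outcome y) independently by DL on the Fisher-z
scale; studies contribute whatever cells they report. This
cellwise-univariate stage is a deliberate simplification of full
two-stage SEM with a joint asymptotic covariance: the quantities it
feeds (pooled correlations, partial correlations, standardized paths)
are reproducible without the joint covariance, and the Monte-Carlo
interval below treats cells as independent — adequate when cell
correlations come from largely overlapping study sets with modest
between-cell dependence, and flagged here as the main caveat. The pooled
matrix is projected to the PSD cone when needed (eigenvalues clipped at
$10^{-6}$, unit diagonal restored, flag raised).

Stage 2 is standardized path algebra: $a = r_{xm}$,
$b = (r_{my} - r_{xm} r_{xy})/(1 - r_{xm}^2)$, direct
$c' = (r_{xy} - r_{xm} r_{my})/(1 - r_{xm}^2)$, indirect $ab$, and
$total = c' + ab = r_{xy}$ exactly (to $10^{-10}$, a test invariant).
Intervals come from 10,000 seeded Monte-Carlo draws of the stage-1 cell
estimates from their asymptotic normals on the z scale; the mediation
verdict is `none` / `partial` / `full` according to whether the indirect
and direct intervals exclude zero. The per-study correlation triplets
behind the published education and cognitive-style mediations live in
supplementary files that are not packaged; the machinery is therefore
validated against simulated truths with known paths rather than against
published path values.

## The synthetic-data generator

`simulate_dataset()` emulates the structure the pipeline assumes — and
its defaults are the packaged dataset's stated world: $k = 105$, true
$\rho = -0.15$, $\tau^2 = 0.018$ (z² units), study sizes log-uniform on
$[20, 40000]$ (matching the observed 20–37,078 span; log-uniform because
study sizes in this literature spread over three orders of magnitude
with heavy small-study mass), moderator level probabilities equal to the
observed composition with zero shifts, and no publication selection.
Selection, when enabled, acts on each study's own two-sided p-value and
sign — publication probability `prob_sig` vs `prob_nonsig` — reflecting
the premise that selective reporting responds to significance rather
than to effect magnitude. One RNG substream per study (derived once from
the master seed) makes datasets byte-reproducible and extensible:
raising $k$ appends studies without reshuffling earlier ones.

What the generator does **not** emulate: correlated moderators (real
sample types and assessment types co-occur non-independently), rounding
of reported correlations to two decimals, p-value bounds, multiple
effect sizes per article, or time trends. A green simulation test
therefore establishes calibration of the statistics under the model's
own assumptions, not robustness to those real-data features.

## Numerical conventions

* REML optimisation: bounded on $[0, \max(10\,\mathrm{var}(y),
  10\,\bar v, 10^{-3})]$, tolerance $10^{-10}$; boundary preferred when
  the likelihood is flat at zero.
* p-curve/p-uniform estimation: conditional p-values in log space;
  KS search tolerance $10^{-6}$; p-uniform root bracket $(-2, 2)$ in z,
  doubled up to four times.
* Trim-and-fill: at most 50 iterations, convergence when $k_0$
  stabilises; $k_0$ capped at $k - 2$.
* Ties in specification curves: lexicographic on the specification's
  factor levels. Quantiles: type 7 everywhere.
* PSD projection floor: $10^{-6}$.
* Degenerate inputs: $k = 1$ pooling returns the study itself with
  heterogeneity flagged `NA`; empty filter results return a zero-row
  dataset rather than an error; excess-significance handles $E \to k$.

## Known limitations

* Wald intervals throughout; no Knapp–Hartung or prediction-interval
  based inference for subgroup contrasts.
* The bias battery's normal-approximation pp-values ignore the exact
  t-distribution of correlations at very small $n$ (the packaged data's
  smallest sample is $n = 20$, where the approximation is still
  serviceable).
* Cellwise stage-1 mediation (no joint asymptotic covariance), as
  discussed above.
* `UNWEIGHTED` pooling reports a normal-theory interval from
  $sd/\sqrt{k}$; for very small $k$ a t-interval would be wider.
* The multiverse's third effect-size metric is a documented placeholder;
  conclusions that depend on it should be checked under
  `spec_grid(metric = c("z", "r"))`.
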