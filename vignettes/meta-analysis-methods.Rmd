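---
title: "Methods: meta-analysis of harvesting effects on forest carbon pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of harvesting effects on forest carbon pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaharvest)
```

## The problem

Forest harvesting redistributes carbon among ecosystem pools — live trees,
snags, understory vegetation, coarse woody debris, the forest floor and the
mineral soil — and the literature reports treatment/reference comparisons
of those pools at many different times since cutting, in different biomes,
with heterogeneous designs and incomplete variance reporting. `metaharvest`
implements the analysis chain needed to synthesize such a database:
per-observation effect sizes, heterogeneity partitioning with hierarchical
moderator selection, random-effects pooling and mixed-effects
meta-regression on parallel weighted and unweighted tracks, nonparametric
bootstrap confidence intervals, and AIC-based selection of
time-since-treatment trend models. A synthetic-data generator with a fully
known generative truth makes every stage testable end to end.

## Effect sizes

The unit of analysis is the log response ratio of a harvested stand against
an uncut reference,

$$RR = \ln\left(\bar{X}_T / \bar{X}_C\right),$$

with the delta-method standard error

$$SE(RR) = \sqrt{\frac{SE_{\bar{X}_T}^2}{\bar{X}_T^2} +
                 \frac{SE_{\bar{X}_C}^2}{\bar{X}_C^2}},$$

so each arm contributes only through the relative error of its mean; the
statistic is invariant to rescaling either arm. Results are displayed as
the percent difference $(e^{RR}-1)\cdot 100$, which is bounded below by
$-100\%$.

Two domain conventions are wired in as small utilities: a biomass-to-carbon
conversion with a default carbon fraction of 0.5, and a generic power-law
allometric evaluator $\sum_j a_j\,\mathrm{dbh}^{b_j}$ whose coefficients
must always be supplied by the caller — species-specific published
coefficient tables are deliberately not bundled, and no silent default
exists.

**Zero treatment means.** A harvested stand can carry exactly zero carbon
in a pool (live trees immediately after clearcutting). $\ln 0$ is
undefined, so such observations are flagged `defined = FALSE`, carry a
display value of $-100\%$, and are excluded from every log-scale model fit.
No offset constant is added: an offset would silently shift every weighted
estimate, whereas exclusion is explicit and countable (`n_undefined` in all
stratum and bin tables). The binned time profiles are the only place where
these rows surface, and only at the display layer.

## Heterogeneity partitioning

For a categorical moderator, total heterogeneity
$Q_{total}=\sum_i w_i (y_i - \bar{y}_w)^2$ around the weighted grand mean
splits into a within-group part $Q_w$ (the same statistic around group
means) and a between-group part $Q_b = Q_{total} - Q_w$, referred to a
$\chi^2$ distribution on (groups − 1) degrees of freedom. Weights are
$1/SE(RR)^2$ on the weighted track and unit weights on the unweighted
track; both use identical formulas, so the machinery serves the full
dataset even where variance information is missing. With unit weights the
$\chi^2$ reference is conservative whenever the true effect variance is
below one, which should be kept in mind when reading unweighted p-values.

The hierarchical selection procedure tests every remaining candidate
moderator at a node, splits on the candidate with the largest significant
$Q_b$ ($p < \alpha$, default 0.05), and recurses into each level until no
candidate is significant or a subgroup is too small. Three numerical
choices make this deterministic and stable:

* **Tie-break**: candidates are held in a fixed priority order (pool,
  treatment, time class, biome, reference type by default);
  `which.max` keeps the first of tied $Q_b$ values.
* **Minimum subgroup size**: 3 effects per level (configurable). A Q test
  on one or two observations per group is uninformative; smaller subgroups
  become explicit "insufficient data" leaves.
* **No multiple-testing correction** across candidates, matching the
  usual practice for this style of variance partitioning. Consequently a
  truly null moderator still splits a node about $\alpha$ of the time;
  partition trees should be read structurally, not as a family-wise test.

Continuous time enters as a categorical decade-bin factor
(`assign_time_class`, bins $[0,10), [10,20), \dots$; width configurable),
because a grouping-style Q analysis needs classes and no canonical bin
edges exist for such data.

## Random-effects pooling and meta-regression

Intercept-only pooling assumes $y_i \sim N(\mu,\ se_i^2+\tau^2)$ and
estimates $\tau^2$ either by the closed-form DerSimonian–Laird moment
estimator or by REML. The REML profile in $\tau^2$ is maximized by
golden-section search on $[0, \max(10\,\mathrm{var}(y),\ \max se_i^2)]$
with tolerance $10^{-12}$, and the boundary value $\tau^2=0$ is checked
explicitly against the interior optimum; agreement with an independent
implementation is verified in the test suite to $\sim10^{-5}$. Negative
moment estimates are truncated at zero. The pooled mean uses weights
$1/(se_i^2+\hat\tau^2)$ with a Wald interval.

`fit_meta_regression` exposes the two parallel tracks behind one surface:

* **Weighted**: inverse-variance mixed-effects meta-regression via
  `metafor::rma.mv`, sampling variances known, moderators as fixed
  effects, random intercepts for biome and decade time class.
* **Unweighted**: the same fixed/random structure as a linear mixed model
  on $RR$ via `lme4::lmer` with unit residual weighting, which admits the
  rows lacking variance information. Because several observations usually
  share a source publication, a `study_id` random intercept is on by
  default on this track (and off on the weighted one, where the
  inverse-variance weights are the primary uncertainty carrier; both
  settings are a single argument away).

Random factors observed at a single level are dropped with a warning;
rank-deficient fixed designs fail naming the aliased columns. With an
intercept-only fixed part and no random terms the weighted track reduces
exactly to `pool_random_effects`, and that nesting identity is tested.

Back-transformation to the percent scale is applied **after** pooling,
never before: the mean of per-observation percent differences is a
different (and, for the skewed exponential transform, biased) estimator,
and a regression test guards against reintroducing it.

## Bootstrap confidence intervals

The unweighted track uses nonparametric case resampling: whole studies are
drawn with replacement (preserving within-study correlation; observation
resampling is available for sensitivity analysis), the statistic is
recomputed per replicate, and percentile bounds are reported. Replicates on
which the statistic fails are dropped and counted, with a warning above 10%
failures and an error when all fail. Every bootstrap is deterministic under
a fixed seed, and functions that run many bootstraps internally
(per-stratum estimates, binned profiles) derive per-cell sub-seeds from the
one seed they are given.

For the per-stratum display table the unweighted point estimate is the
plain stratum mean of $RR$. Within a single pool × treatment × biome cell a
time-class random-intercept model is frequently singular and would have to
be refit on the order of a thousand times inside each bootstrap; the mean
keeps the bootstrap exact and fast, while the full random-effects structure
remains available through `fit_meta_regression` for inferential contrasts.

## Time trends

`fit_time_trend` regresses $RR$ on continuous time since treatment under
three families: linear, a single cubic polynomial, and a natural cubic
spline with interior knots at the 25/50/75% time quantiles (fitted by
polynomial regression). Fitting is on the log scale by default so
back-transformed predictions cannot cross $-100\%$; a percent-scale
sensitivity mode exists and is the one place the $-100\%$ rows can enter a
fit. Predictions are clamped to the observed time range (no extrapolation
beyond the longest chronosequence of each treatment).

`select_trend_model` implements "keep the significant models, then choose
by AIC". *Significant* is defined per family by its defining terms: the
linear slope is tested against the intercept-only model, and the curvature
terms of the cubic and spline families are tested against the nested linear
model (F tests at $\alpha$). Testing curvature against the linear model —
rather than all non-intercept terms against the intercept — is what makes
the selection consistent on a truly linear truth: without it, a cubic
overfit would beat the linear model on raw AIC in roughly 13% of
replicates purely by chance. When no family survives, the intercept-only
fit is returned with an explicit diagnostic.

`binned_time_profile` provides the complementary nonparametric view:
per treatment × pool × decade bin, the unweighted mean with a study-level
bootstrap percentile CI, back-transformed. Empty bins are reported empty,
never interpolated.

## The synthetic-data generator

`generate_dataset` simulates the data structure the analysis assumes, and
its defaults are the package's reference study conditions: 61 studies;
43.1% boreal observations; partial cutting roughly half as frequent in
boreal as in temperate studies (10.3% vs 20.6%); pool composition led by
live trees (25.4%) and forest floor (20.1%); clearcut chronosequences with
median near 15 years reaching 110 years, partial-cut ones with median near
9 years reaching 50; between-study SD $\tau = 0.2$; within-arm CV 0.3 with
3–10 replicate plots; and 19% of rows stripped of variance information
(81% complete). Reference-stand pool ranges are sized so a fully measured
unit totals roughly 220 Mg C ha⁻¹ with live trees and mineral soil
dominating.

Noise enters at two levels: a study-level deviation
$b_s \sim N(0, \tau^2)$ shared by all of a study's observations (on the
log scale, matching the random-effects model), and within-arm sampling
error on the arithmetic scale, Normal with SD $cv \cdot \mu / \sqrt{n}$,
truncated just above zero for the reference arm so the ratio stays
defined. Both arms of a comparison share the drawn replicate count, as in
paired plot designs; a useful side effect is that the leading-order bias
terms of $\ln\bar{X}$ cancel exactly between arms.

True effects are a per-(pool, treatment, biome) constant unless a
trajectory is configured for the (pool, treatment) pair. The default
trajectories encode the qualitative recovery arcs of such data: live trees
recover linearly after partial cutting (from −50% toward −25% over 50
years) and along a steep saturating curve after clearcutting
($\theta(t) = -3.9\,e^{-t/15}$: near-total loss at the origin, close to
the reference by year 60, crossing the partial-cut line near year 33);
coarse woody debris follows a U-shaped quadratic (input pulse at harvest,
deficit near year 25), capped above at its initial pulse so the rising
tail levels off instead of diverging on century-long chronosequences; and
understory vegetation pulses upward and decays within about two decades. A
dedicated flag generates exact zero live-tree stocks for clearcut rows
within a year of harvest, so downstream zero handling is exercised.

What the generator does **not** emulate: correlated pool responses within
a unit beyond the shared study effect, non-Normal heavy-tailed sampling
error, measurement-protocol differences between studies (e.g. variable
soil sampling depths affect only a metadata column), publication bias, and
any mechanistic carbon dynamics — trajectories are phenomenological
stand-ins. Passing recovery tests therefore demonstrates that the
estimators recover the truth under the stated statistical model, not that
the model captures every feature of field data.

## Validation design and problem sizes

The test suite follows an oracle-first pattern. Closed-form hand examples
pin the effect-size formulas to $10^{-10}$; an explicit-loop
implementation (no algebraic shortcuts) is the oracle for the Q
decomposition over a thousand random instances; the DerSimonian–Laird
estimator is checked against its hand formula on two-study instances and
`metafor::rma` serves as an independent reference for REML. Statistical
properties use simulation at sizes chosen to keep Monte-Carlo error well
below the tolerance being asserted: null calibration of $Q_{total}$ at
2,000 replicates; pooling recovery at $\theta=-0.3$, $\tau=0.2$, 200
studies and 500 replicates; bootstrap coverage at 300 outer replicates of
a 61-study dataset with 500 resamples each; hierarchical-selection
recovery and trend-family selection at 100–200 replicates. All simulations
run under fixed seeds.

## Known limitations

* The weighted and unweighted tracks answer subtly different questions
  when missingness of variance information is not at random; the package
  reports both but cannot reconcile them.
* The unit-weight Q test is conservative for effects with variance below
  one (see above); moderator selection on the unweighted track is
  accordingly conservative.
* Percentile bootstrap intervals undercover slightly for small numbers of
  studies; with fewer than ~20 studies in a stratum the intervals should
  be read as approximate.
* The hierarchical partition is a greedy procedure: a moderator masked at
  the root by a correlated competitor can fail to appear even when it is
  marginally significant.
* No publication-bias diagnostics are provided.
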