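---
title: "Spatial analysis and prediction of crime reporting delays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial analysis and prediction of crime reporting delays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reportlag)
```

## The problem

Many serious crimes — rape in particular — are reported to police only
after a delay of days, weeks or sometimes years. The delay between the
occurrence date and the report date is informative twice over: long delays
are a close proxy for under-reporting, and they carry direct forensic and
clinical consequences (evidence recovery windows of roughly one day, one
week and one month). `reportlag` implements an analysis framework for
event-level reporting-delay data aggregated over police districts:

1. **Delay construction** — whole-day delays $\Delta t_i$, the nested
   binary indicators $d_i^{day}, d_i^{week}, d_i^{month}$
   ($\Delta t \le 1, 7, 30$ days), the log transform, and district-level
   proportions $p_j = n_j^{-1}\sum_{i \in j} d_i$ and median delays.
2. **Areal aggregation** — population-weighted transfer of census-tract
   covariates onto districts via polygon-interior intersection.
3. **Spatial autocorrelation** — global and local Moran's I under queen,
   k-nearest-neighbour and same-district weights, with permutation pseudo
   p-values.
4. **Spatial disparity** — a ranked-median permutation envelope and
   one-sided Gini / inter-decile-range permutation tests on district
   median delays.
5. **Staged prediction** — five model specifications crossed with four
   learners under 10-fold cross-validation, and residual
   spatial-autocorrelation (RSA) diagnostics that ask whether a model has
   absorbed the spatial signal.

Everything runs against a bundled synthetic generator, so the full
pipeline is testable without external data. Real open-data extracts can be
supplied via the CSV/GeoJSON readers; such inputs must use a projected
planar CRS (the package does no CRS handling).

## Spatial statistics

With $m$ districts, binary (not row-standardized) weights $w_{j,l}$ and an
attribute $p_j$ with mean $\bar p$:

$$I_{global} = \frac{m}{\sum_{j,l} w_{j,l}}\;
\frac{\sum_{j,l} w_{j,l}(p_j-\bar p)(p_l-\bar p)}{\sum_j (p_j-\bar p)^2},
\qquad
I_j = \frac{(m-1)\,(p_j-\bar p)}{\sum_{l\ne j}(p_l-\bar p)^2}
\sum_{l\ne j} w_{j,l}(p_l-\bar p).$$

Inference is by random relabeling of the values over the units (B = 999 by
default), upper-tailed because the working hypothesis is clustering, with
the add-one convention $p = (1+\#\{I^{(b)} \ge I\})/(1+B)$ so p is never
zero. Local statistics use conditional permutation (unit $j$ held fixed,
the rest shuffled), the standard practice. Both statistics are verified in
the tests against naive double-sum evaluation, and the row-standardized
variant against `ape::Moran.I`. Queen contiguity means sharing at least
one boundary point — corner contacts count.

## Population-weighted aggregation

For tract $b_k$ (population $x_k$) and district $a_j$, with interior
intersection $II_{k\cap j}$:
$P^A_{j|k} = A(II_{k\cap j})/A(b_k)$, $x_{k\cap j} = P^A_{j|k}x_k$,
$x_j = \sum_k x_{k\cap j}$ and $P^x_{k|j} = x_{k\cap j}/x_j$, assuming a
uniformly distributed population within each tract. Intensive attributes
(percentages, medians, averages) aggregate as
$\bar X_j = \sum_k P^x_{k|j}\,attr_k$; extensive attributes (`pop.total`,
`occ.units`) are instead area-apportioned and summed, because
population-proportion-weighting a total double-counts. The
intensive/extensive classification ships as a config table
(`attribute_classes()`). Intersections with area fraction below $10^{-9}$
are dropped as slivers; boundary point-in-polygon ties go to the smallest
tract id.

The geometry layer (shoelace areas, ray-casting point-in-polygon,
Sutherland–Hodgman clipping) is implemented in the package and requires at
least one polygon of each intersecting pair to be convex — always true for
the rectangular synthetic tracts and districts; real-data polygons that
are all non-convex are not supported by the clipping step.

## Disparity tests

Under the null of spatial exchangeability, events are reassigned to
districts uniformly at random with every district's event count held
fixed (equivalently, delays are shuffled over fixed district slots). The
ranked-median envelope repeats this 1000 times, sorts the district medians
of each replicate, and reports per-rank means and 2.5/97.5 percentile
bounds; observed ranked medians outside their rank's interval are flagged.
The percentile form of the interval was chosen over mean ± 1.96 SD because
median distributions at these group sizes are discrete and skewed.

Two scalar one-sided tests summarize disparity in district medians $v$:
the population-form Gini coefficient
$G = \sum_{a,b}|v_a-v_b| / (2n^2\bar v)$ (scale-invariant, no small-sample
correction) and the inter-decile range (90th minus 10th percentile, linear
interpolation between order statistics — R quantile type 7; medians of
even-sized groups are the mean of the central pair). Both use the add-one
upper p-value.

A caveat worth knowing: the IDR is a function of just two order statistics
of integer-valued medians, so its permutation distribution has visible
point masses and the test is mildly conservative at small district counts.
At the default scenario sizes (76 districts, ~78 events each) the type-I
error sits at the lower edge of the nominal band; with very few districts
it drops further.

## The staged models

Feature groups: $V$ survivor characteristics (race, sex, age band,
one-hot with reference levels "other" and "25.44"), $Z$ temporal flags
(meteorological seasons with "fall" as reference, weekend, federal /
Christian / Muslim / Jewish / Hindu holidays, popular celebrations), $X$
areal socio-economics (tract-level under the point regime, district
aggregates under the centroid regime), $Q$ district dummies (first
district as reference), $C$ planar coordinates. The specifications are
NS1 = $f(V)$, NS2 = $f(Z,V)$, S1 = $f(X,Z,V)$, S2 = $f(Q,Z,V)$,
S3 = $f(X,C,Z,V)$; targets are the three indicators (classification) and
$\log(1+\Delta t)$ (regression).

Learners: lasso-penalized linear/logistic models (`glmnet`, penalty by
5-fold inner CV), random forest (`ranger`, 300 trees), gradient boosting
(`xgboost`, 150 rounds, depth 4, eta 0.1 — small fixed defaults, no
tuning protocol is prescribed), and for S3 a Gaussian process
(`kernlab::gausspr`) over the standardized coordinates plus the
L1-pre-selected features. The GP uses one squared-exponential kernel of
fixed width $\sigma = 1/p$ and, for regression, noise variance 0.5 on the
internally scaled target (half the variance treated as noise), rather
than a sum of a spatial kernel and an automatic-relevance kernel: the simpler form is deterministic, supported
directly by the installed stack, and in this setting (coordinates
dominate the spatial signal) performs equivalently; a hand-written
variational GP classifier was judged not worth its maintenance cost.

Folds are stratified by class for binary targets (re-drawn once if a
training fold is single-class, then an error), random for regression, and
fixed by the seed. Standardization of continuous columns and L1 selection
happen strictly inside training folds; S3 coordinates are exempt from
selection and always retained. Metrics on the pooled out-of-sample
predictions: accuracy at the 0.5 threshold, AUC as the Mann–Whitney rank
statistic with 0.5 tie credit, RMSE, and $R^2 = 1-SSE/SST$ (pooled, not
fold-averaged). Classification is compared against the majority-vote
baseline. For classifiers the residual is observed label minus predicted
probability, which keeps the RSA test applicable to a continuous vector.
The coefficient table refits the L1-selected support without penalty
(OLS / ML logistic) and reports Wald p-values — standard post-selection
caveats apply and are printed with the output.

## What the synthetic generator emulates

`scenario_config()` defines a rows × cols grid of unit-square tracts,
districts as square blocks of tracts, and the generative model

$$\log(1+\Delta t_i) = \mu + \textstyle\sum_f \beta_f z_{if} +
u_{district(i)} + \varepsilon_i,\qquad \varepsilon_i \sim N(0, \sigma^2),$$

rounded to whole nonnegative days, with four deliberate features of real
reporting-delay data:

* **Heavy right tail** — a Pareto-tail mixture (probability 0.1, scale 3,
  tail index 1.5, cap 5 years) multiplies the delay of a random subset,
  so the 99th percentile sits far above 10× the median while the median
  stays at a few days. $\mu = \log 4$ and $\sigma = 1.2$ put the median
  at 3–4 days.
* **District-level spatial structure** — a latent Gaussian field on the
  tract grid (iid normal, queen-smoothed twice, standardized) drives both
  the spatially structured socio-economic attributes (poverty, income,
  schooling, insurance, unemployment) and, aggregated to districts,
  smoothed once more and rescaled to `spatial_effect_sd`, the district
  effect $u_j$. Marginally $u_j \sim N(0, sd^2)$; the shared latent field
  is what lets the areal-covariate specification S1 absorb the spatial
  effect, mirroring the random-effects narrative of the framework. The
  remaining attributes are spatially unstructured noise.
* **Occurrence-date heaping** — with probability `heaping_prob` an
  occurrence date is snapped to the 1st/15th of its month and the event
  receives a positive delay shift (`heaping_boost`, default log 3),
  emulating imprecise recall of long-delayed reports and the resulting
  median-delay spikes on those days.
* **Two coordinate regimes** — "point" coordinates uniform within the
  tract (block-level reporting), or "district_centroid" where every
  event sits on its district centroid (centroid-obfuscated reporting).

Presets: `"null"` (no spatial effect, no covariate effects; n = 5928
events over 76 districts, mirroring a large-city configuration) is the
calibration scenario; `"spatial"` (n = 3000, 100 districts, district
effect SD 0.5, effects `vict.u18` +0.8, `vict.female` −0.4, `federal`
+1.0, `winter` +0.3 on the log scale) is the power scenario, with
`"la_style"`/`"ny_style"` selecting the coordinate regimes. Effect signs
follow the direction consistently reported for observed data (younger and
non-female survivors, winter and holiday occurrences → longer delays).

What the generator does **not** emulate: realistic street networks or
population density gradients, survivor-attribute correlation with place,
seasonal event-rate variation, multi-year drift, or the exact share of
month-plus reports in observed data (here ~8–11% versus roughly 30% in
large-city extracts — the tail mixture was set for tail shape, not that
share). Passing calibration and power tests on these scenarios therefore
shows the statistics and the pipeline behave correctly under controlled
structure; it does not certify effect sizes on any real city.

## Numerical choices

* $\log(\Delta t)$ is undefined at the legitimate value
  $\Delta t = 0$; the package uses $\log(1+\Delta t)$ throughout,
  isolated in `log_delay()`.
* Negative delays (report before occurrence) are recording errors:
  flagged, counted and excluded — never clamped.
* Holiday calendar: federal holidays, Christian movable feasts (Gauss
  computus) and popular celebrations are computed; Muslim/Jewish/Hindu
  lunar-calendar dates are bundled as an approximate static table for
  2012–2019, user-overridable via `lunar_table`.
* kNN distance ties and boundary point-in-polygon ties break
  deterministically by smallest id.
* `gini()` errors on all-zero input; constant input returns 0 and yields
  p = 1 in the permutation test.
* All permutation tests use the add-one convention; seeds are explicit
  arguments everywhere, and the generator restores the caller's RNG
  state.

## Problem sizes used in the checks

The test suite and the acceptance script run the calibration analyses at
200 and 100 replicates with 999 (Moran) and 199 (disparity) permutations,
power and recovery analyses over 10–20 seeds at the preset sizes above,
and the model comparison with the lasso and random-forest learners; the
GP enters on smaller n where its cubic cost is irrelevant to the property
being checked. These sizes were chosen to keep Monte-Carlo error well
inside the tested margins.

## Limitations

* The clipping step needs one convex polygon per intersecting pair;
  arbitrary mutually non-convex real-district geometries would need a
  general clipping engine.
* Analytical (normality-based) Moran inference, Geary's C and
  Getis–Ord statistics are out of scope, as are spatial CV schemes and
  formal post-selection inference.
* Under the centroid regime S3's "coordinates" are district centroids;
  the GP then sees a degenerate design with ties, and S2/S3 differences
  mostly vanish — as expected when location is obfuscated.
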