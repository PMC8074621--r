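# reportlag

Spatial analysis and prediction of crime reporting delays.

Reporting delay — the number of whole days between a crime's occurrence
and its report — is both a proxy for under-reporting and a quantity with
direct forensic meaning: one day, one week and one month mark the windows
for clinical care, DNA evidence and toxicological evidence. `reportlag`
provides an end-to-end framework for event-level delay data over police
districts, for analysts working with open crime-report extracts:

* delay indicators `d_day`/`d_week`/`d_month` (delay ≤ 1/7/30 days),
  `log(1+Δt)`, and district proportions
  `p_j = (1/n_j) Σ_{i∈j} d_i` and median delays;
* population-weighted areal aggregation of census-tract covariates onto
  districts: `P^A_{j|k} = A(b_k ∩ a_j)/A(b_k)`, `x_{k∩j} = P^A_{j|k} x_k`,
  `P^x_{k|j} = x_{k∩j}/x_j`, intensive attributes weighted by `P^x`,
  extensive ones area-apportioned;
* global and local Moran's I with permutation pseudo p-values under
  queen / kNN / same-district binary weights,

  `I = (m/Σw) · Σ_{j,l} w_{j,l}(p_j−p̄)(p_l−p̄) / Σ_j (p_j−p̄)²`;
* spatial-disparity permutation tests on district median delays:
  a ranked-median 95% envelope, and one-sided Gini and inter-decile-range
  tests under count-preserving random reassignment;
* a staged predictive comparison — NS1 (survivor), NS2 (+temporal),
  S1 (+areal socio-economics), S2 (+district dummies), S3 (areal +
  coordinates) — with lasso, random forest, gradient boosting and a
  Gaussian process, under seeded 10-fold CV with training-fold-only
  standardization and L1 selection;
* residual-spatial-autocorrelation diagnostics, unpenalized coefficient
  refits on the L1-selected support, and permutation feature importance.

A synthetic-data generator (heavy-tailed delays, latent spatial field
driving both district effects and socio-economic attributes, occurrence-
date heaping, point vs centroid coordinate regimes) makes the whole
pipeline testable without external downloads. See the methods vignette
(`vignettes/spatial-reporting-delays.Rmd`) for the model and every
numerical choice.

## Worked example

```r
library(reportlag)

ds <- generate_events(scenario_preset("spatial", seed = 3))
ev <- ds$events

# district summaries and spatial autocorrelation of median delays
s  <- area_summaries(ev, ds$districts)
qw <- queen_weights(ds$districts$geometry, ids = ds$districts$id)
global_moran(s$median_delay[s$defined], qw, n_perm = 199, seed = 1)
#> Global Moran's I = 0.352635 (E[I] = -0.010101), pseudo p = 0.005 (199 permutations, greater)

# one-sided disparity tests on district median delays
disparity_test(ev, "gini", n_perm = 999, seed = 1)$p_value
#> [1] 0.001

# staged models: does spatial information help predict one-month reporting?
da <- aggregate_attributes(ds$tracts, intersection_weights(ds$tracts, ds$districts))
for (nm in c("NS1", "S3")) {
  sp <- model_spec(nm, "d_month", "lasso_lm", seed = 101)
  ft <- assemble_features(ev, sp, tracts = ds$tracts, district_attrs = da,
                          regime = "point")
  print(fit_predict_cv(ft, sp))
}
#> cv_result: NS1 / d_month / lasso_lm, 10 folds
#>   accuracy = 0.8903
#>   auc = 0.6216
#>   majority baseline = 0.8903
#> cv_result: S3 / d_month / lasso_lm, 10 folds
#>   accuracy = 0.8920
#>   auc = 0.6932
#>   majority baseline = 0.8903
```

The Moran statistic (I = 0.35 against a null expectation of −0.01,
p = 0.005) says district median delays cluster in space; the disparity
test says the spread of district medians far exceeds random assignment;
and the AUC gain from 0.622 (survivor characteristics only) to 0.693
(adding areal covariates and coordinates) is the predictive value of
spatial context — the accuracy column stays at the majority baseline
because the month indicator is imbalanced, which is why AUC is reported
alongside it.

The numbered scripts under `analysis/` run the full narrative (simulate →
delay processing → autocorrelation → disparity → model grid →
diagnostics), writing tables under `results/`.

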