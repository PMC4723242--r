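# facint

Latent-variable indexes of HIV and reproductive-health (RH) service
integration at the health-facility level.

## The problem

Evaluations of integrated HIV–RH care need a quantitative answer to "how
integrated is this clinic?" — both the *potential* for integration
(services co-located in the MCH/FP unit, multi-service rooms, multi-tasking
providers) and its *realisation* (clients actually receiving an RH and an
HIV-related service in one consultation or one visit). `facint` computes
eight facility-level integration attributes from raw client-flow and
facility activity records, codes them ordinally, and combines them with a
Bayesian confirmatory factor model, yielding a **structural** and a
**functional** integration index per facility, with uncertainty, ranks,
fit and convergence diagnostics, and baseline-vs-endline change metrics.

## The model

For facility *i* and ordinal indicator *j* (category *y<sub>ij</sub>* of
*K<sub>j</sub>*), a 2-parameter probit measurement model links the data to
latent integration factors *η<sub>i</sub>*:

y\*<sub>ij</sub> = λ<sub>j</sub>ᵀ η<sub>i</sub> + ε<sub>ij</sub>,  ε<sub>ij</sub> ~ N(0,1),  η<sub>i</sub> ~ N(0, I),

with *y<sub>ij</sub> = c* iff τ<sub>j,c−1</sub> < y\*<sub>ij</sub> ≤ τ<sub>j,c</sub>
for strictly increasing thresholds. Factor and residual variances are fixed
at 1; the standardized loading is λ/√(λ²+1). The two-factor specification
loads the four functional indicators on one factor and the four structural
indicators on the other, orthogonally; a one-factor alternative is
available for comparison. Estimation is a data-augmentation Gibbs sampler
(4 chains × 50,000 iterations by default, compiled core), with
potential-scale-reduction convergence diagnostics and
posterior-predictive chi-square fit checks (zero in the 95%
observed-minus-replicated interval and a non-significant p indicate good
fit). Facility scores are Bayesian plausible values, ranked (1 = most
integrated) and rescaled by +4 so the practical −3..3 range plots on 1..7;
endline waves are scored with baseline measurement parameters so change
reflects latent change, not model drift.

## Worked example

```r
library(facint)

# a synthetic two-wave study with known truth: 40 facilities, two
# orthogonal factors, eight ordinal indicators
sim <- simulate_study(n_facilities = 40, waves = 2, seed = 1)

fit <- integration_cfa(sim$indicators$baseline, n_factors = 2,
                       chains = 4, iter = 12000, seed = 1)
print(fit)
#> Bayesian ordinal-probit factor model (2-factor, orthogonal)
#> 40 facilities, 8 indicators; 4 chains x 12000 iterations (burn-in 50%, thin 1)
#>
#> Standardized loadings (posterior means):
#>   functional:
#>     art_location_score      0.494
#>     temporal_range          0.857
#>     consult_integration     0.984
#>     visit_integration       0.984
#>   structural:
#>     unit_availability       0.981
#>     facility_availability   0.643
#>     room_range              0.747
#>     provider_range          0.888
```

The posterior-mean standardized loadings recover the generating values
(0.489/0.774/0.979/0.984 functional; 0.952/0.617/0.836/0.795 structural)
within their credible intervals. Fit and convergence:

```r
fit_report(fit, n_reps = 1000, seed = 1)
#> Posterior-predictive fit check (augmented-data covariance LR chi2)
#>   2-factor model, 40 facilities, 1000 posterior draws
#>   chi2 difference 95% interval: [-24.414, 27.802]
#>   posterior-predictive p: 0.455
#>   verdict: good fit (interval covers zero, p non-significant)
#>   max PSR: 1.038 (values close to 1 indicate convergence)
```

The interval covers zero and p is non-significant: the two-factor model
fits. The same check on a one-factor fit of the same data rejects it
(interval [11.8, 75.4], p = 0.007) — structural capacity and functional
delivery are distinct dimensions. Scoring and change:

```r
scores_b <- plausible_values(fit)                       # baseline scores
scores_e <- score_fixed(fit, sim$indicators$endline,    # endline, baseline
                        seed = 1)                       # parameters fixed
change_metrics(scores_b, scores_e)
#> Baseline-vs-endline change metrics (40 facilities)
#>   functional   sum |diff| =  30.33   cross-wave r = 0.288
#>   structural   sum |diff| =  19.13   cross-wave r = 0.729
#>   cross-factor r: baseline -0.152, endline -0.247
```

Functional integration changes more between waves (larger sum of absolute
differences, lower cross-wave correlation) than structural integration —
the generator's mean-reversion defaults encode exactly this pattern — and
the cross-factor correlations are small, as expected for orthogonal
dimensions.

Raw records work the same way: `read_client_flow()` +
`read_facility_inventory()` → `build_attribute_table()` → `ordinalize()` →
`integration_cfa()`, or in one step via `run_pipeline()` /
`exec/facint run --config cfg.json`.

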