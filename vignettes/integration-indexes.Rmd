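---
title: "Measuring HIV–RH service integration with latent-variable indexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring HIV–RH service integration with latent-variable indexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

"Integration" of HIV and reproductive-health (RH) services is a latent,
multi-dimensional property of a health facility: it cannot be observed
directly, only through manifestations such as which services a clinic's
MCH/FP unit offers, whether one provider delivers several services, and
whether clients actually receive an RH and an HIV-related service in the
same consultation or visit. `facint` implements a complete pipeline from
raw facility records to latent integration indexes:

1. **Attributes.** Eight facility-level attributes are computed from two
   kinds of raw data. From activity/register data (structural side):
   the share of the five HIV-related services available in the MCH/FP unit;
   the share of all eight RH+HIV services available anywhere in the
   facility; the mean share of HIV-related services provided per MCH/FP
   consultation room; and per clinical staff member per day. From
   client-flow records (functional side): a 0–3 HIV-treatment-location
   score; the share of days on which both an RH and an HIV-related service
   were received by any client; and the shares of clients co-receiving both
   classes within one provider contact and within one one-day visit.
2. **Ordinal coding.** Attributes are coded into ordinal categories with
   pooled-wave cutpoints.
3. **Measurement model.** A Bayesian confirmatory factor model with probit
   links for ordinal indicators, estimated by a data-augmentation Gibbs
   sampler.
4. **Diagnostics, scores, change.** Convergence (PSR) and
   posterior-predictive fit checks; plausible-value facility scores, ranks
   and a 1–7 graphing rescale; fixed-parameter cross-wave scoring and
   baseline-vs-endline change metrics.

## The model

For facility $i$ and indicator $j$ with observed ordinal category
$y_{ij} \in \{0, \dots, K_j-1\}$, the 2-parameter probit measurement model
posits a continuous latent response

$$y^*_{ij} = \lambda_j^\top \eta_i + \varepsilon_{ij}, \qquad
  \varepsilon_{ij} \sim N(0, 1), \qquad \eta_i \sim N(0, I),$$

with $y_{ij} = c$ iff $\tau_{j,c-1} < y^*_{ij} \le \tau_{j,c}$ for strictly
increasing thresholds $\tau_j$ ($\tau_{j,-1} = -\infty$,
$\tau_{j,K_j-1} = \infty$). Loadings are discrimination parameters;
thresholds are the levels of latent integration that must be reached for
each category.

Identification fixes both the factor variances and the residual variances
at 1 (theta parameterization); all loadings and thresholds are free. The
standardized loading of an indicator is
$\lambda_j / \sqrt{\lambda_j^2 + 1} \in (-1, 1)$.

Two confirmatory structures are supported. The one-factor model loads all
eight indicators on a single integration factor. The two-factor model loads
the four functional indicators (treatment-location score, day-level
co-delivery, consultation- and visit-level co-receipt) on a *functional*
factor and the four structural indicators (unit and facility availability,
provider and room range) on a *structural* factor, with the two factors
orthogonal by construction. Reflection invariance (a factor's loadings and
scores can jointly flip sign without changing the likelihood) is resolved
after sampling by orienting every retained draw so that each factor's
loading sum is positive.

```{r}
library(facint)
sim <- simulate_study(n_facilities = 40, waves = 2, seed = 1)
fit <- integration_cfa(sim$indicators$baseline, n_factors = 2,
                       chains = 4, iter = 50000, seed = 1)
summary(fit)
fit_report(fit, n_reps = 1000, seed = 1)
```

## Estimation

The sampler is a data-augmentation Gibbs scheme: truncated-normal draws of
$y^*$ given the data and current parameters (missing cells drawn from the
unconstrained normal, i.e. integrated out under ignorable missingness),
conjugate normal updates for factor scores and loadings, and
truncated-normal conditional draws for each threshold on its data-allowed
interval. Four chains of 50,000 iterations with the first half discarded
as burn-in are the defaults; chains start from dispersed random loadings
and frequency-based thresholds, with per-chain seeds derived
deterministically from one master seed.

**Priors.** Loadings and thresholds have normal$(0, v)$ priors with
$v = 25$ by default. On the probit scale this is only weakly informative:
standardized loadings of $\pm 0.98$ correspond to raw loadings of about
$\pm 5$, i.e. one prior SD, so the prior is essentially flat across the
entire substantively possible range. A much flatter prior (say $v = 10^6$)
is available but not the default, deliberately: with 40 facilities and
indicators that measure their factor almost deterministically, the raw
loading likelihood develops a weakly identified scale ridge
(quasi-separation). Under a flat prior the chains wander far along that
ridge — raw-scale PSR grows without any defect in the identified
quantities, and interval calibration degrades. The $v = 25$ default
regularizes the ridge while leaving the identified quantities essentially
untouched.

**Convergence** is assessed with the proportional scale reduction factor
$\mathrm{PSR} = \sqrt{(W + B)/W}$, where $W$ is the mean within-chain
variance and $B$ the variance of chain means; identical chains give
exactly 1. By default PSR is monitored on the *identified* parameter
scale — standardized loadings, and thresholds divided by the
latent-response SD — because the raw parameters ride the scale ridge
described above; `psr(fit, scale = "raw")` monitors the raw draws.

**Model fit** uses posterior-predictive checking: for a thinned subset of
retained draws, a discrepancy is evaluated on the observed data and on a
replicate generated from the same draw, and the 95% interval of
(observed − replicated) together with $p = \Pr(f^{rep} \ge f^{obs})$ is
reported; zero inside the interval and a non-significant $p$ indicate good
fit. The default discrepancy is a covariance likelihood-ratio chi-square on
the augmented continuous responses, mirroring the observed-vs-replicated
chi-square logic of mainstream Bayesian SEM software. A purely
limited-information alternative (likelihood-ratio G² over all pairwise
two-way indicator tables, with cell probabilities from bivariate-normal
rectangles) is available via `ppc(fit, discrepancy = "pairwise_g2")`. The
pairwise statistic was this package's original default, but in repeated
synthetic experiments it lacked the power to flag a one-factor model fitted
to clearly two-dimensional 40-facility data — the replicate noise of 28
small contingency tables swamps the block-misfit signal — whereas the
covariance LR flags it reliably; hence the switch. Neither statistic is
identical to any commercial implementation.

## Scoring

Facility scores are Bayesian plausible values: by default the posterior
mean of $\eta_i$ with the posterior SD as standard error; a seeded single
posterior draw is available for classical plausible-value semantics.
Facilities are ranked per factor (1 = most integrated, ties averaged) and
scores are rescaled by $+4$ for graphing, mapping the practical $-3..3$
range onto $1..7$; out-of-range values pass through with a warning rather
than being clipped.

For multi-wave studies, endline data are scored with the baseline
measurement parameters fixed at their posterior means
(`score_fixed()` / `predict(fit, newdata)`), so that score changes reflect
latent change rather than drift in the measurement model; applying
fixed-parameter scoring to the baseline data itself reproduces the
plausible values up to the (small) effect of ignoring parameter
uncertainty. `change_metrics()` then reports per-factor sums of absolute
differences and cross-wave correlations, plus within-wave cross-factor
correlations.

## The synthetic-study generator

`simulate_study()` generates the study conditions every claim in the test
suite is evaluated under: 40 facilities, two orthogonal standard-normal
factors, eight ordinal indicators (three categories each; four for the
treatment-location score) with standardized loadings
(0.489, 0.774, 0.979, 0.984) on the functional factor and
(0.952, 0.617, 0.836, 0.795) on the structural factor — magnitudes typical
of strongly measured facility-integration indexes — and equal-probability
thresholds. For two-wave studies the latent change model is mean-reverting,
$\eta_2 = (1-\kappa)\eta_1 + \epsilon$ with variance-preserving noise, so
the cross-wave correlation is $1-\kappa$; defaults $\kappa = 0.5$
(functional) and $\kappa = 0.1$ (structural) encode the common pattern that
client-level delivery regresses to the mean faster than infrastructure.

A further layer (`generate_flow()`) produces client-flow records and
facility inventories whose *expected* computed attributes equal
latent-score-driven targets, so the attribute computation can be tested
end-to-end. It is a fixture with a conditional-independence service model,
not a behavioural simulation: real client flows have day-of-week structure,
provider heterogeneity, correlated service baskets and recording errors
that the generator deliberately omits. Passing tests therefore demonstrate
the correctness of the pipeline's arithmetic and the statistical behaviour
of the estimator under the stated conditions — not that real facility data
meet those conditions.

## Numerical choices and degenerate inputs

* Quantile ordinal coding sends boundary ties to the lower category
  (deterministic); duplicate quantiles are collapsed. An indicator that
  collapses to a single observed category is rejected by name.
* The treatment-location score keeps its native 0–3 scale when the
  facility values are integral; because the facility-level value is a
  client mean (continuous in general), the as-is rule falls back to
  quantile coding with four categories for non-integral input.
* Truncated-normal draws use inverse-CDF sampling where the interval has
  usable mass and tail-rejection samplers (exponential proposal one-sided,
  uniform proposal two-sided) deep in the tails.
* Bivariate-normal rectangle probabilities use the
  Drezner–Wesolowsky/Genz algorithm with adaptive Gauss–Legendre order,
  validated against an independent implementation at $10^{-10}$.
* Missing attribute values are explicit (`NA`), never zero-filled, and are
  integrated out by the augmentation step during fitting. A facility
  present in only one data source yields a row with missing fields and a
  warning.
* Empty client-flow datasets, windows inconsistent with the observed days,
  categories outside the baseline coding and unmatched facility sets all
  raise immediate, named errors.

## Problem sizes used in the test suite

The package defaults (4 × 50,000 iterations) are what an analysis run
should use. The automated tests exercise the same code at smaller,
deliberately chosen sizes: recovery and discrimination checks use 40
facilities with 4 chains × 6,000–12,000 iterations per fit across 20
replicate seeds, orthogonality checks 50 replicate seeds at 2 × 5,000, and
the sampler-vs-grid oracle a 12-facility, 2-indicator model at 4 × 100,000
against a four-dimensional grid posterior (step 0.2, quadrature step 0.1).
These sizes were picked so that Monte-Carlo error is small relative to each
check's tolerance.

## Known limitations

* The sampler's threshold updates move within gaps between adjacent latent
  responses; at sample sizes in the hundreds those gaps shrink and
  threshold mixing slows markedly. The package is designed for
  facility-level samples (tens of units); for much larger samples a
  blocked threshold sampler would be preferable.
* With disjoint indicator blocks and orthogonal factors, the sample
  correlation between the two factors' estimated scores has the usual
  null sampling spread ($\mathrm{SD} \approx 1/\sqrt{n-1}$, i.e. ≈ 0.16 at
  $n = 40$); observed cross-factor correlations of ±0.1–0.2 on one study
  are compatible with exactly orthogonal truth.
* Fixed-parameter scoring ignores baseline parameter uncertainty by
  design (measurement-equivalence scoring); its standard errors are
  conditional SEs.
* Expert-opinion attribute weighting and any causal analysis of score
  changes (e.g. regression-to-the-mean adjustment) are out of scope.
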