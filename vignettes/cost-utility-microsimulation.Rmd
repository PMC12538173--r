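---
title: "Methods: a continuous-time cost-utility microsimulation for relapsing-remitting psychosis care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a continuous-time cost-utility microsimulation for relapsing-remitting psychosis care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relapsim)
```

## The model

`relapsim` simulates individual patients with schizophrenia-spectrum
disorders (SSD) through a continuous-time state-transition model with four
healthcare-use states: stable **out-of-episode**, **in-episode with
outpatient care only**, **in-episode including inpatient care**, and
absorbing **death**. An episode is a period of increased specialised
mental-healthcare use; *relapse* is the transition into an episode,
*remission* the return to stability. Mortality is possible from every
alive state.

Every transition carries a parametric cause-specific hazard
(`transition_spec()`): exponential (constant rate), Weibull
(shape/scale, accelerated-failure covariates) or Gompertz
(exponentially trending rate, proportional-hazards covariates), in the
`flexsurv` parameterisations. Covariates (`age_decades`, `sex_male`,
diagnosis indicators) enter the linear predictor evaluated at sojourn
entry; age itself advances continuously with simulation time, so a relapse
at year 7 of a 40-year-old uses age 47.

The intervention — a one-time course of cognitive behavioural therapy for
psychosis (CBTp) delivered at baseline on top of treatment as usual (TAU)
— acts as a relative risk `rr` multiplying the targeted relapse hazard
during the effect window `[0, duration)`, anchored at treatment delivery.
Outside the window, and always in the TAU arm, the multiplier is 1.

### Event loop and sojourn sampling

From the current state the engine draws a candidate time for every
outgoing transition by inversion of the cumulative hazard: solve
`H(t) = -log(U)` where `H` accumulates the parametric hazard times the
piecewise-constant treatment multiplier. All three families have closed
forms per multiplier piece, so no root finding is involved. The earliest
candidate wins; simultaneous candidates (a measure-zero event kept
deterministic for floating-point robustness) are broken death > remission
> relapse. Hazard multiplication is implemented on the cumulative hazard
(`H -> rho * H` per piece), not via scale-parameter shortcuts, which is
exact for time-varying multipliers and any family.

A patient who has already spent `w` years in their baseline state enters
the first sojourn left-truncated: accumulation starts at state-time `w`.
The same convention is mirrored on the estimation side via
counting-process entry offsets.

### Episode types

The published state structure distinguishes the two episode types but not
the mechanism that assigns them. Two mechanisms are supported
(`relapse_mode`):

* `"episode_type_model"` (default): a single pooled relapse hazard; at
  relapse time a logistic sub-model gives Pr(inpatient episode |
  covariates). This keeps the treatment RR interpretable as acting on
  relapse overall.
* `"competing"`: two separate competing relapse hazards, one per episode
  type.

The treatment-effect `target` defaults to `all_relapse`. The alternative
`inpatient_relapse_only` reflects that the source meta-analyses measured
*rehospitalisation*: in competing mode it multiplies only the inpatient
relapse hazard; in episode-type-model mode the pooled relapse hazard is
scaled by `(1 - p) + rr * p` during the window and the conditional
inpatient probability is shifted to `rr * p / ((1 - p) + rr * p)`, which
is the exact consequence of thinning only the inpatient sub-hazard.

### Common random numbers

Each uniform deviate is addressed by the key `(master_seed, outer_index,
patient, purpose, block)`, with separate purposes for relapse sojourns,
remission sojourns, death candidates and episode-type decisions. The k-th
decision of a given kind therefore uses the same uniform in both arms even
after event *times* diverge, and results are invariant to patient
processing order. Consequences, verified pathwise in the test suite:

* with `rr = 1` the two arms are byte-identical, so the incremental cost
  is exactly the treatment cost and the QALY difference exactly zero, per
  patient;
* with `rr < 1` targeting all relapses, monotonicity of the inversion in
  the multiplier couples the arms so that no patient spends *more* time
  in-episode when treated;
* simulating a long horizon and truncating reproduces the short-horizon
  run exactly.

The shipped base-case transition specs carry **zero covariate
coefficients**. This is deliberate: with covariate-free transition hazards
the pathwise coupling above is exact. Age-dependent relapse or remission
hazards (fully supported) can in principle produce individual patients for
whom a delayed relapse leads, via a different age at entry, to a longer
episode; coupling then holds in expectation rather than pathwise.

## Economic valuation

Each sojourn in state `s` accrues utility `u_s` and an annualised cost
rate `exp(intercept_s + X beta)` (EUR/year, price year 2019); the
log-linear form keeps predicted costs positive. Death accrues nothing.
Discounting is continuous with instantaneous rate `rho = log(1 + r)`, so a
flow over a whole year discounts exactly as annual compounding at rate
`r`; the closed form for an arbitrary interval `[t0, t1]` is
`level * (exp(-rho t0) - exp(-rho t1)) / rho`, validated against numerical
quadrature at 1e-8 relative tolerance. The one-time CBTp cost
`n_sessions * unit_cost / group_size` is incurred at t = 0 (discount
factor 1) in the intervention arm only. Adverse-event and travel/training
costs are zero by assumption; the `direct_utility_bonus` slot (an additive
utility during the effect window, default 0) exists only for one-way
sensitivity analysis of direct quality-of-life effects.

The ICER is reported as `dC/dE` only in the trade-off quadrants; cost
saving with health gain is labelled *dominant*, the reverse *dominated*.
"Cost-effective" means NMB ≥ 0, i.e. the threshold comparison is
boundary-inclusive.

## Parameters: defaults, units, provenance

| Quantity | Default | Unit | Provenance |
|---|---|---|---|
| treatment effect `rr` | 0.79 (CI 0.60–1.04) | – | published meta-analysis (base case) |
| alternative `rr` (scenario) | 0.70 (CI 0.54–0.91) | – | published meta-analysis |
| effect `duration` | 2 (scenarios 1–10) | years | trial follow-up limit |
| sessions × unit cost | 16 × 108.22 | EUR | published costing (= 1731.52) |
| discounting costs/effects | 3.5%/3.5% (scenario 4%/1.5%) | /year | UK / Dutch guidelines |
| horizon | 10 | years | study design |
| WTP threshold | 50,000 | EUR/QALY | study design |
| PSA loops | 750 × 250 (desk runs scaled down) | – | study design |
| utilities | 0.92 / 0.76 / 0.60 (SE 0.03/0.05/0.05) | – | placeholder |
| transition rates | relapse 0.40; remission 2.0 / 1.5; death 0.01 / 0.02 | /year | placeholder |
| cost intercepts | log(3000 / 15000 / 60000) | log EUR/year | placeholder |
| episode-type intercept | logit(0.35) | log-odds | placeholder |

Values marked *placeholder* stand in for registry estimates that are not
public. They were chosen once for clinical plausibility — mean stable
period 2.5 years, mean episodes of 6/8 months, modest excess mortality
in-episode, an order-of-magnitude cost gradient from stable care to
episodes with admissions — and are not tuned to reproduce any published
result. The in-episode-with-outpatient-care utility is constructed by the
midpoint rule (`midpoint_utility()`): the average of the best and worst
state values with the larger of the two standard errors. A second
placeholder set tagged `lay_TTO` supports the lay-valuation scenario.

### Uncertainty distributions

The supplementary table describing the original PSA distributions is not
available, so the families are this package's choice, recorded in the
parameter file so they can be overridden by overriding the values:

* `rr`: lognormal with `meanlog = log(rr)` and
  `sdlog = (log(ci_high) - log(ci_low)) / (2 z)`, `z` the exact 97.5%
  normal quantile (1.959964…), not 1.96, so the implied interval
  round-trips to machine precision;
* utilities: beta, moment-matched to (mean, SE), redrawn until the
  ordering stable ≥ episode-outpatient ≥ episode-inpatient holds; if the
  SE is infeasibly large for a beta (`se^2 >= m(1-m)`) a [0,1]-truncated
  normal is used with a warning;
* transition parameters and cost/episode-type coefficients: normal on the
  log scale for positive parameters, on the coefficient scale otherwise,
  independent by default (a diagonal multivariate normal; off-diagonal
  structure would require the unavailable fitted covariances).

Structural quantities — session count, discount rates, horizon, effect
duration — are never drawn.

## The synthetic cohort generator

`generate_cohort()` emulates a specialised mental-healthcare registry
cohort: 60% male, age truncated-normal(40, 12) on [18, 80], a
four-category diagnosis mix (schizophrenia 0.55, schizoaffective 0.15,
other psychotic 0.25, substance-related 0.05), a prior-CBTp flag with
prevalence 2679/12835 (so the expected excluded count in a cohort of
12,835 is 2,679), and 25% of patients starting in-episode, their episode
type drawn from the episode-type sub-model. All marginals are
configuration, not assertions about the registry's joint distribution —
the generator exists so that the estimation stage can be validated by
parameter recovery, not to reproduce demographic tables.

Time already spent in the baseline state is drawn from the stationary
forward-recurrence distribution of the state's sojourn time where that has
a closed form — for a state whose exits are all exponential the residual
(and by memorylessness the elapsed) time is exponential with the total
exit rate — and is 0 otherwise. This avoids artificially synchronising
the whole cohort's episode clocks at t = 0. How the original study
assigned baseline status at its data split is not stated; this is the
package's choice and it is configurable via the cohort table.

What the generator does *not* emulate: covariate-dependent baseline
states, secular trends, measurement error in episode boundaries,
loss to follow-up before the horizon, and any dependence between
covariates. Passing recovery tests therefore show the estimators are
consistent under the model's own assumptions, not that the model fits any
particular real population.

## Estimation

`extract_spells()` turns trajectories into one row per sojourn with entry
offsets; person-time is conserved by construction and verified in tests.
`fit_sojourn()` fits each transition cause-specifically (competing exits
are right-censoring) by maximum likelihood via `flexsurv::flexsurvreg()`;
Weibull covariates are reported on both the accelerated-failure scale they
are fitted on and as proportional-hazards equivalents (`-shape * b`), so
the scale a coefficient lives on is never ambiguous. Non-convergence is
reported in the `fit_report`, not thrown. `fit_episode_type()` is a
logistic GLM with quasi-separation detection; `fit_cost_equation()` is a
log-scale linear model per state (its intercepts estimate log *median*
cost rates under multiplicative lognormal noise, which is the generating
model of `generate_cost_records()`). `fit_model()` chains everything and
returns a parameter set that plugs straight back into the engine; the
headline pipeline property — generate with known truth at n = 5,000,
refit, recover every component within 3 SE — runs in the acceptance suite.

## Numerical and design choices

* **Tie-breaks**: death > remission > relapse, documented above.
* **Effect window**: `[0, duration)`, half-open; at `t = duration` the
  multiplier is already 1. Patients in-episode at baseline carry the
  window from t = 0 (not from first remission): treatment is delivered at
  baseline regardless of current state.
* **Gompertz with negative shape** has bounded total hazard; inversion
  correctly returns an infinite candidate when the target exceeds the
  remaining mass.
* **Inner loops** sample `n_inner` patients *with replacement* from the
  post-exclusion cohort (resampled slots get fresh stream keys, so a
  twice-sampled patient contributes two independent trajectories);
  `n_inner = "all"` simulates the full cohort. The original design's
  250 inner loops are taken as given configuration.
* **Scenario runs** rerun the full PSA under identical seeds, so scenario
  contrasts are free of between-run Monte-Carlo noise; the scenario table's
  expected ICER is by construction the ratio of pooled outer means.
* **Tornado rows** are deterministic point-parameter paired runs, sorted
  by ICER spread (NMB spread where a dominance label makes the ICER
  undefined), ties by name.
* **Test problem sizes** were fixed once at the scale the checks need:
  5,000 patients for occupancy-vs-matrix-exponential and parameter
  recovery, 2,000 for the pathwise-coupling and CRN-null checks, 200
  outer × 150 inner for the acceptance script's PSA (scaled down from
  750 × 250). Long-run occupancy is compared against the exact
  finite-horizon time average `1/3 - (1 - e^{-3T})/(9T)` rather than the
  bare stationary value, which removes the transient bias from the check
  instead of hiding it in a wider tolerance.

## Limitations

The headline published figures of the motivating analysis (QALY gain
0.038, incremental cost EUR 492, ICER EUR 12,947, 61.2% probability of
cost-effectiveness) depend on registry-fitted transition, utility and cost
parameters that are not public; with placeholder parameters this package
reproduces the *arithmetic* and the *qualitative directions* (dominance
fractions, scenario orderings, discounting effects) but not those numbers,
and does not attempt to. No societal-perspective costs, medication
adherence, symptom dynamics, capacity constraints or treatment waiting
lists are modelled. Cox/semi-parametric fitting and multiple imputation of
covariates are out of scope; the eligible-population size behind any
national extrapolation is an input (`population_extrapolation()`), not an
estimate.
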