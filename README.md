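# relapsim

Patient-level cost-utility microsimulation of adding cognitive behavioural
therapy for psychosis (CBTp) to treatment as usual (TAU) for patients with
schizophrenia-spectrum disorders (SSD).

## The problem and the model

SSD patients cycle between periods of stable, low-intensity specialised
mental-healthcare use ("out-of-episode") and episodes of increased care,
which either involve only outpatient contacts or include inpatient
admissions. CBTp reduces the risk of relapse/rehospitalisation, but trials
are short; judging long-term cost-effectiveness requires simulation.

`relapsim` simulates each patient through a continuous-time state-transition
model with four states

```
out_of_episode  <-->  episode_outpatient / episode_inpatient  -->  dead
```

where *relapse* (out → in-episode) and *remission* (the reverse) are
parametric cause-specific hazards (exponential, Weibull or Gompertz, with
covariate effects), the episode type is resolved at relapse time by a
logistic sub-model, and death is absorbing. CBTp is a one-time treatment at
baseline modelled as a relative risk RR = 0.79 (95% CI 0.60–1.04) on the
relapse hazard for a limited window (2 years in the base case). Each sojourn
accrues utility u_s (QALYs) and an annualised cost rate exp(X beta_s)
(EUR/year, price year 2019), both discounted in continuous time at annual
rates of 3.5%/3.5% (costs/effects). Arms are compared per patient with
common random numbers (CRN), so the incremental statistics

* ΔC, ΔE — mean incremental costs (EUR) and QALYs per patient,
* ICER = ΔC/ΔE, NMB = λ·ΔE − ΔC at willingness-to-pay λ (EUR 50,000/QALY)

are estimated with strongly reduced Monte-Carlo variance. A probabilistic
sensitivity analysis draws parameters from their uncertainty distributions
(lognormal RR from the published CI, moment-matched beta utilities, normal
coefficients) in outer loops and simulates patient panels in inner loops,
yielding the cost-effectiveness plane, the acceptability curve (CEAC),
tornado tables and a scenario grid.

Because the registry that motivated this design cannot be shared, the
package ships a synthetic cohort generator with known ground truth, plus
maximum-likelihood re-estimation of every model component
(`fit_sojourn()`, `fit_episode_type()`, `fit_cost_equation()`), so the full
pipeline is testable by parameter recovery. Transition rates, utilities and
cost levels in `default_parameters()` are documented placeholders, not
registry estimates; the treatment parameters (RR, sessions, unit cost,
discounting, horizon, WTP) are the published ones.

## Worked example

```r
library(relapsim)

params <- load_parameters(system.file("extdata", "base_case.yaml",
                                      package = "relapsim"))
cohort <- generate_cohort(cohort_config(n_patients = 2000, seed = 42), params)
cohort <- apply_exclusions(cohort)
#> exclusions: 443 of 2000 patients flagged with prior CBTp; 1557 retained

tau  <- simulate_arm(cohort, params, "tau",      master_seed = 42)
cbtp <- simulate_arm(cohort, params, "tau_cbtp", master_seed = 42)
tau
#> Trajectory set: 1557 patients, 9930 transitions, horizon 10 y (arm tau)
#>   deaths: 164, censored at horizon: 1393

incremental(arm_outcomes(tau, cohort, params, "tau"),
            arm_outcomes(cbtp, cohort, params, "tau_cbtp"))
#> Incremental result over 1557 paired patients:
#>   delta costs:  EUR -60.72 per patient
#>   delta QALYs:  0.0161 per patient
#>   ICER:         dominant
#>   NMB @ EUR 50000: EUR 866.79 per patient
```

Patients who already received CBTp are excluded (they cannot benefit from
the hypothetical roll-out). Under this deterministic point-parameter run the
intervention gains 0.0161 QALYs per patient and *saves* EUR 60.72 — the
EUR 1,731.52 treatment cost is more than offset by avoided episode care —
so it is labelled *dominant* and no ratio is reported. The positive NMB says
the same thing at the EUR 50,000 threshold. Parameter uncertainty around
such a point estimate is what `run_psa()` quantifies:

```r
psa <- run_psa(params, cohort, psa_config(n_outer = 200, n_inner = 150,
                                          master_seed = 42))
ceac(psa)             # probability cost-effective vs willingness-to-pay
ce_plane_export(psa)  # per-draw (dE, dC) points and quadrant summary
```

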