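{
  "schema_version": "integer; format version, currently 1",
  "currency": "unit and price year of all monetary amounts (EUR, 2019)",
  "horizon": "simulation horizon in years (> 0, default 10)",
  "wtp": "willingness-to-pay threshold, EUR/QALY (default 50000)",
  "relapse_mode": "'episode_type_model' (single relapse hazard split by the logistic sub-model) or 'competing' (separate hazards per episode type)",
  "effect": {
    "rr": "relative risk on the targeted relapse hazard (> 0)",
    "ci_low": "lower 95% bound (0 < ci_low <= rr)",
    "ci_high": "upper 95% bound (>= rr)",
    "duration": "effect duration in years after one-time treatment at t = 0",
    "target": "'all_relapse' or 'inpatient_relapse_only'",
    "direct_utility_bonus": "additive utility during the effect window"
  },
  "utilities": {
    "values": "named utility weight in [-1, 1] per alive state",
    "ses": "named standard error (>= 0) per alive state",
    "provenance": "'patient_TTO' or 'lay_TTO'"
  },
  "costs": {
    "intercepts": "named log annual-cost-rate intercept per alive state (EUR/year)",
    "coefs": "named covariate coefficients on the log cost rate (age_decades, sex_male, diagnosis_<level>, sojourn_years)",
    "se": "named PSA standard errors"
  },
  "intervention": {
    "n_sessions": "number of therapy sessions (>= 0)",
    "unit_cost": "EUR per session",
    "group_size": "patients sharing a session (>= 1)"
  },
  "episode_type": {
    "intercept": "log-odds of an inpatient episode at relapse",
    "coefs": "named covariate coefficients",
    "se": "named PSA standard errors ('intercept' + coefficient names)"
  },
  "discount": {
    "rate_costs": "annual discount rate for costs (>= 0)",
    "rate_effects": "annual discount rate for QALYs (>= 0)"
  },
  "transitions": {
    "from": "origin state (never 'dead')",
    "to": "destination state, or 'in_episode' for a sub-model-resolved relapse",
    "family": "'exponential', 'weibull' or 'gompertz'",
    "rate": "exponential/gompertz rate (1/years)",
    "shape": "weibull or gompertz shape",
    "scale": "weibull scale (years)",
    "coefs": "named covariate coefficients (log-hazard scale; weibull: log-scale/AFT)",
    "se": "named PSA standard errors (log_rate, log_scale, log_shape, coefficient names)"
  }
}
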