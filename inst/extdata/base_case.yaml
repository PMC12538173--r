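schema_version: 1
currency:
  unit: EUR
  price_year: 2019
horizon: 10.0
wtp: 50000.0
relapse_mode: episode_type_model
effect:
  rr: 0.79
  ci_low: 0.6
  ci_high: 1.04
  duration: 2.0
  target: all_relapse
  direct_utility_bonus: 0.0
utilities:
  values:
    out_of_episode: 0.92
    episode_outpatient: 0.76
    episode_inpatient: 0.6
  ses:
    out_of_episode: 0.03
    episode_outpatient: 0.05
    episode_inpatient: 0.05
  provenance: patient_TTO
costs:
  intercepts:
    out_of_episode: 8.0063676
    episode_outpatient: 9.6158055
    episode_inpatient: 11.0020998
  coefs: []
  se:
    out_of_episode: 0.05
    episode_outpatient: 0.05
    episode_inpatient: 0.05
intervention:
  n_sessions: 16.0
  unit_cost: 108.22
  group_size: 1.0
episode_type:
  intercept: -0.6190392
  coefs: []
  se:
    intercept: 0.1
discount:
  rate_costs: 0.035
  rate_effects: 0.035
transitions:
  relapse:
    from: out_of_episode
    to: in_episode
    family: exponential
    rate: 0.4
    coefs: []
    se:
      log_rate: 0.05
  remission_outpatient:
    from: episode_outpatient
    to: out_of_episode
    family: exponential
    rate: 2.0
    coefs: []
    se:
      log_rate: 0.05
  remission_inpatient:
    from: episode_inpatient
    to: out_of_episode
    family: exponential
    rate: 1.5
    coefs: []
    se:
      log_rate: 0.05
  death_out:
    from: out_of_episode
    to: dead
    family: exponential
    rate: 0.01
    coefs: []
    se:
      log_rate: 0.1
  death_episode_outpatient:
    from: episode_outpatient
    to: dead
    family: exponential
    rate: 0.02
    coefs: []
    se:
      log_rate: 0.1
  death_episode_inpatient:
    from: episode_inpatient
    to: dead
    family: exponential
    rate: 0.02
    coefs: []
    se:
      log_rate: 0.1
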