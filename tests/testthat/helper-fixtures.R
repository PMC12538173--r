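# Fixtures are built in code: small parameter sets with known ground truth
# and homogeneous cohorts for closed-form checks.

# all-exponential parameter set; death transitions are omitted entirely
# when death_rate is NULL (no mortality)
test_params <- function(relapse = 0.5, remission_out = 2.0,
                        remission_in = remission_out,
                        death_rate = NULL, p_inpatient = 0.3,
                        rr = 0.79, ci_low = 0.60, ci_high = 1.04,
                        duration = 2, horizon = 10,
                        rate_costs = 0.035, rate_effects = 0.035,
                        ses = FALSE) {
  se1 <- if (ses) c(log_rate = 0.05) else numeric(0)
  trs <- list(
    relapse = transition_spec("out_of_episode", "in_episode", "exponential",
                              rate = relapse, se = se1),
    remission_outpatient = transition_spec("episode_outpatient",
                                           "out_of_episode", "exponential",
                                           rate = remission_out, se = se1),
    remission_inpatient = transition_spec("episode_inpatient",
                                          "out_of_episode", "exponential",
                                          rate = remission_in, se = se1))
  if (!is.null(death_rate)) {
    for (s in alive_states()) {
      trs[[paste0("death_", s)]] <-
        transition_spec(s, "dead", "exponential", rate = death_rate,
                        se = se1)
    }
  }
  parameter_set(
    transitions = trs,
    episode_type = episode_type_model(intercept = qlogis(p_inpatient)),
    utilities = default_utilities("patient_TTO"),
    costs = cost_equation(intercepts = c(out_of_episode = log(3000),
                                         episode_outpatient = log(15000),
                                         episode_inpatient = log(60000))),
    intervention = intervention_cost(16, 108.22, 1),
    effect = treatment_effect(rr, ci_low, ci_high, duration = duration),
    discount = discount_spec(rate_costs, rate_effects),
    horizon = horizon)
}

# homogeneous cohort: everyone starts stable out-of-episode at t = 0
flat_cohort <- function(n, age = 40, sex = "male",
                        diagnosis = "schizophrenia") {
  data.frame(patient_id = seq_len(n), age = age, sex = sex,
             diagnosis = diagnosis, prior_cbtp = FALSE,
             baseline_state = "out_of_episode",
             time_in_baseline_state = 0,
             stringsAsFactors = FALSE)
}

# per-patient total time in episode states
in_episode_time <- function(trajectories, cohort) {
  sp <- extract_spells(trajectories, cohort)
  ep <- sp$state %in% episode_states()
  out <- tapply((sp$t1 - sp$t0)[ep],
                factor(sp$patient_id[ep], levels = cohort$patient_id),
                sum, default = 0)
  as.numeric(out)
}

# state occupied by each patient at absolute time t
state_at <- function(trajectories, cohort, t) {
  sp <- extract_spells(trajectories, cohort)
  dead <- trajectories$patients$end_status == "dead" &
    trajectories$patients$end_time <= t
  hit <- sp[sp$t0 <= t & sp$t1 > t, ]
  m <- match(cohort$patient_id, hit$patient_id)
  out <- hit$state[m]
  out[dead[match(cohort$patient_id, trajectories$patients$patient_id)]] <- "dead"
  out
}
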