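#' Configuration of the synthetic registry-like cohort
#'
#' The generator emulates a specialised mental-healthcare registry
#' population of schizophrenia-spectrum patients. Default marginals are
#' documented placeholders (the source registry's joint distribution is
#' not public): 60\% male, age from a normal(40, 12) truncated to
#' \[18, 80\], a four-category diagnosis mix, a prior-CBTp flag prevalence
#' of 2679/12835 (so that the expected excluded count in a cohort of
#' 12,835 is 2,679), and 25\% of patients starting in-episode.
#'
#' @param n_patients cohort size (>= 0).
#' @param sex_proportion probability of male sex.
#' @param age_mean,age_sd,age_min,age_max truncated-normal age model
#'   (years).
#' @param diagnosis_mix named probability vector over diagnosis categories
#'   (must sum to 1 within 1e-9).
#' @param prior_cbtp_proportion probability of the prior-CBTp exclusion
#'   flag.
#' @param baseline_in_episode_proportion probability of starting t = 0
#'   in-episode (episode type then drawn from the episode-type sub-model).
#' @param seed integer seed; the same configuration and seed reproduce the
#'   cohort exactly.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          sex_proportion = 0.60,
                          age_mean = 40, age_sd = 12,
                          age_min = 18, age_max = 80,
                          diagnosis_mix = c(schizophrenia = 0.55,
                                            schizoaffective = 0.15,
                                            other_psychotic = 0.25,
                                            substance_related = 0.05),
                          prior_cbtp_proportion = 2679 / 12835,
                          baseline_in_episode_proportion = 0.25,
                          seed = 1) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 ||
      n_patients < 0 || n_patients != round(n_patients)) {
    stop("'n_patients' must be a single non-negative integer")
  }
  probs <- c(sex_proportion, prior_cbtp_proportion,
             baseline_in_episode_proportion)
  if (any(probs < 0 | probs > 1)) {
    stop("all proportions must lie in [0, 1]")
  }
  if (is.null(names(diagnosis_mix)) || any(diagnosis_mix < 0)) {
    stop("'diagnosis_mix' must be a named non-negative probability vector")
  }
  if (abs(sum(diagnosis_mix) - 1) > 1e-9) {
    stop("'diagnosis_mix' must sum to 1 (within 1e-9)")
  }
  if (age_min >= age_max || age_min < 0) stop("invalid age bounds")
  structure(list(n_patients = as.integer(n_patients),
                 sex_proportion = sex_proportion,
                 age_mean = age_mean, age_sd = age_sd,
                 age_min = age_min, age_max = age_max,
                 diagnosis_mix = diagnosis_mix,
                 prior_cbtp_proportion = prior_cbtp_proportion,
                 baseline_in_episode_proportion = baseline_in_episode_proportion,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# exact truncated-normal sampling by quantile inversion
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(p_lo + runif(n) * (p_hi - p_lo), mean, sd)
}

#' Generate a synthetic baseline cohort
#'
#' Draws `n_patients` patient profiles from the configured marginals.
#' Patients starting in-episode get their episode type from the
#' episode-type sub-model of `parameters`; time already spent in the
#' baseline state is drawn from the forward-recurrence (stationary
#' residual) distribution of the state's sojourn time where that is
#' available in closed form -- for exponential sojourns this is the
#' exponential itself -- and is 0 otherwise, avoiding artificial
#' synchronisation of the cohort at t = 0.
#'
#' @param config a [cohort_config()].
#' @param parameters a [parameter_set()] supplying the episode-type model
#'   and sojourn families for baseline-state assignment.
#' @return data frame with columns `patient_id, age, sex, diagnosis,
#'   prior_cbtp, baseline_state, time_in_baseline_state`.
#' @examples
#' ch <- generate_cohort(cohort_config(n_patients = 100, seed = 7))
#' table(ch$baseline_state)
#' @export
generate_cohort <- function(config, parameters = default_parameters()) {
  stopifnot(inherits(config, "cohort_config"))
  validate_parameters(parameters)
  n <- config$n_patients
  if (n == 0) {
    return(data.frame(patient_id = integer(0), age = numeric(0),
                      sex = character(0), diagnosis = character(0),
                      prior_cbtp = logical(0), baseline_state = character(0),
                      time_in_baseline_state = numeric(0),
                      stringsAsFactors = FALSE))
  }
  with_seed(config$seed, {
    age <- rtruncnorm(n, config$age_mean, config$age_sd,
                      config$age_min, config$age_max)
    sex <- ifelse(runif(n) < config$sex_proportion, "male", "female")
    diagnosis <- sample(names(config$diagnosis_mix), n, replace = TRUE,
                        prob = config$diagnosis_mix)
    prior_cbtp <- runif(n) < config$prior_cbtp_proportion
    in_episode <- runif(n) < config$baseline_in_episode_proportion
    sex_male <- as.numeric(sex == "male")
    et <- parameters$episode_type
    baseline_state <- rep("out_of_episode", n)
    if (!is.null(et)) {
      p_in <- vapply(seq_len(n), function(i) {
        episode_type_prob(et, age[i], sex_male[i], diag_indicators(diagnosis[i]))
      }, 0)
    } else {
      p_in <- rep(0.5, n)
    }
    u_type <- runif(n)
    baseline_state[in_episode] <-
      ifelse(u_type[in_episode] < p_in[in_episode],
             "episode_inpatient", "episode_outpatient")
    w <- vapply(seq_len(n), function(i) {
      forward_recurrence_time(parameters, baseline_state[i], age[i],
                              sex_male[i], diag_indicators(diagnosis[i]))
    }, 0)
    data.frame(patient_id = seq_len(n), age = age, sex = sex,
               diagnosis = diagnosis, prior_cbtp = prior_cbtp,
               baseline_state = baseline_state,
               time_in_baseline_state = w,
               stringsAsFactors = FALSE)
  })
}

# stationary forward-recurrence draw of time already spent in a state.
# With all-exponential exits the total exit rate is constant and the
# residual (and hence, by memorylessness, the elapsed) time is exponential
# with that rate; other families have no closed form here and return 0.
forward_recurrence_time <- function(parameters, state, age, sex_male,
                                    diag_ind) {
  specs <- Filter(function(s) s$from == state, parameters$transitions)
  if (!length(specs) ||
      !all(vapply(specs, function(s) s$family == "exponential", TRUE))) {
    return(0)
  }
  total <- sum(vapply(specs, function(s) {
    s$rate * exp(linpred(s$coefs, age, sex_male, diag_ind))
  }, 0))
  if (total <= 0) return(0)
  -log(runif(1)) / total
}

#' Exclude patients who already received CBTp
#'
#' The intervention is only offered to patients who did not receive CBTp
#' during usual care, so flagged patients are removed before simulation.
#' Counts before and after are reported via `message()`; excluding an
#' already-clean cohort is a no-op (the operation is idempotent).
#'
#' @param cohort cohort data frame with a logical `prior_cbtp` column.
#' @return the cohort restricted to `prior_cbtp == FALSE`.
#' @examples
#' ch <- generate_cohort(cohort_config(n_patients = 200, seed = 1))
#' nrow(apply_exclusions(ch))
#' @export
apply_exclusions <- function(cohort) {
  if (!"prior_cbtp" %in% names(cohort)) {
    stop("cohort lacks the 'prior_cbtp' flag")
  }
  n0 <- nrow(cohort)
  out <- cohort[!cohort$prior_cbtp, , drop = FALSE]
  message(sprintf("exclusions: %d of %d patients flagged with prior CBTp; %d retained",
                  n0 - nrow(out), n0, nrow(out)))
  if (n0 > 0 && nrow(out) == 0) {
    warning("all patients excluded: cohort is empty")
  }
  out
}

#' Generate "observed" historical trajectories with known ground truth
#'
#' Simulates the cohort under usual care (no intervention) with the given
#' generating parameters and censors at the horizon, standing in for the
#' non-shareable registry follow-up. Because the output comes from the
#' same generative law as the engine, the estimation functions can be
#' validated by parameter recovery against `true_parameters`.
#'
#' @param cohort cohort data frame.
#' @param true_parameters the generating [parameter_set()].
#' @param horizon follow-up length in years (>= 0; 0 censors everyone
#'   immediately).
#' @param seed integer master seed.
#' @return a `trajectory_set` (see [simulate_arm()]).
#' @export
generate_observed_trajectories <- function(cohort, true_parameters,
                                           horizon = true_parameters$horizon,
                                           seed = 1) {
  stopifnot(horizon >= 0)
  if (horizon == 0) {
    return(new_trajectory_set(
      data.frame(patient_id = integer(0), time = numeric(0),
                 from_state = character(0), to_state = character(0),
                 stringsAsFactors = FALSE),
      data.frame(patient_id = cohort$patient_id,
                 baseline_state = cohort$baseline_state,
                 end_time = rep(0, nrow(cohort)),
                 end_status = rep("censored", nrow(cohort)),
                 stringsAsFactors = FALSE),
      horizon = 0, arm = "tau"))
  }
  simulate_arm(cohort, true_parameters, arm = "tau", outer_index = 0,
               horizon = horizon, master_seed = seed)
}
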