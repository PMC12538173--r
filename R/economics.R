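# Conversion of trajectories into discounted QALYs and costs, and the
# incremental decision statistics (delta costs, delta QALYs, ICER, NMB).
# Discounting is continuous with instantaneous rate rho = log(1 + r), so a
# flow over a whole year discounts exactly as annual compounding would.

#' Present value of a constant flow over a sojourn
#'
#' Discounts a constant per-year value accruing over `[t0, t1]` at annual
#' rate `r`, using the continuous-time closed form
#' `level * (exp(-rho t0) - exp(-rho t1)) / rho` with `rho = log(1 + r)`;
#' an annual rate of 0 returns `level * (t1 - t0)`. Vectorised over all
#' arguments.
#'
#' @param level flow per year (utility or EUR/year).
#' @param t0,t1 interval endpoints in years, `0 <= t0 <= t1`.
#' @param annual_rate annual discount rate (>= 0).
#' @return the discounted value (same units as `level` x years).
#' @examples
#' discounted_sojourn_value(1, 0, 1, 0.035) # ~ 0.98299
#' @export
discounted_sojourn_value <- function(level, t0, t1, annual_rate) {
  if (any(annual_rate < 0)) stop("'annual_rate' must be >= 0")
  if (any(t0 < 0) || any(t1 < t0)) stop("need 0 <= t0 <= t1")
  n <- max(length(level), length(t0), length(t1), length(annual_rate))
  rho <- rep_len(log1p(annual_rate), n)
  out <- rep_len(level, n) * (rep_len(t1, n) - rep_len(t0, n))
  disc <- rho > 0
  if (any(disc)) {
    out[disc] <- (rep_len(level, n) *
                    (exp(-rho * rep_len(t0, n)) -
                       exp(-rho * rep_len(t1, n))) / rho)[disc]
  }
  out
}

#' One-time CBTp treatment cost per patient
#'
#' `n_sessions * unit_cost / group_size`, incurred once at t = 0 in the
#' intervention arm for eligible (non-excluded) patients only; being at
#' t = 0 it is not discounted.
#'
#' @param ic an [intervention_cost()].
#' @return EUR per patient.
#' @examples
#' cbtp_treatment_cost(intervention_cost(16, 108.22, 1)) # 1731.52
#' @export
cbtp_treatment_cost <- function(ic) {
  stopifnot(inherits(ic, "intervention_cost"))
  if (ic$group_size < 1) stop("'group_size' must be >= 1")
  ic$n_sessions * ic$unit_cost / ic$group_size
}

# split spell rows at an absolute time point, so utility bonuses and the
# effect window can be applied per sub-interval
split_spells_at <- function(sp, at) {
  if (!is.finite(at) || at <= 0) return(sp)
  cross <- sp$t0 < at & sp$t1 > at
  if (!any(cross)) return(sp)
  a <- sp[cross, , drop = FALSE]
  b <- a
  a$t1 <- at
  b$t0 <- at
  out <- rbind(sp[!cross, , drop = FALSE], a, b)
  out[order(out$patient_id, out$t0), , drop = FALSE]
}

# vectorised outcome accumulation over a whole arm's spell table
arm_outcomes_from_spells <- function(spells, cohort, draw, arm) {
  sp <- spells[spells$state %in% alive_states(), , drop = FALSE]
  assert_state(spells$state)
  eff <- draw$effect
  bonus_active <- arm == "tau_cbtp" && eff$direct_utility_bonus != 0
  if (bonus_active) sp <- split_spells_at(sp, eff$duration)

  u <- draw$utilities$values[sp$state]
  if (bonus_active) {
    u <- u + ifelse(sp$t1 <= eff$duration, eff$direct_utility_bonus, 0)
  }
  cost_rate <- exp(cost_lp(draw$costs, sp))
  re <- draw$discount$rate_effects
  rc <- draw$discount$rate_costs
  q_disc <- discounted_sojourn_value(u, sp$t0, sp$t1, re)
  q_raw <- u * (sp$t1 - sp$t0)
  c_disc <- discounted_sojourn_value(cost_rate, sp$t0, sp$t1, rc)
  c_raw <- cost_rate * (sp$t1 - sp$t0)

  ids <- cohort$patient_id
  by <- factor(sp$patient_id, levels = ids)
  sum_by <- function(x) {
    if (!length(x)) return(numeric(length(ids)))
    as.numeric(tapply(x, by, sum, default = 0))
  }
  dur <- sp$t1 - sp$t0
  res <- data.frame(
    patient_id = ids,
    qalys = sum_by(q_disc),
    costs = sum_by(c_disc),
    qalys_undiscounted = sum_by(q_raw),
    costs_undiscounted = sum_by(c_raw),
    life_years = sum_by(dur),
    time_out_of_episode = sum_by(dur * (sp$state == "out_of_episode")),
    time_episode_outpatient = sum_by(dur * (sp$state == "episode_outpatient")),
    time_episode_inpatient = sum_by(dur * (sp$state == "episode_inpatient")),
    stringsAsFactors = FALSE)
  if (arm == "tau_cbtp") {
    tc <- cbtp_treatment_cost(draw$intervention)
    res$costs <- res$costs + tc
    res$costs_undiscounted <- res$costs_undiscounted + tc
  }
  res
}

#' Discounted QALYs and costs for simulated trajectories
#'
#' Accumulates, per patient: discounted and undiscounted QALYs (state
#' utility, plus the direct-utility bonus during the effect window in the
#' intervention arm, integrated with the effects discount rate), discounted
#' and undiscounted costs (the cost-equation annual rate per sojourn with
#' the costs discount rate, plus the one-time CBTp cost at t = 0 in the
#' intervention arm), life-years and time per state. Death contributes
#' nothing to either.
#'
#' @param trajectories a `trajectory_set` for one arm.
#' @param cohort the simulated cohort (covariates feed the cost equation).
#' @param draw the [parameter_set()] / PSA draw the arm was simulated
#'   under.
#' @param arm `"tau"` or `"tau_cbtp"`; defaults to the arm recorded in
#'   `trajectories`.
#' @return data frame of class `patient_outcomes`, one row per patient.
#' @export
arm_outcomes <- function(trajectories, cohort, draw,
                         arm = attr(trajectories, "arm")) {
  stopifnot(arm %in% arms())
  spells <- extract_spells(trajectories, cohort)
  out <- arm_outcomes_from_spells(spells, cohort, draw, arm)
  class(out) <- c("patient_outcomes", class(out))
  attr(out, "arm") <- arm
  out
}

#' Outcomes of a single patient trajectory
#'
#' Single-trajectory wrapper around the vectorised accumulation: takes one
#' patient's sojourn records and returns their discounted QALYs and costs.
#'
#' @param sojourns data frame with columns `state, t0, t1` (one row per
#'   sojourn; death rows are ignored as death accrues nothing).
#' @param utilities a [utility_set()].
#' @param cost_eq a [cost_equation()].
#' @param discount a [discount_spec()].
#' @param effect a [treatment_effect()] (for the utility bonus window).
#' @param arm `"tau"` or `"tau_cbtp"`.
#' @param profile optional list/row with `age, sex, diagnosis` for the
#'   cost-equation covariates (defaults give zero covariate contribution).
#' @param intervention an [intervention_cost()] added at t = 0 when `arm`
#'   is the intervention arm; default adds nothing.
#' @return one-row data frame as in [arm_outcomes()].
#' @examples
#' tr <- data.frame(state = "out_of_episode", t0 = 0, t1 = 10)
#' accumulate_outcomes(tr, default_utilities(), cost_equation(
#'   c(out_of_episode = log(1000), episode_outpatient = log(1000),
#'     episode_inpatient = log(1000))),
#'   discount_spec(0, 0), treatment_effect(), "tau")
#' @export
accumulate_outcomes <- function(sojourns, utilities, cost_eq, discount,
                                effect, arm, profile = NULL,
                                intervention = intervention_cost(0, 0, 1)) {
  draw <- list(utilities = utilities, costs = cost_eq, discount = discount,
               effect = effect, intervention = intervention)
  sp <- sojourns
  sp$patient_id <- sp$patient_id %||% 1L
  sp$age_decades <- ((profile$age %||% 0) + sp$t0) / 10
  sp$sex_male <- as.numeric((profile$sex %||% "") == "male")
  if (!is.null(profile$diagnosis)) {
    sp[[paste0("diagnosis_", profile$diagnosis)]] <- 1
  }
  sp$duration <- sp$t1 - sp$t0
  cohort <- data.frame(patient_id = unique(sp$patient_id))
  arm_outcomes_from_spells(sp, cohort, draw, arm)
}

#' Incremental cost-effectiveness statistics for a CRN-paired comparison
#'
#' Differences the per-patient means of two outcome tables simulated on
#' the same patients (common random numbers), and reports the incremental
#' cost-effectiveness ratio and net monetary benefit. The ICER is the
#' ratio `delta_costs / delta_qalys` only in the trade-off quadrants; an
#' intervention that saves money and gains QALYs is labelled `"dominant"`,
#' one that costs money and loses QALYs `"dominated"` (no ratio reported).
#'
#' @param outcomes_tau,outcomes_cbtp [arm_outcomes()] tables for the two
#'   arms (identical `patient_id` sets, same order not required).
#' @param wtp willingness-to-pay threshold, EUR/QALY.
#' @return object of class `incremental_result`: `delta_costs`,
#'   `delta_qalys` (per patient), `icer` (number or dominance label),
#'   `nmb` (`wtp * delta_qalys - delta_costs`), `wtp`, `n`.
#' @examples
#' # the published worked example: EUR 492 / 0.038 QALY ~ EUR 12,947 per QALY
#' 492 / 0.038
#' @export
incremental <- function(outcomes_tau, outcomes_cbtp, wtp = 50000) {
  if (nrow(outcomes_tau) != nrow(outcomes_cbtp) ||
      !setequal(outcomes_tau$patient_id, outcomes_cbtp$patient_id)) {
    stop("arm outcome tables are not paired on the same patients")
  }
  m <- match(outcomes_tau$patient_id, outcomes_cbtp$patient_id)
  dc <- mean(outcomes_cbtp$costs[m]) - mean(outcomes_tau$costs)
  de <- mean(outcomes_cbtp$qalys[m]) - mean(outcomes_tau$qalys)
  icer <- if (de > 0 && dc < 0) {
    "dominant"
  } else if (de < 0 && dc > 0) {
    "dominated"
  } else if (de == 0) {
    if (dc == 0) "equivalent" else if (dc > 0) "dominated" else "dominant"
  } else {
    dc / de
  }
  structure(list(delta_costs = dc, delta_qalys = de, icer = icer,
                 nmb = wtp * de - dc, wtp = wtp, n = nrow(outcomes_tau)),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("Incremental result over %d paired patients:\n", x$n))
  cat(sprintf("  delta costs:  EUR %.2f per patient\n", x$delta_costs))
  cat(sprintf("  delta QALYs:  %.4f per patient\n", x$delta_qalys))
  if (is.character(x$icer)) {
    cat(sprintf("  ICER:         %s\n", x$icer))
  } else {
    cat(sprintf("  ICER:         EUR %.0f per QALY\n", x$icer))
  }
  cat(sprintf("  NMB @ EUR %g: EUR %.2f per patient\n", x$wtp, x$nmb))
  invisible(x)
}

#' Scale per-patient incremental results to an eligible population
#'
#' Multiplies per-patient incremental QALYs and costs by the size of the
#' eligible population. That size is an input: the model does not estimate
#' how many patients nationwide would be offered the treatment.
#'
#' @param per_patient an [incremental()] result.
#' @param n_eligible eligible population size (> 0).
#' @return list with `total_qalys`, `total_costs`, `n_eligible`.
#' @export
population_extrapolation <- function(per_patient, n_eligible) {
  stopifnot(inherits(per_patient, "incremental_result"))
  if (!is.numeric(n_eligible) || n_eligible <= 0) {
    stop("'n_eligible' must be > 0")
  }
  list(total_qalys = per_patient$delta_qalys * n_eligible,
       total_costs = per_patient$delta_costs * n_eligible,
       n_eligible = n_eligible)
}
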