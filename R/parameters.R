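#' Parametric specification of one state-to-state transition
#'
#' A cause-specific hazard for one transition of the multi-state model.
#' Supported families and their parameterisations follow
#' [flexsurv::flexsurvreg()]:
#' * `exponential`: constant hazard `rate` (1/years);
#' * `weibull`: shape/scale accelerated-failure form, cumulative hazard
#'   `(t/scale)^shape`; covariates act multiplicatively on `scale`
#'   (time-acceleration); the proportional-hazards equivalent of a
#'   log-scale coefficient `b` is `-shape * b` on the log-hazard;
#' * `gompertz`: hazard `rate * exp(shape * t)` with `shape` possibly
#'   negative; covariates act on `rate` (proportional hazards).
#'
#' `coefs` is a named numeric vector of covariate coefficients; recognised
#' names are `age_decades` (current age / 10, updated continuously with
#' simulation time), `sex_male` (0/1) and `diagnosis_<level>` indicators.
#' `se` holds prior standard errors for the probabilistic sensitivity
#' analysis, on the log-parameter scale for `rate`/`scale`/`shape`
#' (entries `log_rate`, `log_scale`, `log_shape`) and on the coefficient
#' scale for covariates.
#'
#' @param from,to state labels; `to` may be `"in_episode"` for a relapse
#'   whose destination (outpatient vs inpatient episode) is resolved by the
#'   episode-type sub-model at relapse time.
#' @param family `"exponential"`, `"weibull"` or `"gompertz"`.
#' @param rate,shape,scale positive reals in year units (see above; which
#'   are required depends on the family).
#' @param coefs named numeric vector of covariate coefficients.
#' @param se named numeric vector of PSA standard errors (may be empty).
#' @return an object of class `transition_spec`.
#' @examples
#' transition_spec("out_of_episode", "in_episode", "exponential", rate = 0.4)
#' @export
transition_spec <- function(from, to,
                            family = c("exponential", "weibull", "gompertz"),
                            rate = NULL, shape = NULL, scale = NULL,
                            coefs = numeric(0), se = numeric(0)) {
  family <- match.arg(family)
  assert_state(from, alive_states(), "from_state")
  assert_state(to, c(health_states(), IN_EPISODE), "to_state")
  if (identical(from, "dead")) stop("no transitions out of the death state")
  chk_pos <- function(x, nm) {
    if (is.null(x)) stop(sprintf("transition %s->%s (%s): '%s' is required",
                                 from, to, family, nm), call. = FALSE)
    if (!is.finite(x) || x <= 0) {
      stop(sprintf("transition %s->%s: '%s' must be a positive number",
                   from, to, nm), call. = FALSE)
    }
    x
  }
  params <- switch(family,
    exponential = list(rate = chk_pos(rate, "rate")),
    weibull = list(shape = chk_pos(shape, "shape"),
                   scale = chk_pos(scale, "scale")),
    gompertz = {
      if (is.null(shape) || !is.finite(shape)) {
        stop("gompertz transition needs a finite 'shape'", call. = FALSE)
      }
      list(shape = shape, rate = chk_pos(rate, "rate"))
    })
  structure(c(list(from = from, to = to, family = family),
              params,
              list(coefs = unlist(coefs) %||% numeric(0),
                   se = unlist(se) %||% numeric(0))),
            class = "transition_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Time-limited relative-risk treatment effect of CBTp
#'
#' CBTp is modelled as a relative risk `rr` on the relapse hazard, active
#' during the effect window `[0, duration)` anchored at simulation start
#' (treatment is delivered once, at baseline). `target` selects whether the
#' effect multiplies all relapse transitions or only relapses into episodes
#' with inpatient care (rehospitalisation). `direct_utility_bonus` is an
#' additive utility increment active during the effect window in the
#' intervention arm, default 0; it exists for one-way sensitivity analysis
#' of direct quality-of-life improvements.
#'
#' @param rr relative risk (dimensionless, > 0); base case 0.79.
#' @param ci_low,ci_high 95\% confidence bounds around `rr`, used to build
#'   the lognormal PSA distribution (see [rr_to_lognormal()]).
#' @param duration effect duration in years (> 0); base case 2.
#' @param target `"all_relapse"` or `"inpatient_relapse_only"`.
#' @param direct_utility_bonus additive utility during the effect window.
#' @return an object of class `treatment_effect`.
#' @export
treatment_effect <- function(rr = 0.79, ci_low = 0.60, ci_high = 1.04,
                             duration = 2,
                             target = c("all_relapse", "inpatient_relapse_only"),
                             direct_utility_bonus = 0) {
  target <- match.arg(target)
  if (!is.finite(rr) || rr <= 0) stop("effect 'rr' must be positive")
  if (!(ci_low > 0 && ci_low <= rr && rr <= ci_high)) {
    stop("effect CI must satisfy 0 < ci_low <= rr <= ci_high")
  }
  if (!is.finite(duration) || duration <= 0) {
    stop("effect 'duration' must be positive")
  }
  structure(list(rr = rr, ci_low = ci_low, ci_high = ci_high,
                 duration = duration, target = target,
                 direct_utility_bonus = direct_utility_bonus),
            class = "treatment_effect")
}

#' Health-state utility weights
#'
#' One utility weight (dimensionless, in `[-1, 1]`) and its standard error
#' per alive state; death has utility 0 by construction. `provenance`
#' records whether the weights come from a patient time-trade-off sample
#' (`"patient_TTO"`, the base case) or a lay-person sample (`"lay_TTO"`,
#' a scenario). The shipped values are documented placeholders, not
#' registry estimates.
#'
#' @param values,ses named numeric vectors over [alive_states()].
#' @param provenance `"patient_TTO"` or `"lay_TTO"`.
#' @return an object of class `utility_set`.
#' @seealso [midpoint_utility()] for the rule used to fill the
#'   episode-with-outpatient-care state.
#' @export
utility_set <- function(values, ses, provenance = c("patient_TTO", "lay_TTO")) {
  provenance <- match.arg(provenance)
  st <- alive_states()
  if (!all(st %in% names(values)) || !all(st %in% names(ses))) {
    stop("utility_set needs named 'values' and 'ses' for every alive state")
  }
  values <- unlist(values)[st]
  ses <- unlist(ses)[st]
  if (any(values < -1 | values > 1)) stop("utility values must lie in [-1, 1]")
  if (any(ses < 0)) stop("utility standard errors must be >= 0")
  structure(list(values = values, ses = ses, provenance = provenance),
            class = "utility_set")
}

#' Shipped placeholder utility weights
#'
#' The base `"patient_TTO"` set uses 0.92 for stable out-of-episode, 0.60
#' for in-episode with inpatient care and the [midpoint_utility()] rule
#' for in-episode with outpatient care (0.76, SE 0.05); the `"lay_TTO"`
#' scenario set widens the gap between stable and in-episode health, as
#' lay valuation samples typically do. Both are documented placeholders,
#' not registry estimates.
#'
#' @param provenance `"patient_TTO"` (base case) or `"lay_TTO"`.
#' @return a [utility_set()].
#' @export
default_utilities <- function(provenance = c("patient_TTO", "lay_TTO")) {
  provenance <- match.arg(provenance)
  if (provenance == "patient_TTO") {
    mid <- midpoint_utility(0.92, 0.03, 0.60, 0.05)
    utility_set(
      values = c(out_of_episode = 0.92,
                 episode_outpatient = mid$value,
                 episode_inpatient = 0.60),
      ses = c(out_of_episode = 0.03,
              episode_outpatient = mid$se,
              episode_inpatient = 0.05),
      provenance = "patient_TTO")
  } else {
    # lay-person TTO samples typically value the severe states lower,
    # widening the gap between stable and in-episode health
    mid <- midpoint_utility(0.90, 0.03, 0.48, 0.06)
    utility_set(
      values = c(out_of_episode = 0.90,
                 episode_outpatient = mid$value,
                 episode_inpatient = 0.48),
      ses = c(out_of_episode = 0.03,
              episode_outpatient = mid$se,
              episode_inpatient = 0.06),
      provenance = "lay_TTO")
  }
}

#' Midpoint rule for the episode-with-outpatient-care utility
#'
#' The utility of the in-episode-with-outpatient-care state is the average
#' of the best (stable out-of-episode) and worst (in-episode with inpatient
#' care) state utilities; its uncertainty is the larger of the two standard
#' errors.
#'
#' @param u_best,se_best utility and SE of the best state.
#' @param u_worst,se_worst utility and SE of the worst state.
#' @return list with elements `value` and `se`.
#' @examples
#' midpoint_utility(0.9, 0.02, 0.6, 0.05) # value 0.75, se 0.05
#' @export
midpoint_utility <- function(u_best, se_best, u_worst, se_worst) {
  list(value = (u_best + u_worst) / 2, se = max(se_best, se_worst))
}

#' Log-linear cost equation
#'
#' Assigns an annualised cost rate (EUR/year, price year 2019) to a patient
#' occupying a state: `rate = exp(intercept[state] + X beta)`, guaranteeing
#' non-negative costs. Recognised coefficient names are as in
#' [transition_spec()] plus `sojourn_years` (the modelled length of the
#' current sojourn; defaults to an absent/zero coefficient). Death costs
#' nothing.
#'
#' @param intercepts named numeric vector of log cost-rate intercepts over
#'   [alive_states()].
#' @param coefs named numeric covariate coefficients (log scale).
#' @param se named PSA standard errors for intercepts (`<state>`) and
#'   coefficients.
#' @return an object of class `cost_equation`.
#' @export
cost_equation <- function(intercepts, coefs = numeric(0), se = numeric(0)) {
  st <- alive_states()
  if (!all(st %in% names(intercepts))) {
    stop("cost_equation needs named 'intercepts' for every alive state")
  }
  structure(list(intercepts = unlist(intercepts)[st],
                 coefs = unlist(coefs) %||% numeric(0),
                 se = unlist(se) %||% numeric(0)),
            class = "cost_equation")
}

#' One-time CBTp intervention cost
#'
#' @param n_sessions number of therapy sessions (base case 16).
#' @param unit_cost cost per session in EUR (base case 108.22, price year
#'   2019: one hour of a qualified practitioner).
#' @param group_size patients per session (>= 1); > 1 models group therapy
#'   with the session cost shared.
#' @return an object of class `intervention_cost`.
#' @export
intervention_cost <- function(n_sessions = 16, unit_cost = 108.22,
                              group_size = 1) {
  if (n_sessions < 0) stop("'n_sessions' must be >= 0")
  if (unit_cost < 0) stop("'unit_cost' must be >= 0")
  if (group_size < 1) stop("'group_size' must be >= 1")
  structure(list(n_sessions = n_sessions, unit_cost = unit_cost,
                 group_size = group_size),
            class = "intervention_cost")
}

#' Annual discount rates for costs and effects
#'
#' Base case 3.5\%/3.5\% (UK guideline); the Dutch-guideline scenario uses
#' 4\% for costs and 1.5\% for effects.
#'
#' @param rate_costs,rate_effects annual rates (>= 0, dimensionless).
#' @return an object of class `discount_spec`.
#' @export
discount_spec <- function(rate_costs = 0.035, rate_effects = 0.035) {
  if (rate_costs < 0 || rate_effects < 0) stop("discount rates must be >= 0")
  structure(list(rate_costs = rate_costs, rate_effects = rate_effects),
            class = "discount_spec")
}

#' Logistic sub-model for the episode type at relapse
#'
#' Pr(episode includes inpatient care | covariates) =
#' `plogis(intercept + X beta)`. Used both at relapse time in the engine
#' (when `relapse_mode = "episode_type_model"`) and to assign baseline
#' episode types in the synthetic cohort.
#'
#' @param intercept log-odds intercept.
#' @param coefs named numeric covariate coefficients (names as in
#'   [transition_spec()]).
#' @param se named PSA standard errors (`intercept` plus coefficient names).
#' @return an object of class `episode_type_model`.
#' @export
episode_type_model <- function(intercept, coefs = numeric(0), se = numeric(0)) {
  structure(list(intercept = intercept,
                 coefs = unlist(coefs) %||% numeric(0),
                 se = unlist(se) %||% numeric(0)),
            class = "episode_type_model")
}

#' Assemble and validate a full model parameterisation
#'
#' A `parameter_set` carries everything a simulation run needs: the
#' transition hazards, the episode-type sub-model, utilities, cost
#' equation, intervention cost, treatment effect, discount rates, the time
#' horizon (default 10 years) and the willingness-to-pay threshold
#' (default EUR 50,000 per QALY). A `parameter_draw` (from
#' [draw_psa_parameters()]) has the same structure with uncertain
#' quantities realised from their PSA distributions.
#'
#' `relapse_mode` selects how the two episode types arise: with
#' `"episode_type_model"` a single relapse hazard is split at relapse time
#' by the logistic sub-model; with `"competing"` the transition list must
#' instead contain separate competing hazards out-of-episode ->
#' episode_outpatient and -> episode_inpatient.
#'
#' @param transitions named list of [transition_spec()] objects covering
#'   every transition of the state graph.
#' @param episode_type an [episode_type_model()] (required in
#'   `"episode_type_model"` mode).
#' @param utilities a [utility_set()].
#' @param costs a [cost_equation()].
#' @param intervention an [intervention_cost()].
#' @param effect a [treatment_effect()].
#' @param discount a [discount_spec()].
#' @param horizon simulation horizon in years (> 0).
#' @param wtp willingness-to-pay threshold, EUR/QALY.
#' @param relapse_mode `"episode_type_model"` or `"competing"`.
#' @return an object of class `parameter_set`.
#' @seealso [default_parameters()], [load_parameters()],
#'   [draw_psa_parameters()].
#' @export
parameter_set <- function(transitions, episode_type = NULL, utilities,
                          costs, intervention, effect, discount,
                          horizon = 10, wtp = 50000,
                          relapse_mode = c("episode_type_model", "competing")) {
  relapse_mode <- match.arg(relapse_mode)
  ps <- structure(list(transitions = transitions,
                       episode_type = episode_type,
                       utilities = utilities,
                       costs = costs,
                       intervention = intervention,
                       effect = effect,
                       discount = discount,
                       horizon = horizon,
                       wtp = wtp,
                       relapse_mode = relapse_mode),
                  class = "parameter_set")
  validate_parameters(ps)
}

#' @rdname parameter_set
#' @param params object to validate.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  req <- function(field, cls) {
    x <- params[[field]]
    if (is.null(x)) stop(sprintf("parameter field '%s' is missing", field),
                         call. = FALSE)
    if (!is.null(cls) && !inherits(x, cls)) {
      stop(sprintf("parameter field '%s' must be a %s", field, cls),
           call. = FALSE)
    }
    x
  }
  req("effect", "treatment_effect")
  req("utilities", "utility_set")
  req("costs", "cost_equation")
  req("intervention", "intervention_cost")
  req("discount", "discount_spec")
  if (!is.numeric(params$horizon) || params$horizon <= 0) {
    stop("parameter field 'horizon' must be > 0", call. = FALSE)
  }
  if (!is.numeric(params$wtp) || params$wtp < 0) {
    stop("parameter field 'wtp' must be >= 0", call. = FALSE)
  }
  trs <- req("transitions", NULL)
  if (!length(trs) || !all(vapply(trs, inherits, TRUE, "transition_spec"))) {
    stop("'transitions' must be a non-empty list of transition_spec objects",
         call. = FALSE)
  }
  froms <- vapply(trs, `[[`, "", "from")
  tos <- vapply(trs, `[[`, "", "to")
  if (any(froms == "dead")) stop("no transitions out of the death state",
                                 call. = FALSE)
  if (params$relapse_mode == "episode_type_model") {
    if (!inherits(params$episode_type, "episode_type_model")) {
      stop("parameter field 'episode_type' is missing", call. = FALSE)
    }
    if (!any(froms == "out_of_episode" & tos == IN_EPISODE)) {
      stop("episode_type_model mode needs an out_of_episode -> in_episode relapse transition",
           call. = FALSE)
    }
  } else {
    if (!all(c("episode_outpatient", "episode_inpatient") %in%
             tos[froms == "out_of_episode"])) {
      stop("competing mode needs separate relapse transitions into both episode states",
           call. = FALSE)
    }
  }
  for (s in episode_states()) {
    if (!any(froms == s & tos == "out_of_episode")) {
      stop(sprintf("missing remission transition %s -> out_of_episode", s),
           call. = FALSE)
    }
  }
  params
}

#' Base-case model parameterisation
#'
#' The base-case treatment parameters are: relative risk 0.79 (95\% CI
#' 0.60-1.04) on relapse for 2 years, 16 individual sessions at EUR 108.22,
#' discounting 3.5\%/3.5\%, 10-year horizon, WTP EUR 50,000/QALY.
#' Transition rates, the episode-type intercept, utility weights and cost
#' intercepts are documented placeholders chosen to be clinically
#' plausible for a specialised mental-healthcare population (the registry
#' estimates they stand in for are not published); see the package
#' vignette for the rationale behind each value.
#'
#' @return a [parameter_set()].
#' @examples
#' p <- default_parameters()
#' p$effect$rr
#' @export
default_parameters <- function() {
  parameter_set(
    transitions = list(
      relapse = transition_spec(
        "out_of_episode", IN_EPISODE, "exponential", rate = 0.40,
        se = c(log_rate = 0.05)),
      remission_outpatient = transition_spec(
        "episode_outpatient", "out_of_episode", "exponential", rate = 2.0,
        se = c(log_rate = 0.05)),
      remission_inpatient = transition_spec(
        "episode_inpatient", "out_of_episode", "exponential", rate = 1.5,
        se = c(log_rate = 0.05)),
      death_out = transition_spec(
        "out_of_episode", "dead", "exponential", rate = 0.010,
        se = c(log_rate = 0.10)),
      death_episode_outpatient = transition_spec(
        "episode_outpatient", "dead", "exponential", rate = 0.020,
        se = c(log_rate = 0.10)),
      death_episode_inpatient = transition_spec(
        "episode_inpatient", "dead", "exponential", rate = 0.020,
        se = c(log_rate = 0.10))),
    episode_type = episode_type_model(intercept = qlogis(0.35),
                                      se = c(intercept = 0.10)),
    utilities = default_utilities("patient_TTO"),
    costs = cost_equation(
      intercepts = c(out_of_episode = log(3000),
                     episode_outpatient = log(15000),
                     episode_inpatient = log(60000)),
      se = c(out_of_episode = 0.05, episode_outpatient = 0.05,
             episode_inpatient = 0.05)),
    intervention = intervention_cost(16, 108.22, 1),
    effect = treatment_effect(0.79, 0.60, 1.04, duration = 2),
    discount = discount_spec(0.035, 0.035),
    horizon = 10,
    wtp = 50000)
}

#' Convert a published relative risk and CI into a lognormal distribution
#'
#' Given a relative risk with a symmetric-on-the-log-scale confidence
#' interval, returns the lognormal sampling distribution used in the PSA:
#' `meanlog = log(rr)` and
#' `sdlog = (log(ci_high) - log(ci_low)) / (2 * z)` with `z` the exact
#' standard-normal quantile for the interval level.
#'
#' @param rr,ci_low,ci_high point estimate and confidence bounds (> 0).
#' @param level confidence level of the interval (default 0.95).
#' @return list with `meanlog` and `sdlog`.
#' @examples
#' rr_to_lognormal(0.79, 0.60, 1.04) # meanlog ~ -0.2357, sdlog ~ 0.1403
#' @export
rr_to_lognormal <- function(rr, ci_low, ci_high, level = 0.95) {
  if (any(c(rr, ci_low, ci_high) <= 0)) {
    stop("relative risk and CI bounds must be positive")
  }
  if (!(ci_low <= rr && rr <= ci_high)) {
    stop("need ci_low <= rr <= ci_high")
  }
  z <- qnorm(1 - (1 - level) / 2)
  list(meanlog = log(rr), sdlog = (log(ci_high) - log(ci_low)) / (2 * z))
}

# Moment-matched beta draw for a utility weight; falls back to a normal
# truncated to [0, 1] when the SE is too large for the mean.
draw_utility <- function(mean, se) {
  if (se == 0) return(mean)
  if (mean <= 0 || mean >= 1 || se^2 >= mean * (1 - mean)) {
    warning(sprintf(
      "beta moment matching infeasible for utility mean %.3f, se %.3f; using truncated normal",
      mean, se))
    repeat {
      x <- rnorm(1, mean, se)
      if (x >= 0 && x <= 1) return(x)
    }
  }
  nu <- mean * (1 - mean) / se^2 - 1
  rbeta(1, mean * nu, (1 - mean) * nu)
}

#' Draw one PSA realisation of the parameter set
#'
#' Samples each uncertain quantity from its probabilistic-sensitivity
#' distribution: the treatment-effect relative risk from the lognormal
#' implied by its confidence interval ([rr_to_lognormal()]); state
#' utilities from moment-matched beta distributions, re-drawn until the
#' ordering out-of-episode >= episode-outpatient >= episode-inpatient
#' holds; transition parameters, episode-type coefficients and cost
#' coefficients from normal distributions around their point values (log
#' scale for positive parameters). Structural quantities -- session count,
#' discount rates, horizon, effect duration -- are left untouched.
#' Quantities with zero/absent standard errors are degenerate and return
#' their point values, so a parameter set with all SEs zero draws itself.
#'
#' @param params a [parameter_set()].
#' @param seed integer seed addressing this draw's random substream; the
#'   same seed always yields the same draw.
#' @return the drawn `parameter_set`, with class `parameter_draw` prepended.
#' @export
draw_psa_parameters <- function(params, seed) {
  validate_parameters(params)
  with_seed(as.integer(seed), {
    draw <- params

    ln <- rr_to_lognormal(params$effect$rr, params$effect$ci_low,
                          params$effect$ci_high)
    if (ln$sdlog > 0) {
      rr <- exp(rnorm(1, ln$meanlog, ln$sdlog))
      draw$effect$rr <- rr
      draw$effect$ci_low <- min(draw$effect$ci_low, rr)
      draw$effect$ci_high <- max(draw$effect$ci_high, rr)
    }

    u <- params$utilities
    for (tries in seq_len(1000)) {
      vals <- mapply(draw_utility, u$values, u$ses)
      if (vals["out_of_episode"] >= vals["episode_outpatient"] &&
          vals["episode_outpatient"] >= vals["episode_inpatient"]) break
      if (tries == 1000) vals[] <- sort(unname(vals), decreasing = TRUE)
    }
    draw$utilities$values[] <- vals

    draw$transitions <- lapply(params$transitions, draw_transition)

    et <- params$episode_type
    if (!is.null(et)) {
      draw$episode_type$intercept <-
        et$intercept + rnorm(1, 0, se_of(et$se, "intercept"))
      draw$episode_type$coefs <- draw_coefs(et$coefs, et$se)
    }

    ce <- params$costs
    draw$costs$intercepts <- ce$intercepts +
      rnorm(length(ce$intercepts), 0,
            vapply(names(ce$intercepts), se_of, 0, se = ce$se))
    draw$costs$coefs <- draw_coefs(ce$coefs, ce$se)

    class(draw) <- c("parameter_draw", class(params))
    draw
  })
}

se_of <- function(se, name) if (name %in% names(se)) se[[name]] else 0

draw_coefs <- function(coefs, se) {
  if (!length(coefs)) return(coefs)
  coefs + rnorm(length(coefs), 0,
                vapply(names(coefs), se_of, 0, se = se))
}

draw_transition <- function(spec) {
  for (p in intersect(c("rate", "scale"), names(spec))) {
    s <- se_of(spec$se, paste0("log_", p))
    if (s > 0) spec[[p]] <- exp(log(spec[[p]]) + rnorm(1, 0, s))
  }
  if ("shape" %in% names(spec)) {
    s <- se_of(spec$se, "log_shape")
    if (s > 0 && spec$shape > 0) {
      spec$shape <- exp(log(spec$shape) + rnorm(1, 0, s))
    }
  }
  spec$coefs <- draw_coefs(spec$coefs, spec$se)
  spec
}

#' @export
print.parameter_set <- function(x, ...) {
  kind <- if (inherits(x, "parameter_draw")) "PSA parameter draw" else
    "Model parameter set"
  cat(sprintf("%s (%d transitions, relapse mode '%s')\n", kind,
              length(x$transitions), x$relapse_mode))
  cat(sprintf("  effect: RR %.3f (CI %.2f-%.2f) on %s for %g y\n",
              x$effect$rr, x$effect$ci_low, x$effect$ci_high,
              x$effect$target, x$effect$duration))
  cat(sprintf("  utilities (%s): %s\n", x$utilities$provenance,
              paste(sprintf("%s=%.3f", names(x$utilities$values),
                            x$utilities$values), collapse = ", ")))
  cat(sprintf("  intervention: %g sessions x EUR %.2f / group of %g\n",
              x$intervention$n_sessions, x$intervention$unit_cost,
              x$intervention$group_size))
  cat(sprintf("  discounting %.1f%%/%.1f%% (costs/effects), horizon %g y, WTP EUR %g\n",
              100 * x$discount$rate_costs, 100 * x$discount$rate_effects,
              x$horizon, x$wtp))
  invisible(x)
}
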