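# Serialisation of parameter sets (YAML / JSON) and of cohort and
# trajectory tables (CSV). Parameter files carry a schema version and the
# currency/price-year tag; all times are years, all money is EUR.

params_to_list <- function(params) {
  tr <- lapply(params$transitions, function(s) {
    out <- list(from = s$from, to = s$to, family = s$family)
    for (p in intersect(c("rate", "shape", "scale"), names(s))) out[[p]] <- s[[p]]
    out$coefs <- as.list(s$coefs)
    out$se <- as.list(s$se)
    out
  })
  list(
    schema_version = 1L,
    currency = list(unit = "EUR", price_year = 2019L),
    horizon = params$horizon,
    wtp = params$wtp,
    relapse_mode = params$relapse_mode,
    effect = unclass(params$effect),
    utilities = list(values = as.list(params$utilities$values),
                     ses = as.list(params$utilities$ses),
                     provenance = params$utilities$provenance),
    costs = list(intercepts = as.list(params$costs$intercepts),
                 coefs = as.list(params$costs$coefs),
                 se = as.list(params$costs$se)),
    intervention = unclass(params$intervention),
    episode_type = if (!is.null(params$episode_type)) {
      list(intercept = params$episode_type$intercept,
           coefs = as.list(params$episode_type$coefs),
           se = as.list(params$episode_type$se))
    },
    discount = unclass(params$discount),
    transitions = tr)
}

num_vec <- function(x) {
  if (is.null(x) || !length(x)) numeric(0) else unlist(x)
}

need <- function(x, field) {
  if (is.null(x)) stop(sprintf("parameter field '%s' is missing", field),
                       call. = FALSE)
  x
}

params_from_list <- function(pl) {
  eff <- need(pl$effect, "effect")
  need(eff$rr, "effect.rr")
  need(eff$ci_low, "effect.ci_low")
  need(eff$ci_high, "effect.ci_high")
  ut <- need(pl$utilities, "utilities")
  co <- need(pl$costs, "costs")
  trs <- need(pl$transitions, "transitions")
  defaults <- character(0)
  dflt <- function(x, field, value) {
    if (!is.null(x)) return(x)
    defaults <<- c(defaults, sprintf("%s = %s", field, format(value)))
    value
  }
  params <- parameter_set(
    transitions = lapply(trs, function(s) {
      transition_spec(need(s$from, "transitions.from"),
                      need(s$to, "transitions.to"),
                      need(s$family, "transitions.family"),
                      rate = s$rate, shape = s$shape, scale = s$scale,
                      coefs = num_vec(s$coefs), se = num_vec(s$se))
    }),
    episode_type = if (!is.null(pl$episode_type)) {
      episode_type_model(need(pl$episode_type$intercept,
                              "episode_type.intercept"),
                         coefs = num_vec(pl$episode_type$coefs),
                         se = num_vec(pl$episode_type$se))
    },
    utilities = utility_set(num_vec(need(ut$values, "utilities.values")),
                            num_vec(need(ut$ses, "utilities.ses")),
                            dflt(ut$provenance, "utilities.provenance",
                                 "patient_TTO")),
    costs = cost_equation(num_vec(need(co$intercepts, "costs.intercepts")),
                          coefs = num_vec(co$coefs), se = num_vec(co$se)),
    intervention = do.call(intervention_cost,
                           need(pl$intervention, "intervention")),
    effect = treatment_effect(eff$rr, eff$ci_low, eff$ci_high,
                              duration = need(eff$duration, "effect.duration"),
                              target = dflt(eff$target, "effect.target",
                                            "all_relapse"),
                              direct_utility_bonus =
                                dflt(eff$direct_utility_bonus,
                                     "effect.direct_utility_bonus", 0)),
    discount = do.call(discount_spec, need(pl$discount, "discount")),
    horizon = dflt(pl$horizon, "horizon", 10),
    wtp = dflt(pl$wtp, "wtp", 50000),
    relapse_mode = dflt(pl$relapse_mode, "relapse_mode",
                        "episode_type_model"))
  if (length(defaults)) {
    message("filled parameter defaults: ", paste(defaults, collapse = "; "))
  }
  params
}

#' Read and write parameter files
#'
#' Parameter sets are stored as YAML or JSON (chosen by file extension)
#' with a versioned schema; EUR amounts are tagged with price year 2019.
#' Loading validates every field and fills documented defaults (horizon,
#' WTP, effect target, relapse mode) with a message; a missing required
#' field raises an error naming it. `parameter_schema()` returns a list
#' documenting every field of the format.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @param params a [parameter_set()].
#' @return `load_parameters()` returns a validated [parameter_set()];
#'   `save_parameters()` invisibly returns `path`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' save_parameters(default_parameters(), f)
#' p <- load_parameters(f)
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  pl <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  params_from_list(pl)
}

#' @rdname load_parameters
#' @export
save_parameters <- function(params, path) {
  validate_parameters(params)
  pl <- params_to_list(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(pl, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(pl, path)
  }
  invisible(path)
}

#' @rdname load_parameters
#' @export
parameter_schema <- function() {
  list(
    schema_version = "integer; format version, currently 1",
    currency = "unit and price year of all monetary amounts (EUR, 2019)",
    horizon = "simulation horizon in years (> 0, default 10)",
    wtp = "willingness-to-pay threshold, EUR/QALY (default 50000)",
    relapse_mode = "'episode_type_model' (single relapse hazard split by the logistic sub-model) or 'competing' (separate hazards per episode type)",
    effect = list(
      rr = "relative risk on the targeted relapse hazard (> 0)",
      ci_low = "lower 95% bound (0 < ci_low <= rr)",
      ci_high = "upper 95% bound (>= rr)",
      duration = "effect duration in years after one-time treatment at t = 0",
      target = "'all_relapse' or 'inpatient_relapse_only'",
      direct_utility_bonus = "additive utility during the effect window"),
    utilities = list(
      values = "named utility weight in [-1, 1] per alive state",
      ses = "named standard error (>= 0) per alive state",
      provenance = "'patient_TTO' or 'lay_TTO'"),
    costs = list(
      intercepts = "named log annual-cost-rate intercept per alive state (EUR/year)",
      coefs = "named covariate coefficients on the log cost rate (age_decades, sex_male, diagnosis_<level>, sojourn_years)",
      se = "named PSA standard errors"),
    intervention = list(
      n_sessions = "number of therapy sessions (>= 0)",
      unit_cost = "EUR per session",
      group_size = "patients sharing a session (>= 1)"),
    episode_type = list(
      intercept = "log-odds of an inpatient episode at relapse",
      coefs = "named covariate coefficients",
      se = "named PSA standard errors ('intercept' + coefficient names)"),
    discount = list(
      rate_costs = "annual discount rate for costs (>= 0)",
      rate_effects = "annual discount rate for QALYs (>= 0)"),
    transitions = list(
      from = "origin state (never 'dead')",
      to = "destination state, or 'in_episode' for a sub-model-resolved relapse",
      family = "'exponential', 'weibull' or 'gompertz'",
      rate = "exponential/gompertz rate (1/years)",
      shape = "weibull or gompertz shape",
      scale = "weibull scale (years)",
      coefs = "named covariate coefficients (log-hazard scale; weibull: log-scale/AFT)",
      se = "named PSA standard errors (log_rate, log_scale, log_shape, coefficient names)"))
}

#' Modify a single parameter by path
#'
#' Addresses one value inside a [parameter_set()] with a dotted path such
#' as `"effect.duration"`, `"intervention.n_sessions"`,
#' `"discount.rate_costs"`, `"utilities.values.out_of_episode"` or
#' `"transitions.relapse.rate"`. The special path `"utilities"` replaces
#' the whole [utility_set()]. Used by the tornado and scenario runners;
#' the modified set is re-validated.
#'
#' @param params a [parameter_set()].
#' @param path dotted path string (must address an existing field).
#' @param value replacement value.
#' @return the modified, validated `parameter_set`.
#' @examples
#' p <- set_parameter(default_parameters(), "effect.duration", 5)
#' @export
set_parameter <- function(params, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (identical(parts, "utilities")) {
    stopifnot(inherits(value, "utility_set"))
    params$utilities <- value
    return(validate_parameters(params))
  }
  cur <- params
  for (p in parts) {
    if (!p %in% names(cur)) {
      stop(sprintf("unknown parameter path '%s' (no field '%s')", path, p),
           call. = FALSE)
    }
    cur <- cur[[p]]
  }
  params[[parts]] <- value
  validate_parameters(params)
}

# apply a named overlay (list of path = value) to a parameter set
apply_overlay <- function(params, overlay) {
  for (nm in names(overlay)) {
    params <- set_parameter(params, nm, overlay[[nm]])
  }
  params
}

#' Read and write cohort and trajectory tables
#'
#' Cohorts are CSV files with columns `patient_id, age, sex, diagnosis,
#' prior_cbtp, baseline_state, time_in_baseline_state`; trajectory sets are
#' a long-format transitions CSV (`patient_id, time, from_state, to_state`)
#' plus a per-patient table (`patient_id, baseline_state, end_time,
#' end_status`) written alongside with suffix `_patients.csv`. Times are
#' years from simulation start.
#'
#' @param cohort a cohort data frame as from [generate_cohort()].
#' @param trajectories a `trajectory_set` as from [simulate_arm()].
#' @param path CSV file path.
#' @return readers return the object; writers invisibly return `path`.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  ch <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "age", "sex", "diagnosis", "prior_cbtp",
           "baseline_state", "time_in_baseline_state")
  miss <- setdiff(req, names(ch))
  if (length(miss)) stop("cohort file lacks column(s): ",
                         paste(miss, collapse = ", "))
  ch$prior_cbtp <- as.logical(ch$prior_cbtp)
  assert_state(ch$baseline_state, alive_states(), "baseline_state")
  ch
}

patients_path <- function(path) sub("(\\.csv)?$", "_patients.csv",
                                    path, ignore.case = TRUE)

#' @rdname write_cohort
#' @export
write_trajectories <- function(trajectories, path) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  write.csv(trajectories$transitions, path, row.names = FALSE)
  write.csv(trajectories$patients, patients_path(path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_trajectories <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  pat <- read.csv(patients_path(path), stringsAsFactors = FALSE)
  new_trajectory_set(tr, pat,
                     horizon = suppressWarnings(max(pat$end_time, 0)),
                     arm = "tau")
}
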