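# Re-estimation of model components from trajectory data: sojourn spells,
# cause-specific parametric hazards (competing transitions treated as
# right-censoring), the episode-type logistic sub-model and the log-linear
# cost equations. Fitting is by maximum likelihood via flexsurv / glm / lm;
# left truncation (time already spent in the baseline state at t = 0) is
# handled through counting-process entry offsets.

#' Convert a trajectory set into a sojourn (spell) table
#'
#' One row per sojourn: the occupied state, entry and exit (or censoring)
#' time, an event indicator and, for events, the destination state
#' (competing destinations are recorded as-is; a cause-specific fit decides
#' later which count as events). When the cohort is supplied, baseline
#' left-truncation offsets (`time_in_baseline_state`) and covariate columns
#' (`age_decades` at spell entry, `sex_male`, `diagnosis_*` indicators) are
#' attached for model fitting.
#'
#' @param trajectories a `trajectory_set` (from [simulate_arm()],
#'   [generate_observed_trajectories()] or [read_trajectories()]).
#' @param cohort optional cohort data frame keyed by `patient_id`.
#' @return data frame with columns `patient_id, state, t0, t1, duration,
#'   tstart, status, destination` (+ covariates if `cohort` given).
#' @export
extract_spells <- function(trajectories, cohort = NULL) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  tr <- trajectories$transitions
  pat <- trajectories$patients
  if (any(tr$from_state == "dead")) {
    bad <- tr$patient_id[tr$from_state == "dead"][1]
    stop("transition out of the death state for patient ", bad)
  }
  o <- order(tr$patient_id, tr$time)
  tr <- tr[o, , drop = FALSE]
  if (nrow(tr) > 1) {
    same <- tr$patient_id[-1] == tr$patient_id[-nrow(tr)]
    nondec <- diff(tr$time) <= 0
    if (any(same & nondec)) {
      bad <- tr$patient_id[-1][same & nondec][1]
      stop("transition times not strictly increasing for patient ", bad)
    }
  }
  first <- !duplicated(tr$patient_id)
  t0 <- if (nrow(tr)) c(0, head(tr$time, -1)) else numeric(0)
  t0[first] <- 0
  ev <- data.frame(patient_id = tr$patient_id, state = tr$from_state,
                   t0 = t0, t1 = tr$time, status = rep(1L, nrow(tr)),
                   destination = tr$to_state, stringsAsFactors = FALSE)
  # trailing censored spell for everyone not ending in death
  last <- !duplicated(tr$patient_id, fromLast = TRUE)
  last_to <- setNames(tr$to_state[last], tr$patient_id[last])
  last_t <- setNames(tr$time[last], tr$patient_id[last])
  alive <- pat[pat$end_status != "dead", , drop = FALSE]
  key <- as.character(alive$patient_id)
  trail <- data.frame(
    patient_id = alive$patient_id,
    state = ifelse(key %in% names(last_to), last_to[key],
                   alive$baseline_state),
    t0 = ifelse(key %in% names(last_t), last_t[key], 0),
    t1 = alive$end_time, status = rep(0L, nrow(alive)),
    destination = rep(NA_character_, nrow(alive)),
    stringsAsFactors = FALSE)
  sp <- rbind(ev, trail)
  sp <- sp[order(sp$patient_id, sp$t0), , drop = FALSE]
  sp$duration <- sp$t1 - sp$t0
  sp$tstart <- 0
  if (!is.null(cohort)) {
    m <- match(sp$patient_id, cohort$patient_id)
    sp$tstart[sp$t0 == 0] <- cohort$time_in_baseline_state[m][sp$t0 == 0]
    sp$age_decades <- (cohort$age[m] + sp$t0) / 10
    sp$sex_male <- as.numeric(cohort$sex[m] == "male")
    for (d in unique(cohort$diagnosis)) {
      sp[[paste0("diagnosis_", d)]] <- as.numeric(cohort$diagnosis[m] == d)
    }
  }
  rownames(sp) <- NULL
  sp
}

flexsurv_dist <- function(family) {
  switch(family, exponential = "exp", weibull = "weibull",
         gompertz = "gompertz",
         stop("unsupported family: ", family))
}

#' Fit one cause-specific parametric sojourn distribution
#'
#' Maximum-likelihood fit of the `from_state` sojourn hazard towards
#' `to_state`, treating exits to competing destinations (and censoring) as
#' right-censored, via [flexsurv::flexsurvreg()]. `to_state =
#' "in_episode"` pools relapses into either episode state (the pooled
#' relapse hazard of the episode-type-model formulation). Covariates enter
#' on the log-rate scale for exponential/Gompertz (proportional hazards)
#' and on the log-scale (accelerated failure) for Weibull; the report also
#' carries the proportional-hazards equivalents `coefs_ph = -shape * b`
#' for Weibull so the scale a coefficient lives on is never ambiguous.
#' Spells with `tstart > 0` (time already in state at follow-up start)
#' enter as left-truncated.
#'
#' @param spells spell table from [extract_spells()] (with covariate
#'   columns when `covariates` are requested).
#' @param from_state occupied state whose sojourn is modelled.
#' @param to_state event destination (a state label, or `"in_episode"`).
#' @param family `"exponential"`, `"weibull"` or `"gompertz"`.
#' @param covariates character vector of covariate column names.
#' @return an object of class `fit_report`: the fitted [transition_spec()]
#'   (`$spec`), `$loglik`, `$se`, `$coefs_ph` (Weibull only),
#'   `$converged`, `$n_events`, `$n_censored`.
#' @export
fit_sojourn <- function(spells, from_state, to_state,
                        family = c("exponential", "weibull", "gompertz"),
                        covariates = character(0)) {
  family <- match.arg(family)
  sub <- spells[spells$state == from_state, , drop = FALSE]
  if (!nrow(sub)) stop("no spells in state ", from_state)
  to_states <- if (to_state == IN_EPISODE) episode_states() else to_state
  sub$.status <- as.integer(!is.na(sub$destination) &
                              sub$destination %in% to_states)
  n_events <- sum(sub$.status)
  if (n_events < 2) {
    stop(sprintf("fewer than 2 events for transition %s -> %s",
                 from_state, to_state))
  }
  miss <- setdiff(covariates, names(sub))
  if (length(miss)) stop("spell table lacks covariate column(s): ",
                         paste(miss, collapse = ", "))
  truncated <- any(sub$tstart > 0)
  lhs <- if (truncated) {
    "survival::Surv(tstart, tstart + duration, .status)"
  } else {
    "survival::Surv(duration, .status)"
  }
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f <- as.formula(paste(lhs, "~", rhs))
  fit <- tryCatch(
    flexsurv::flexsurvreg(f, data = sub, dist = flexsurv_dist(family)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(spec = NULL, loglik = NA_real_, se = NULL,
                          converged = FALSE, message = conditionMessage(fit),
                          n_events = n_events,
                          n_censored = nrow(sub) - n_events),
                     class = "fit_report"))
  }
  est <- setNames(fit$res[, "est"], rownames(fit$res))
  ses <- setNames(fit$res[, "se"], rownames(fit$res))
  cf <- est[covariates]
  spec <- switch(family,
    exponential = transition_spec(from_state, to_state, family,
                                  rate = est[["rate"]], coefs = cf),
    weibull = transition_spec(from_state, to_state, family,
                              shape = est[["shape"]], scale = est[["scale"]],
                              coefs = cf),
    gompertz = transition_spec(from_state, to_state, family,
                               shape = est[["shape"]], rate = est[["rate"]],
                               coefs = cf))
  structure(list(
    spec = spec,
    loglik = fit$loglik,
    se = ses,
    coefs_ph = if (family == "weibull" && length(covariates)) {
      -est[["shape"]] * cf
    },
    converged = is.null(fit$opt$convergence) || fit$opt$convergence == 0,
    n_events = n_events,
    n_censored = nrow(sub) - n_events),
    class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  if (is.null(x$spec)) {
    cat("Sojourn fit: did not converge (", x$message %||% "", ")\n")
    return(invisible(x))
  }
  s <- x$spec
  pars <- intersect(c("rate", "shape", "scale"), names(s))
  cat(sprintf("Sojourn fit %s -> %s (%s): %s; loglik %.2f; %d events, %d censored%s\n",
              s$from, s$to, s$family,
              paste(sprintf("%s = %.4g", pars, unlist(s[pars])),
                    collapse = ", "),
              x$loglik, x$n_events, x$n_censored,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Fit the episode-type logistic sub-model
#'
#' Logistic maximum-likelihood fit of Pr(episode includes inpatient care)
#' over all in-episode spells. Quasi-complete separation is detected (via
#' the glm fitted-probability warning or runaway coefficients) and
#' reported with a warning rather than an error.
#'
#' @param spells spell table from [extract_spells()].
#' @param covariates character vector of covariate column names.
#' @return list of class `episode_type_fit` with the fitted
#'   [episode_type_model()] (`$model`), `$se`, `$separation`, `$n`,
#'   `$loglik`.
#' @export
fit_episode_type <- function(spells, covariates = character(0)) {
  sub <- spells[spells$state %in% episode_states(), , drop = FALSE]
  if (!nrow(sub)) stop("no in-episode spells")
  sub$.y <- as.integer(sub$state == "episode_inpatient")
  if (length(unique(sub$.y)) < 2) {
    stop("single-class data: every episode has the same type")
  }
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(as.formula(paste(".y ~", rhs)), data = sub, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (any(abs(coef(fit)) > 15)) separation <- TRUE
  if (separation) {
    warning("possible (quasi-)separation in the episode-type fit")
  }
  cf <- coef(fit)
  structure(list(
    model = episode_type_model(intercept = cf[["(Intercept)"]],
                               coefs = cf[setdiff(names(cf), "(Intercept)")]),
    se = sqrt(diag(vcov(fit))),
    separation = separation,
    n = nrow(sub),
    loglik = as.numeric(logLik(fit))),
    class = "episode_type_fit")
}

#' Fit log-linear cost equations from cost records
#'
#' Regresses the log annualised cost rate (`cost / exposure`) on state
#' indicators and covariates, so predicted cost rates are positive by
#' construction. States absent from the records get no intercept;
#' [predict_cost_rate()] raises for them.
#'
#' @param cost_records data frame with columns `patient_id, state,
#'   exposure, cost` (+ covariate columns); `exposure` in years, > 0.
#' @param covariates character vector of covariate column names
#'   (`sojourn_years` may be included and is taken from `exposure`).
#' @return a [cost_equation()] (possibly with partial intercepts) with an
#'   attached `fit` attribute carrying `se`, `sigma` and `n`.
#' @export
fit_cost_equation <- function(cost_records, covariates = character(0)) {
  if (any(cost_records$exposure <= 0)) {
    stop("non-positive exposure time in cost records")
  }
  cr <- cost_records
  assert_state(cr$state, alive_states())
  cr$.lograte <- log(cr$cost / cr$exposure)
  cr$state <- factor(cr$state, levels = intersect(alive_states(),
                                                  unique(cr$state)))
  if ("sojourn_years" %in% covariates && !"sojourn_years" %in% names(cr)) {
    cr$sojourn_years <- cr$exposure
  }
  single <- nlevels(cr$state) == 1
  rhs <- paste(c(if (single) "1" else c("0", "state"), covariates),
               collapse = " + ")
  fit <- lm(as.formula(paste(".lograte ~", rhs)), data = cr)
  cf <- coef(fit)
  state_rows <- if (single) match("(Intercept)", names(cf)) else
    grep("^state", names(cf))
  intercepts <- setNames(cf[state_rows],
                         if (single) levels(cr$state) else
                           sub("^state", "", names(cf)[state_rows]))
  eq <- structure(list(intercepts = intercepts,
                       coefs = cf[setdiff(seq_along(cf), state_rows)],
                       se = sqrt(diag(vcov(fit)))),
                  class = "cost_equation")
  attr(eq, "fit") <- list(sigma = summary(fit)$sigma, n = nrow(cr))
  eq
}

#' Predict an annualised cost rate for one state occupancy
#'
#' @param cost_eq a [cost_equation()].
#' @param state occupied state.
#' @param age,sex_male,diagnosis patient covariates (age in years at
#'   sojourn entry).
#' @param sojourn_years modelled sojourn length (used only when the
#'   equation has a `sojourn_years` coefficient).
#' @return cost rate in EUR/year (0 for the death state).
#' @export
predict_cost_rate <- function(cost_eq, state, age = 0, sex_male = 0,
                              diagnosis = NULL, sojourn_years = 0) {
  if (state == "dead") return(0)
  if (!state %in% names(cost_eq$intercepts)) {
    stop("cost equation has no intercept for state ", state)
  }
  lp <- cost_eq$intercepts[[state]]
  cf <- cost_eq$coefs
  if (length(cf)) {
    di <- if (is.null(diagnosis)) list() else diag_indicators(diagnosis)
    for (nm in names(cf)) {
      lp <- lp + cf[[nm]] * switch(nm,
        age_decades = age / 10,
        sex_male = sex_male,
        sojourn_years = sojourn_years,
        di[[nm]] %||% 0)
    }
  }
  exp(lp)
}

#' Generate synthetic per-spell cost records
#'
#' Turns the alive-state spells of a trajectory set into cost records with
#' multiplicative lognormal noise around the cost-equation rate, for
#' testing cost-equation recovery: `cost = exposure * exp(lp + e)`,
#' `e ~ N(0, noise_sdlog^2)`.
#'
#' @param trajectories a `trajectory_set`.
#' @param cohort the matching cohort (for covariates).
#' @param cost_eq the generating [cost_equation()].
#' @param noise_sdlog lognormal noise SD (0 for noiseless records).
#' @param seed integer seed.
#' @return a cost-record data frame suitable for [fit_cost_equation()].
#' @export
generate_cost_records <- function(trajectories, cohort, cost_eq,
                                  noise_sdlog = 0.5, seed = 1) {
  sp <- extract_spells(trajectories, cohort)
  sp <- sp[sp$state %in% alive_states() & sp$duration > 0, , drop = FALSE]
  lp <- cost_lp(cost_eq, sp)
  with_seed(as.integer(seed), {
    noise <- if (noise_sdlog > 0) rnorm(nrow(sp), 0, noise_sdlog) else 0
    data.frame(patient_id = sp$patient_id, state = sp$state,
               exposure = sp$duration,
               cost = sp$duration * exp(lp + noise),
               age_decades = sp$age_decades, sex_male = sp$sex_male,
               sp[grep("^diagnosis_", names(sp))],
               stringsAsFactors = FALSE)
  })
}

# vectorised cost-equation linear predictor over a spell table
cost_lp <- function(cost_eq, spells) {
  miss <- setdiff(unique(spells$state), names(cost_eq$intercepts))
  if (length(miss)) stop("cost equation has no intercept for state ",
                         paste(miss, collapse = ", "))
  lp <- unname(cost_eq$intercepts[spells$state])
  cf <- cost_eq$coefs
  for (nm in names(cf)) {
    x <- switch(nm,
      age_decades = spells$age_decades,
      sex_male = spells$sex_male,
      sojourn_years = spells$duration,
      spells[[nm]] %||% 0)
    lp <- lp + cf[[nm]] * x
  }
  lp
}

#' Re-estimate a full parameter set from observed trajectories
#'
#' Fits every transition of the state graph (cause-specifically) plus the
#' episode-type sub-model from a trajectory set, and returns a copy of
#' `base_parameters` with the fitted values plugged in -- the estimation
#' analogue of building the model from registry follow-up, and the second
#' half of the parameter-recovery loop (generate with known truth, refit,
#' compare).
#'
#' @param trajectories a `trajectory_set`.
#' @param cohort the matching cohort.
#' @param base_parameters a [parameter_set()] providing the graph, the
#'   families to fit, and the non-estimated components (utilities, costs,
#'   effect, discounting).
#' @param covariates covariate names passed to every fit.
#' @return list with `parameters` (the re-estimated [parameter_set()]),
#'   `fits` (named [fit_sojourn()] reports) and `episode_type_fit`.
#' @export
fit_model <- function(trajectories, cohort, base_parameters,
                      covariates = character(0)) {
  validate_parameters(base_parameters)
  spells <- extract_spells(trajectories, cohort)
  fits <- list()
  params <- base_parameters
  for (nm in names(base_parameters$transitions)) {
    sp <- base_parameters$transitions[[nm]]
    rep <- fit_sojourn(spells, sp$from, sp$to, sp$family, covariates)
    fits[[nm]] <- rep
    if (!is.null(rep$spec)) {
      rep$spec$se <- sp$se # keep the PSA priors of the base set
      params$transitions[[nm]] <- rep$spec
    }
  }
  et_fit <- NULL
  if (params$relapse_mode == "episode_type_model") {
    et_fit <- fit_episode_type(spells, covariates)
    et_fit$model$se <- base_parameters$episode_type$se
    params$episode_type <- et_fit$model
  }
  list(parameters = validate_parameters(params), fits = fits,
       episode_type_fit = et_fit)
}
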