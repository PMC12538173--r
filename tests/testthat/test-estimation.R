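# Spell bookkeeping and maximum-likelihood recovery of transition,
# episode-type and cost parameters. Oracles are closed-form MLEs or an
# independent optimiser on the hand-written log-likelihood, never the
# fitting routine under test.

make_ts <- function(transitions, patients) {
  relapsim:::new_trajectory_set(transitions, patients, horizon = 10,
                                arm = "tau")
}

test_that("spell extraction does the direct bookkeeping", {
  tr <- data.frame(patient_id = 1L, time = c(1, 1.5),
                   from_state = c("out_of_episode", "episode_outpatient"),
                   to_state = c("episode_outpatient", "out_of_episode"),
                   stringsAsFactors = FALSE)
  pat <- data.frame(patient_id = 1L, baseline_state = "out_of_episode",
                    end_time = 10, end_status = "censored",
                    stringsAsFactors = FALSE)
  sp <- extract_spells(make_ts(tr, pat))
  expect_equal(nrow(sp), 3)
  expect_equal(sp$duration, c(1, 0.5, 8.5))
  expect_equal(sp$status, c(1L, 1L, 0L))
  expect_equal(sp$state, c("out_of_episode", "episode_outpatient",
                           "out_of_episode"))
  expect_equal(sp$destination[1:2], c("episode_outpatient", "out_of_episode"))
  expect_true(is.na(sp$destination[3]))

  # no transitions: a single censored spell of length 10
  sp0 <- extract_spells(make_ts(tr[0, ], pat))
  expect_equal(nrow(sp0), 1)
  expect_equal(sp0$duration, 10)
  expect_equal(sp0$status, 0L)

  # death at t = 2: event spell with destination dead, nothing after
  trd <- data.frame(patient_id = 1L, time = 2,
                    from_state = "out_of_episode", to_state = "dead",
                    stringsAsFactors = FALSE)
  patd <- data.frame(patient_id = 1L, baseline_state = "out_of_episode",
                     end_time = 2, end_status = "dead",
                     stringsAsFactors = FALSE)
  spd <- extract_spells(make_ts(trd, patd))
  expect_equal(nrow(spd), 1)
  expect_equal(spd$destination, "dead")

  # out-of-order times are a data error naming the patient
  bad <- data.frame(patient_id = c(7L, 7L), time = c(2, 2),
                    from_state = c("out_of_episode", "episode_outpatient"),
                    to_state = c("episode_outpatient", "out_of_episode"),
                    stringsAsFactors = FALSE)
  expect_error(extract_spells(make_ts(bad, pat)), "patient 7")
})

test_that("exponential sojourn fit recovers the closed-form MLE rate", {
  p <- test_params(relapse = 0.5, remission_out = 2, remission_in = 2)
  ch <- flat_cohort(3000)
  ts <- generate_observed_trajectories(ch, p, horizon = 10, seed = 41)
  sp <- extract_spells(ts, ch)
  fit <- fit_sojourn(sp, "out_of_episode", "in_episode", "exponential")
  # closed-form cause-specific MLE: events / person-time at risk
  sub <- sp[sp$state == "out_of_episode", ]
  mle <- sum(sub$status) / sum(sub$duration)
  expect_equal(fit$spec$rate, mle, tolerance = 1e-4)
  se <- mle / sqrt(sum(sub$status))
  expect_lt(abs(fit$spec$rate - 0.5), 3 * se)
  expect_true(fit$converged)
  expect_equal(fit$n_events + fit$n_censored, nrow(sub))
})

test_that("Weibull sojourn fit matches an independent optimiser and recovers the truth", {
  set.seed(55)
  n <- 5000
  shape <- 1.3
  scale <- 2.0
  t_true <- rweibull(n, shape, scale)
  cens <- pmin(t_true, 4) # ~20% administrative censoring at 4 y
  status <- as.integer(t_true <= 4)
  sp <- data.frame(patient_id = seq_len(n), state = "episode_inpatient",
                   t0 = 0, t1 = cens, duration = cens, tstart = 0,
                   status = status,
                   destination = ifelse(status == 1, "out_of_episode", NA),
                   stringsAsFactors = FALSE)
  fit <- fit_sojourn(sp, "episode_inpatient", "out_of_episode", "weibull")
  # independent oracle: generic optimiser on the written-out log-likelihood
  nll <- function(par) {
    a <- exp(par[1]); s <- exp(par[2])
    -sum(status * (log(a) - log(s) + (a - 1) * (log(cens) - log(s))) -
           (cens / s)^a)
  }
  o <- optim(c(0, 0), nll, method = "BFGS")
  expect_equal(fit$spec$shape, exp(o$par[1]), tolerance = 1e-3)
  expect_equal(fit$spec$scale, exp(o$par[2]), tolerance = 1e-3)
  expect_lt(abs(fit$spec$shape - shape), 0.1 * shape)
  expect_lt(abs(fit$spec$scale - scale), 0.1 * scale)
})

test_that("degenerate sojourn data are refused", {
  sp <- data.frame(patient_id = 1:5, state = "out_of_episode", t0 = 0,
                   t1 = 1, duration = 1, tstart = 0, status = 0L,
                   destination = NA_character_, stringsAsFactors = FALSE)
  expect_error(fit_sojourn(sp, "out_of_episode", "in_episode",
                           "exponential"), "fewer than 2 events")
})

test_that("episode-type logistic fit recovers known coefficients", {
  set.seed(66)
  n <- 10000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0 + 1.0 * x))
  sp <- data.frame(patient_id = seq_len(n),
                   state = ifelse(y == 1, "episode_inpatient",
                                  "episode_outpatient"),
                   cov_x = x, stringsAsFactors = FALSE)
  fit <- fit_episode_type(sp, covariates = "cov_x")
  expect_lt(abs(fit$model$intercept - 0), 3 * fit$se[["(Intercept)"]])
  expect_lt(abs(fit$model$coefs[["cov_x"]] - 1.0), 3 * fit$se[["cov_x"]])
  expect_false(fit$separation)
})

test_that("covariate-free episode-type fit returns the logit of the proportion", {
  set.seed(67)
  n <- 8000
  y <- rbinom(n, 1, 0.3)
  sp <- data.frame(patient_id = seq_len(n),
                   state = ifelse(y == 1, "episode_inpatient",
                                  "episode_outpatient"),
                   stringsAsFactors = FALSE)
  fit <- fit_episode_type(sp)
  # closed form: intercept = logit(sample proportion), truth logit(0.3)
  expect_equal(fit$model$intercept, qlogis(mean(y)), tolerance = 1e-6)
  expect_lt(abs(fit$model$intercept - qlogis(0.3)),
            3 * fit$se[["(Intercept)"]])
})

test_that("separated and single-class episode data are flagged", {
  sp <- data.frame(patient_id = 1:20,
                   state = rep(c("episode_inpatient", "episode_outpatient"),
                               each = 10),
                   cov_x = c(rep(1, 10), rep(0, 10)),
                   stringsAsFactors = FALSE)
  expect_warning(fit <- fit_episode_type(sp, covariates = "cov_x"),
                 "separation")
  expect_true(fit$separation)
  one <- sp[sp$state == "episode_inpatient", ]
  expect_error(fit_episode_type(one), "single-class")
})

test_that("cost-equation fit recovers state intercepts, exactly so without noise", {
  p <- test_params()
  ch <- generate_cohort(cohort_config(n_patients = 2000, seed = 9),
                        parameters = p)
  ts <- generate_observed_trajectories(ch, p, horizon = 10, seed = 10)
  rec <- generate_cost_records(ts, ch, p$costs, noise_sdlog = 0.5, seed = 2)
  fit <- fit_cost_equation(rec)
  for (s in alive_states()) {
    truth <- p$costs$intercepts[[s]]
    se <- fit$se[[paste0("state", s)]]
    expect_lt(abs(fit$intercepts[[s]] - truth), 3 * se)
  }
  # log-scale regression oracle: per-state mean of log rates
  oracle <- tapply(log(rec$cost / rec$exposure), rec$state, mean)
  expect_equal(unname(fit$intercepts[names(oracle)]), as.numeric(oracle),
               tolerance = 1e-8)
  # noiseless records recover the truth to optimiser tolerance
  rec0 <- generate_cost_records(ts, ch, p$costs, noise_sdlog = 0, seed = 2)
  fit0 <- fit_cost_equation(rec0)
  expect_equal(unname(fit0$intercepts[alive_states()]),
               unname(p$costs$intercepts[alive_states()]), tolerance = 1e-8)
  expect_error(fit_cost_equation(transform(rec, exposure = 0)),
               "exposure")
})

test_that("a single-state cost fit reports other states as absent and refuses to predict them", {
  rec <- data.frame(patient_id = 1:50, state = "out_of_episode",
                    exposure = 1, cost = exp(rnorm(50, log(3000), 0.2)),
                    stringsAsFactors = FALSE)
  fit <- fit_cost_equation(rec)
  expect_named(fit$intercepts, "out_of_episode")
  expect_error(predict_cost_rate(fit, "episode_inpatient"),
               "no intercept")
  expect_gt(predict_cost_rate(fit, "out_of_episode"), 0)
})

test_that("end-to-end parameter recovery: generate, refit, compare within 3 SE", {
  p <- test_params(relapse = 0.5, remission_out = 2.0, remission_in = 1.5,
                   death_rate = 0.02, p_inpatient = 0.35)
  ch <- generate_cohort(cohort_config(n_patients = 5000, seed = 19),
                        parameters = p)
  ts <- generate_observed_trajectories(ch, p, horizon = 10, seed = 20)
  res <- fit_model(ts, ch, p)
  for (nm in names(p$transitions)) {
    truth <- p$transitions[[nm]]$rate
    fit <- res$fits[[nm]]
    expect_true(fit$converged)
    se <- fit$se[["rate"]]
    expect_lt(abs(fit$spec$rate - truth), 3 * max(se, 1e-8))
  }
  et <- res$episode_type_fit
  expect_lt(abs(et$model$intercept - qlogis(0.35)),
            3 * et$se[["(Intercept)"]])
  # the re-estimated set plugs straight back into the engine
  ts2 <- simulate_arm(ch[1:20, ], res$parameters, "tau", master_seed = 1)
  expect_s3_class(ts2, "trajectory_set")
})

test_that("cause-specific likelihood factorises: separate fits equal the closed-form joint MLE", {
  # with exponential competing risks the joint likelihood factorises into
  # per-destination terms: each MLE is events_d / total person-time
  p <- test_params(relapse = 0.8, remission_out = 2, remission_in = 2,
                   death_rate = 0.1)
  ch <- flat_cohort(2000)
  ts <- generate_observed_trajectories(ch, p, horizon = 10, seed = 43)
  sp <- extract_spells(ts, ch)
  sub <- sp[sp$state == "out_of_episode", ]
  persontime <- sum(sub$duration)
  for (dest in list(c("in_episode", "episode_outpatient",
                      "episode_inpatient"), "dead")) {
    fit <- fit_sojourn(sp, "out_of_episode", dest[1], "exponential")
    n_ev <- sum(sub$destination %in%
                  (if (dest[1] == "in_episode") episode_states() else dest),
                na.rm = TRUE)
    expect_equal(fit$spec$rate, n_ev / persontime, tolerance = 1e-4)
  }
})
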