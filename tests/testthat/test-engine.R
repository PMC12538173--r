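# Simulation engine: hazard multiplier, cumulative-hazard inversion,
# CRN pairing, and distributional correctness of the event loop.

test_that("hazard multiplier applies RR only in-arm, on-target and in-window", {
  eff <- treatment_effect(0.79, 0.60, 1.04, duration = 2)
  relapse <- transition_spec("out_of_episode", "in_episode", "exponential",
                             rate = 0.4)
  remission <- transition_spec("episode_outpatient", "out_of_episode",
                               "exponential", rate = 2)
  expect_equal(hazard_multiplier("tau", eff, relapse, 1.0), 1)
  expect_equal(hazard_multiplier("tau_cbtp", eff, relapse, 0), 0.79)
  expect_equal(hazard_multiplier("tau_cbtp", eff, relapse, 1.0), 0.79)
  expect_equal(hazard_multiplier("tau_cbtp", eff, relapse, 1.999), 0.79)
  # the window is [0, duration): the boundary itself is untreated
  expect_equal(hazard_multiplier("tau_cbtp", eff, relapse, 2.0), 1)
  expect_equal(hazard_multiplier("tau_cbtp", eff, remission, 1.0), 1)
})

test_that("exponential inversion matches the closed form and halving the rate doubles the time", {
  sp <- transition_spec("out_of_episode", "in_episode", "exponential",
                        rate = 0.5)
  u <- exp(-1)
  expect_equal(sample_transition_time(sp, u = u), 2.0)
  expect_equal(sample_transition_time(sp, multiplier = list(t = 0, m = 0.5),
                                      u = u), 4.0)
  # monotone in the multiplier, pathwise in U
  for (uu in c(0.05, 0.3, 0.9)) {
    t1 <- sample_transition_time(sp, u = uu)
    t2 <- sample_transition_time(sp, multiplier = list(t = c(0, 2),
                                                       m = c(0.79, 1)),
                                 u = uu)
    expect_gte(t2, t1)
  }
  expect_error(sample_transition_time(sp, multiplier = list(t = 0, m = 0),
                                      u = 0.5), "positive")
})

test_that("Weibull inversion reproduces the analytic distribution (KS test)", {
  sp <- transition_spec("out_of_episode", "in_episode", "weibull",
                        shape = 2, scale = 1)
  us <- relapsim:::with_seed(404, runif(10000))
  draws <- vapply(us, function(u) sample_transition_time(sp, u = u), 0)
  ks <- suppressWarnings(ks.test(draws, pweibull, shape = 2, scale = 1))
  # below the 1% critical value
  expect_gt(ks$p.value, 0.01)
})

test_that("piecewise inversion satisfies the defining equation H(t) = -log(U) for every family", {
  specs <- list(
    transition_spec("out_of_episode", "in_episode", "exponential",
                    rate = 0.7, coefs = c(age_decades = 0.05)),
    transition_spec("episode_inpatient", "out_of_episode", "weibull",
                    shape = 1.4, scale = 1.5),
    transition_spec("out_of_episode", "dead", "gompertz",
                    shape = 0.08, rate = 0.01),
    transition_spec("out_of_episode", "dead", "gompertz",
                    shape = -0.3, rate = 0.4))
  # hazard written out independently of the package's closed forms
  hazard_oracle <- function(spec, u, lp) {
    switch(spec$family,
      exponential = rep_len(spec$rate * exp(lp), length(u)),
      weibull = {
        sc <- spec$scale * exp(lp)
        (spec$shape / sc) * (u / sc)^(spec$shape - 1)
      },
      gompertz = spec$rate * exp(lp) * exp(spec$shape * u))
  }
  set.seed(77)
  for (spec in specs) {
    for (rep in 1:25) {
      lp <- runif(1, -0.3, 0.3)
      entry <- runif(1, 0, 3)
      w <- sample(c(0, runif(1, 0, 2)), 1)
      mult <- list(t = c(0, entry + runif(1, 0.1, 2)),
                   m = runif(2, 0.4, 1.5))
      u <- runif(1, 0.02, 0.98)
      tau <- sample_transition_time(spec, lp = lp, multiplier = mult,
                                    entry_time = entry, time_in_state = w,
                                    u = u)
      # independent quadrature oracle, integrating each smooth piece of
      # the multiplied hazard separately
      piecewise_H <- function(upto) {
        brk <- mult$t[2] - entry # piece boundary in time-since-entry
        cuts <- sort(unique(pmin(pmax(c(0, brk, upto), 0), upto)))
        total <- 0
        for (k in seq_len(length(cuts) - 1)) {
          mid <- (cuts[k] + cuts[k + 1]) / 2
          m <- if (entry + mid < mult$t[2]) mult$m[1] else mult$m[2]
          total <- total + m * integrate(function(s) {
            hazard_oracle(spec, w + s, lp)
          }, cuts[k], cuts[k + 1], rel.tol = 1e-11)$value
        }
        total
      }
      if (!is.finite(tau)) {
        # bounded total hazard: the target must exceed the total mass
        expect_lt(piecewise_H(200), -log(u))
      } else {
        expect_equal(piecewise_H(tau - entry), -log(u), tolerance = 1e-7)
      }
    }
  }
})

test_that("with a null effect, CRN pairing makes the two arms identical pathwise", {
  p <- test_params(rr = 1, ci_low = 1, ci_high = 1, death_rate = 0.02)
  ch <- flat_cohort(100)
  a <- simulate_arm(ch, p, "tau", master_seed = 9)
  b <- simulate_arm(ch, p, "tau_cbtp", master_seed = 9)
  expect_identical(a$transitions, b$transitions)
  expect_identical(a$patients, b$patients)
})

test_that("occupancy matches the two-state Markov stationary fraction 1/3", {
  # relapse 1/y, remission 2/y, no death: long-run in-episode time 1/3
  p <- test_params(relapse = 1, remission_out = 2, remission_in = 2,
                   horizon = 50)
  ch <- flat_cohort(2000)
  ts <- simulate_arm(ch, p, "tau", master_seed = 31, horizon = 50)
  frac <- in_episode_time(ts, ch) / 50
  se <- sd(frac) / sqrt(length(frac))
  # exact finite-horizon mean occupancy starting out-of-episode:
  # (1/T) int_0^T p_ep(t) dt with p_ep(t) = (1/3)(1 - exp(-3t))
  expected <- 1 / 3 - (1 - exp(-3 * 50)) / (9 * 50)
  expect_lt(abs(mean(frac) - expected), 3 * se)
  expect_lt(abs(mean(frac) - 1 / 3), 4 * se)
})

test_that("results are invariant to patient processing order", {
  p <- test_params(death_rate = 0.02)
  ch <- flat_cohort(50)
  a <- simulate_arm(ch, p, "tau", master_seed = 4)
  perm <- sample(nrow(ch))
  b <- simulate_arm(ch[perm, ], p, "tau", master_seed = 4)
  bo <- b$patients[order(b$patients$patient_id), ]
  rownames(bo) <- NULL
  expect_equal(bo, a$patients)
  bt <- b$transitions[order(b$transitions$patient_id, b$transitions$time), ]
  rownames(bt) <- NULL
  at <- a$transitions[order(a$transitions$patient_id, a$transitions$time), ]
  rownames(at) <- NULL
  expect_equal(bt, at)
})

test_that("distinct outer indices give independent replications", {
  p <- test_params()
  ch <- flat_cohort(2000)
  counts <- function(ts) {
    tab <- table(factor(ts$transitions$patient_id[
      ts$transitions$to_state %in% episode_states()],
      levels = ch$patient_id))
    as.numeric(tab)
  }
  a <- counts(simulate_arm(ch, p, "tau", outer_index = 1, master_seed = 6))
  b <- counts(simulate_arm(ch, p, "tau", outer_index = 2, master_seed = 6))
  r <- cor(a, b)
  expect_lt(abs(r), 3 / sqrt(length(a)))
})

test_that("simulating a long horizon and truncating reproduces the short horizon pathwise", {
  p <- test_params(death_rate = 0.02)
  ch <- flat_cohort(80)
  s10 <- simulate_arm(ch, p, "tau", master_seed = 13, horizon = 10)
  s20 <- simulate_arm(ch, p, "tau", master_seed = 13, horizon = 20)
  t20 <- s20$transitions[s20$transitions$time <= 10, ]
  rownames(t20) <- NULL
  expect_equal(s10$transitions, t20)
})

test_that("person-time is conserved: spell durations add up to death or censoring time", {
  p <- test_params(death_rate = 0.05)
  ch <- generate_cohort(cohort_config(n_patients = 300, seed = 17),
                        parameters = p)
  ts <- simulate_arm(ch, p, "tau", master_seed = 8)
  sp <- extract_spells(ts, ch)
  tot <- tapply(sp$duration, factor(sp$patient_id, ch$patient_id), sum,
                default = 0)
  expect_equal(as.numeric(tot), ts$patients$end_time, tolerance = 1e-10)
  # all event times within the horizon
  expect_true(all(ts$transitions$time <= 10))
})

test_that("overwhelming mortality absorbs everyone almost immediately", {
  p <- test_params(death_rate = 1000)
  ch <- flat_cohort(50)
  ts <- simulate_arm(ch, p, "tau", master_seed = 2)
  expect_true(all(ts$patients$end_status == "dead"))
  expect_lt(sum(ts$patients$end_time), 1)
})

test_that("under CRN and RR < 1 on all relapses, in-episode time is never larger in the intervention arm", {
  p <- test_params(rr = 0.79, death_rate = 0.02)
  ch <- generate_cohort(cohort_config(n_patients = 500, seed = 23),
                        parameters = p)
  tau <- simulate_arm(ch, p, "tau", master_seed = 12)
  cbtp <- simulate_arm(ch, p, "tau_cbtp", master_seed = 12)
  expect_true(all(in_episode_time(cbtp, ch) <=
                    in_episode_time(tau, ch) + 1e-12))
})

test_that("a state without outgoing transitions is rejected", {
  p <- test_params()
  p$transitions$remission_inpatient <- NULL
  expect_error(simulate_arm(flat_cohort(2), p, "tau"),
               "remission transition")
})
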