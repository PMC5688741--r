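test_that("with no covariates the Breslow baseline is the Nelson-Aalen d/n", {
  cfg <- default_scenario(n_subjects = 150)
  eh <- simulate_cohort(cfg, seed = 21)
  rs <- build_risk_sets(eh)
  fit <- fit_multistate_cox(eh, covariates = character())
  for (lab in names(fit$transitions)) {
    bh <- fit$transitions[[lab]]$basehaz
    ev <- rs$events[rs$events$trans == lab, ]
    expect_equal(bh$time, ev$time)
    expect_equal(bh$increment, ev$d / ev$n)
  }
})

test_that("baseline hazard arithmetic and right-continuity", {
  # d/n sequence (1/10, 1/8) -> cumulative 0.1 then 0.225
  sp <- surv_space(60)
  df <- data.frame(subject_id = 1:10, entry_age = 55,
                   exit_age = c(56, rep(56.5, 1), rep(58, 8)),
                   from_state = "W",
                   to_state = c("D", NA, "D", rep(NA, 7)))
  eh <- as_event_history(df, sp)
  fit <- fit_multistate_cox(eh)
  bh <- baseline_cumulative_hazard(fit, "W->D")
  expect_equal(bh$cumulative, c(0.1, 0.225))
  # evaluation between jumps equals the value at the previous jump
  expect_equal(hazard_at(bh, c(55.5, 56, 57, 58, 59)),
               c(0, 0.1, 0.1, 0.225, 0.225))
  expect_error(baseline_cumulative_hazard(fit, "S->W"), "unknown transition")
})

test_that("a transition with no events yields the constant-zero hazard", {
  sp <- illness_death_space()
  df <- data.frame(subject_id = 1:5, entry_age = 55, exit_age = 56:60,
                   from_state = "W",
                   to_state = c("D", "D", NA, NA, NA))
  fit <- fit_multistate_cox(as_event_history(df, sp))
  bh <- baseline_cumulative_hazard(fit, "S->W")
  expect_equal(length(bh$time), 0L)
  expect_equal(hazard_at(bh, c(55, 59)), c(0, 0))
})

test_that("a binary covariate's hazard ratio is recovered on simulated data", {
  # single transition, true HR 2, constant baseline 0.3/yr, 3-yr window
  sp <- surv_space(58)
  cfg <- sim_config(2000,
                    transitions = list("W->D" = list(rates = 0.3,
                                                     beta = c(g = log(2)))),
                    covariates = list(g = list(prevalence = 0.5)),
                    age_range = c(55, 58), space = sp)
  eh <- simulate_cohort(cfg, seed = 22)
  fit <- fit_multistate_cox(eh, covariates = "g")
  tr <- fit$transitions[["W->D"]]
  expect_lt(abs(tr$coef[["g"]] - log(2)), 3 * tr$se[["g"]])
})

test_that("stacked stratified fit equals separate per-transition fits", {
  cfg <- default_scenario(n_subjects = 400)
  eh <- simulate_cohort(cfg, seed = 23)
  fa <- fit_multistate_cox(eh, covariates = c("srh_poor", "male"),
                           method = "per_transition")
  fb <- fit_multistate_cox(eh, covariates = c("srh_poor", "male"),
                           method = "stacked")
  for (lab in names(fa$transitions)) {
    ba <- fa$transitions[[lab]]$coef
    bb <- fb$transitions[[lab]]$coef
    expect_equal(ba, bb, tolerance = 1e-8)
    expect_equal(fa$transitions[[lab]]$basehaz$cumulative,
                 fb$transitions[[lab]]$basehaz$cumulative, tolerance = 1e-8)
  }
})

test_that("rescaling all weights by a constant changes neither beta nor the baseline", {
  cfg <- default_scenario(n_subjects = 300)
  eh <- simulate_cohort(cfg, seed = 24)
  f1 <- fit_multistate_cox(eh, covariates = "srh_poor")
  f2 <- fit_multistate_cox(eh, covariates = "srh_poor",
                           weights = rep(2.5, nrow(eh)))
  for (lab in names(f1$transitions)) {
    expect_equal(f1$transitions[[lab]]$coef, f2$transitions[[lab]]$coef,
                 tolerance = 1e-6)
    expect_equal(f1$transitions[[lab]]$basehaz$increment,
                 f2$transitions[[lab]]$basehaz$increment, tolerance = 1e-8)
  }
})

test_that("small-theta gamma frailty agrees with the no-frailty fit", {
  sp <- surv_space(58)
  cfg <- sim_config(800,
                    transitions = list("W->D" = list(rates = 0.4,
                                                     beta = c(g = log(2)))),
                    covariates = list(g = list(prevalence = 0.5)),
                    age_range = c(55, 58), space = sp)
  eh <- simulate_cohort(cfg, seed = 25)
  f0 <- fit_multistate_cox(eh, covariates = "g", method = "stacked")
  f1 <- fit_multistate_cox(eh, covariates = "g", method = "stacked",
                           frailty = TRUE, frailty_theta = 1e-4)
  # with the frailty variance pinned near zero the penalized fit must
  # collapse onto the ordinary partial-likelihood estimate
  b0 <- f0$transitions[["W->D"]]$coef[["g"]]
  b1 <- f1$transitions[["W->D"]]$coef[["g"]]
  expect_lt(abs(b0 - b1), 0.01)
  # and an estimated frailty on the same data still returns a fit
  f2 <- fit_multistate_cox(eh, covariates = "g", method = "stacked",
                           frailty = TRUE)
  expect_true(is.finite(f2$transitions[["W->D"]]$coef[["g"]]))
})

test_that("proportionality diagnostics behave on identical, proportional and single strata", {
  sp <- surv_space(60)
  base <- data.frame(subject_id = 1:20, entry_age = 55,
                     exit_age = seq(55.2, 59, length.out = 20),
                     from_state = "W",
                     to_state = rep(c("D", NA), 10))
  # identical strata -> identical curves
  two <- rbind(cbind(base, g = 0),
               cbind(transform(base, subject_id = subject_id + 100), g = 1))
  pd <- proportionality_diagnostics(as_event_history(two, sp), covariate = "g")
  c0 <- pd[pd$level == "0", ]
  c1 <- pd[pd$level == "1", ]
  expect_equal(c0$cumhaz, c1$cumhaz)

  # single stratum -> one curve per transition, no ratio table
  pd1 <- proportionality_diagnostics(as_event_history(cbind(base, g = 0), sp),
                                     covariate = "g")
  expect_null(attr(pd1, "log_ratio"))

  # proportional strata with HR 2 -> late log cumulative-hazard ratio ~ log 2
  cfg <- sim_config(4000,
                    transitions = list("W->D" = list(rates = 0.3,
                                                     beta = c(g = log(2)))),
                    covariates = list(g = list(prevalence = 0.5)),
                    age_range = c(55, 60), space = sp)
  eh <- simulate_cohort(cfg, seed = 26)
  pd2 <- proportionality_diagnostics(eh, covariate = "g")
  lr <- attr(pd2, "log_ratio")
  late <- lr[lr$time > stats::quantile(lr$time, 0.6), ]
  expect_lt(abs(mean(late$log_ratio) - log(2)), 0.15)
})

test_that("the hazard-ratio summary table has the reporting shape", {
  cfg <- default_scenario(n_subjects = 400)
  eh <- simulate_cohort(cfg, seed = 27)
  tab <- summary_table(fit_multistate_cox(eh, covariates = c("srh_poor",
                                                             "male")))
  expect_named(tab, c("transition", "covariate", "HR", "lower", "upper", "p"))
  expect_true(all(tab$lower <= tab$HR & tab$HR <= tab$upper, na.rm = TRUE))
})
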