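test_that("zero intensities leave the full horizon in the starting state", {
  sp <- danish_labor_market()
  df <- data.frame(subject_id = 1:3, entry_age = 55, exit_age = 65,
                   from_state = "W", to_state = NA)
  rs <- build_risk_sets(as_event_history(df, sp))
  cv <- product_integral(nonparametric_intensities(rs), 55, 65)
  est <- expected_durations(cv, sp)
  expect_equal(est$years[est$state == "W"], 10)
  expect_equal(sum(est$years[est$state != "W"]), 0)
  # straight-line WLE curve
  curve <- wle_by_starting_age(nonparametric_intensities(rs), sp,
                               ages = 55:64)
  expect_equal(curve$E_W, 65 - curve$starting_age)
})

test_that("pure-death expectancy matches the closed form (1 - e^(-lambda T)) / lambda", {
  sp <- surv_space(2)
  cfg <- sim_config(10, transitions = list("W->D" = list(rates = 0.5)),
                    age_range = c(0, 2), space = sp)
  A <- worklife:::generator_at(cfg, list(), 1)
  s <- discretized_series(A, 0, 2, 4000, sp)
  est <- expected_durations(product_integral(s, 0, 2), sp)
  expect_lt(abs(est$years[est$state == "W"] - (1 - exp(-1)) / 0.5), 1e-3)
  # and the simulator's own oracle agrees exactly
  expect_equal(unname(true_wle(cfg, list(), 0)["W"]), (1 - exp(-1)) / 0.5,
               tolerance = 1e-9)
})

test_that("occupancy is conserved: expected durations sum to the horizon", {
  cfg <- default_scenario(n_subjects = 300)
  eh <- simulate_cohort(cfg, seed = 51)
  sp <- attr(eh, "space")
  s <- nonparametric_intensities(build_risk_sets(eh))
  for (start in c(55, 58.3, 61)) {
    est <- expected_durations(product_integral(s, start, 65), sp)
    expect_equal(sum(est$years), 65 - start, tolerance = 1e-8)
  }
})

test_that("a curve stopping short of pension age is refused", {
  cfg <- default_scenario(n_subjects = 100)
  eh <- simulate_cohort(cfg, seed = 52)
  s <- nonparametric_intensities(build_risk_sets(eh))
  cv <- product_integral(s, 55, 60)
  expect_error(expected_durations(cv, attr(eh, "space")), "pension age")
})

test_that("MSLT and Cox-MSLT give identical expectancies on covariate-free data", {
  cfg <- nocov_scenario(300)
  eh <- simulate_cohort(cfg, seed = 53)
  sp <- attr(eh, "space")
  rs <- build_risk_sets(eh)
  e1 <- expected_durations(product_integral(
    nonparametric_intensities(rs), 55, 65), sp)
  e2 <- expected_durations(product_integral(
    cox_intensities(fit_multistate_cox(eh)), 55, 65), sp)
  expect_equal(e1$years, e2$years, tolerance = 1e-10)
})

test_that("the trapezium quadrature on whole ages approximates the exact step integral", {
  cfg <- default_scenario(n_subjects = 400)
  eh <- simulate_cohort(cfg, seed = 54)
  sp <- attr(eh, "space")
  cv <- product_integral(nonparametric_intensities(build_risk_sets(eh)),
                         55, 65)
  e_step <- expected_durations(cv, sp)
  e_trap <- expected_durations(cv, sp, quadrature = "trapezium")
  expect_lt(max(abs(e_step$years - e_trap$years)), 0.25)
  expect_equal(sum(e_trap$years), 10, tolerance = 1e-8)
})

test_that("WLE recomputation per starting age equals a direct product integral", {
  cfg <- nocov_scenario(200)
  eh <- simulate_cohort(cfg, seed = 55)
  sp <- attr(eh, "space")
  s <- nonparametric_intensities(build_risk_sets(eh))
  curve <- wle_by_starting_age(s, sp, ages = c(56, 59, 62))
  for (i in seq_len(nrow(curve))) {
    direct <- expected_durations(
      product_integral(s, curve$starting_age[i], 65), sp)
    expect_equal(curve$total_wle[i], attr(direct, "total_wle"),
                 tolerance = 1e-12)
  }
})

test_that("bound areas bracket the point estimate and collapse at zero variance", {
  cfg <- default_scenario(n_subjects = 250)
  eh <- simulate_cohort(cfg, seed = 56)
  sp <- attr(eh, "space")
  rs <- build_risk_sets(eh)
  cv <- pointwise_ci(greenwood_covariance(rs, product_integral(
    nonparametric_intensities(rs), 55, 65)))
  est <- expected_durations(cv, sp)
  expect_true(all(est$lower <= est$years + 1e-12))
  expect_true(all(est$years <= est$upper + 1e-12))

  cv0 <- cv
  cv0$var[] <- 0
  cv0 <- pointwise_ci(cv0)
  b0 <- wle_bounds(cv0, sp)
  expect_equal(b0$lower, est$years, tolerance = 1e-12)
  expect_equal(b0$upper, est$years, tolerance = 1e-12)
})

test_that("bound areas match hand integration on a small pure-survival history", {
  sp <- surv_space(65)
  df <- data.frame(subject_id = 1:10, entry_age = 55,
                   exit_age = c(56, 57, 57.5, 58, 59, 59.5, 61, 62, 63, 64.2),
                   from_state = "W",
                   to_state = c("D", "D", NA, "D", NA, "D", NA, "D", NA, NA))
  rs <- build_risk_sets(as_event_history(df, sp))
  cv <- pointwise_ci(greenwood_covariance(rs, product_integral(
    nonparametric_intensities(rs), 55, 65)))
  b <- wle_bounds(cv, sp)
  # hand step integration of the clipped Wald limits
  ev <- rs$events
  S <- cumprod(1 - ev$d / ev$n)
  se <- S * sqrt(cumsum(ev$d / (ev$n * (ev$n - ev$d))))
  lo <- pmax(S - stats::qnorm(0.975) * se, 0)
  hi <- pmin(S + stats::qnorm(0.975) * se, 1)
  widths <- diff(c(ev$time, 65))
  expect_equal(b$lower[b$state == "W"], (ev$time[1] - 55) + sum(lo * widths),
               tolerance = 1e-10)
  expect_equal(b$upper[b$state == "W"], (ev$time[1] - 55) + sum(hi * widths),
               tolerance = 1e-10)
})

test_that("the expectancy report lines up groups, states, totals and months", {
  cfg <- default_scenario(n_subjects = 800)
  eh <- simulate_cohort(cfg, seed = 57)
  sp <- attr(eh, "space")
  rs <- build_risk_sets(eh)
  fit <- fit_multistate_cox(eh, covariates = c("srh_poor", "male"))
  series <- list(good = cox_intensities(fit, list(srh_poor = 0, male = 0)),
                 poor = cox_intensities(fit, list(srh_poor = 1, male = 0)))
  tab <- expectancy_report(series, sp, s = 55,
                           riskset_list = list(good = rs, poor = rs),
                           months = TRUE)
  expect_setequal(unique(tab$group), c("good", "poor"))
  expect_setequal(unique(tab$state), c("W", "S", "U", "total"))
  tot <- tab[tab$state == "total", ]
  for (g in c("good", "poor"))
    expect_equal(tot$years[tot$group == g],
                 sum(tab$years[tab$group == g & tab$state != "total"]))
  expect_equal(tab$months, years_to_months(tab$years))
  # identical profiles give identical rows
  tab2 <- expectancy_report(list(a = series$good, b = series$good), sp,
                            s = 55)
  expect_equal(tab2$years[tab2$group == "a"],
               tab2$years[tab2$group == "b"])
})

test_that("months conversion rounds half-up as reported", {
  expect_identical(years_to_months(c(0.60, 1.15)), c(7L, 14L))
  expect_identical(years_to_months(0.5416667), 7L)  # 6.5 months rounds up
})
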