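#' Expected state durations and worklife expectancy
#'
#' Integrates the state-occupation probability curve from the starting age to
#' pension age: E(h) is the area under P_{start,h}(s, u) for u in (s, t_p].
#' The default quadrature is the exact integral of the piecewise-constant
#' (right-continuous) Aalen-Johansen step function; a trapezium rule on a
#' whole-age grid is available as an alternative. Worklife expectancy is the
#' sum of E(h) over the state space's `wle_states`. Expected durations over
#' all states always sum to the horizon length t_p - s (occupancy
#' conservation).
#'
#' @param curve an `occupation_curve` (see [product_integral]); must reach
#'   pension age, i.e. `curve$t_end >= pension_age`.
#' @param space a [state_space].
#' @param start_state the state conditioned on at the starting age
#'   (default `"W"`).
#' @param quadrature `"step"` (exact for the estimator, default) or
#'   `"trapezium"` (half-weighted endpoints on `grid`).
#' @param grid evaluation ages for the trapezium rule; default whole ages
#'   from the starting age to pension age.
#' @return A `wle_estimate`: data.frame with one row per state (`state`,
#'   `years`, and `lower`/`upper` when the curve carries confidence limits),
#'   with attributes `s`, `start_state`, `horizon`, `total_wle` (and
#'   `total_lower`/`total_upper`).
#' @examples
#' cfg <- default_scenario(n_subjects = 300)
#' eh <- simulate_cohort(cfg, seed = 1)
#' series <- nonparametric_intensities(build_risk_sets(eh))
#' est <- expected_durations(product_integral(series, 55, 65),
#'                           attr(eh, "space"))
#' attr(est, "total_wle")
#' @export
expected_durations <- function(curve, space, start_state = "W",
                               quadrature = c("step", "trapezium"),
                               grid = NULL) {
  quadrature <- match.arg(quadrature)
  stopifnot(inherits(curve, "occupation_curve"),
            start_state %in% space$states)
  t_p <- space$pension_age
  s <- curve$s
  if (curve$t_end < t_p - 1e-9)
    stop("curve ends at ", curve$t_end, " but pension age is ", t_p,
         ": follow-up must cover the full horizon")
  E <- integrate_curve(curve, start_state, s, t_p, quadrature, grid,
                       what = "P")
  out <- data.frame(state = curve$states, years = E)
  has_ci <- !is.null(curve$lower)
  if (has_ci) {
    out$lower <- integrate_curve(curve, start_state, s, t_p, quadrature,
                                 grid, what = "lower")
    out$upper <- integrate_curve(curve, start_state, s, t_p, quadrature,
                                 grid, what = "upper")
  }
  structure(out, class = c("wle_estimate", "data.frame"),
            s = s, start_state = start_state, horizon = t_p - s,
            total_wle = sum(E[curve$states %in% space$wle_states]),
            total_lower = if (has_ci)
              sum(out$lower[curve$states %in% space$wle_states]),
            total_upper = if (has_ci)
              sum(out$upper[curve$states %in% space$wle_states]))
}

# area under row `start_state` of the chosen array, from s to t_p
integrate_curve <- function(curve, start_state, s, t_p, quadrature, grid,
                            what) {
  A <- switch(what, P = curve$P, lower = curve$lower, upper = curve$upper)
  if (is.null(A)) stop("curve has no '", what, "' values")
  states <- curve$states
  m <- length(states)
  h <- match(start_state, states)
  times <- curve$times
  keep <- times <= t_p + 1e-12
  times <- times[keep]
  K <- length(times)
  if (quadrature == "step") {
    ident <- as.numeric(states == start_state)
    if (K == 0L) return(ident * (t_p - s))
    widths <- diff(c(times, t_p))
    E <- ident * (times[1L] - s)
    rows <- matrix(A[h, , seq_len(K)], nrow = m)
    E + as.numeric(rows %*% widths)
  } else {
    if (is.null(grid)) grid <- seq(ceiling(s), floor(t_p))
    grid <- sort(unique(c(s, grid[grid > s & grid < t_p], t_p)))
    vals <- vapply(grid, function(u) eval_curve_at(A, curve, h, u,
                                                   start_state), numeric(m))
    dg <- diff(grid)
    wts <- c(dg / 2, 0) + c(0, dg / 2)  # trapezium weights
    as.numeric(vals %*% wts)
  }
}

# step-function evaluation of row h of an occupation array at age u
eval_curve_at <- function(A, curve, h, u, start_state) {
  k <- findInterval(u + 1e-12, curve$times)
  if (k == 0L) return(as.numeric(curve$states == start_state))
  A[h, , k]
}

#' @export
print.wle_estimate <- function(x, ...) {
  cat("Expected state durations from age ", attr(x, "s"), " (start state ",
      attr(x, "start_state"), ", horizon ", attr(x, "horizon"),
      " years)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("Total WLE: ", format(attr(x, "total_wle"), digits = 4), " years\n",
      sep = "")
  invisible(x)
}

#' Confidence bounds on expected durations
#'
#' Lower and upper bounds computed as areas under the pointwise lower and
#' upper confidence limits of the occupation probabilities, using the same
#' quadrature as the point estimate. Because the pointwise limits are
#' dependent across ages and states, these areas are approximate bounds and
#' should be interpreted with caution.
#'
#' @inheritParams expected_durations
#' @return data.frame `state`, `lower`, `upper` (years).
#' @export
wle_bounds <- function(curve, space, start_state = "W",
                       quadrature = c("step", "trapezium"), grid = NULL) {
  quadrature <- match.arg(quadrature)
  if (is.null(curve$lower)) stop("curve has no pointwise limits; run ",
                                 "pointwise_ci() first")
  est <- expected_durations(curve, space, start_state, quadrature, grid)
  data.frame(state = est$state, lower = est$lower, upper = est$upper)
}

#' Worklife expectancy by starting age
#'
#' Recomputes the product integral and the expected durations from every
#' starting age on a grid, conditioning only on occupying `start_state` at
#' that age — the WLE-by-age curve.
#'
#' @param series an `intensity_series`.
#' @param space a [state_space].
#' @param ages starting ages (all below pension age); default whole ages from
#'   55 to pension age - 1.
#' @param start_state conditioning state, default `"W"`.
#' @param riskset optional `risk_set_table`; when supplied, Greenwood
#'   pointwise limits and bound areas are attached (slower).
#' @return data.frame with one row per starting age: `starting_age`,
#'   `expected_work_years` (E of `start_state`... each WLE state's expected
#'   years in its own column), `total_wle`, and `lower`/`upper` totals when
#'   `riskset` is given.
#' @export
wle_by_starting_age <- function(series, space, ages = NULL,
                                start_state = "W", riskset = NULL) {
  if (is.null(ages))
    ages <- seq(55, space$pension_age - 1)
  stopifnot(all(ages < space$pension_age))
  rows <- lapply(ages, function(s) {
    cv <- product_integral(series, s, space$pension_age)
    if (!is.null(riskset))
      cv <- pointwise_ci(greenwood_covariance(riskset, cv))
    est <- expected_durations(cv, space, start_state)
    row <- data.frame(starting_age = s, total_wle = attr(est, "total_wle"))
    for (h in space$wle_states)
      row[[paste0("E_", h)]] <- est$years[est$state == h]
    if (!is.null(riskset)) {
      row$lower <- attr(est, "total_lower")
      row$upper <- attr(est, "total_upper")
    }
    row
  })
  do.call(rbind, rows)
}

#' Expectancy report across covariate profiles or strata
#'
#' Tabulates expected years in each WLE state (with confidence limits when
#' available) for several groups: one intensity series per group, e.g. from
#' [cox_intensities] with different covariate profiles, or from
#' [nonparametric_intensities] on stratified data.
#'
#' @param series_list named list of `intensity_series`, one per group.
#' @param space a [state_space].
#' @param s starting age.
#' @param start_state conditioning state at age `s`.
#' @param riskset_list optional named list of `risk_set_table`s matching
#'   `series_list`, enabling Greenwood confidence limits.
#' @param months also report months (years x 12, rounded half-up).
#' @return data.frame: `group`, `state`, `years`, `lower`, `upper`
#'   (and `months` when requested), plus one `total` row per group. Bound
#'   columns carry the dependent-outcomes caveat of [wle_bounds].
#' @export
expectancy_report <- function(series_list, space, s = 55, start_state = "W",
                              riskset_list = NULL, months = FALSE) {
  stopifnot(is.list(series_list), length(names(series_list)) ==
              length(series_list))
  rows <- lapply(names(series_list), function(g) {
    cv <- product_integral(series_list[[g]], s, space$pension_age)
    if (!is.null(riskset_list))
      cv <- pointwise_ci(greenwood_covariance(riskset_list[[g]], cv))
    est <- expected_durations(cv, space, start_state)
    sub <- est[est$state %in% space$wle_states, , drop = FALSE]
    out <- data.frame(group = g, state = sub$state, years = sub$years,
                      lower = if (!is.null(sub$lower)) sub$lower else NA_real_,
                      upper = if (!is.null(sub$upper)) sub$upper else NA_real_)
    tot <- data.frame(group = g, state = "total",
                      years = attr(est, "total_wle"),
                      lower = attr(est, "total_lower") %||% NA_real_,
                      upper = attr(est, "total_upper") %||% NA_real_)
    rbind(out, tot)
  })
  out <- do.call(rbind, rows)
  if (months) out$months <- years_to_months(out$years)
  rownames(out) <- NULL
  out
}

#' Convert years to whole months
#'
#' Months are years x 12, rounded half-up to the nearest integer (0.60 years
#' is 7 months; 1.15 years is 14 months).
#'
#' @param years numeric vector of durations in years.
#' @return integer vector of months.
#' @examples
#' years_to_months(c(0.60, 1.15))
#' @export
years_to_months <- function(years) {
  as.integer(floor(years * 12 + 0.5))
}

#' Total worklife expectancy of an estimate
#'
#' @param estimate a `wle_estimate` from [expected_durations].
#' @return The sum of expected years over the WLE states.
#' @export
total_wle <- function(estimate) {
  attr(estimate, "total_wle")
}
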