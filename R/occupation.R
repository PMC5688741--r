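#' Aalen-Johansen transition probabilities by the product integral
#'
#' Estimates the transition-probability matrices P(s, t) as the finite
#' product over event ages u in (s, t] of the factors (I + A(u)), where A(u)
#' are the intensity matrices of the series. All intermediate matrices
#' P(s, t_k) are retained, so the state-occupation curve is available at every
#' event age.
#'
#' @param series an `intensity_series` (either estimation route).
#' @param s starting age (conditioning age).
#' @param t end age; must exceed `s`.
#' @return An `occupation_curve`: list with the starting age `s`, end age
#'   `t_end`, `times` (event ages in (s, t]), `P` (states x states x times
#'   array of P(s, t_k)), the factors' increments `dA`, per-entry effective
#'   at-risk sizes when available, and the state order. With no event ages in
#'   the window, P(s, t) is the identity.
#' @examples
#' eh <- as_event_history(data.frame(
#'   subject_id = 1:10, entry_age = 55, exit_age = 56,
#'   from_state = "W", to_state = c("S", "S", rep(NA, 8))),
#'   danish_labor_market())
#' cv <- product_integral(nonparametric_intensities(build_risk_sets(eh)),
#'                        s = 55, t = 65)
#' cv$P["W", c("W", "S"), 1]  # 0.8, 0.2
#' @export
product_integral <- function(series, s, t) {
  stopifnot(inherits(series, "intensity_series"), s < t)
  states <- series$states
  m <- length(states)
  sel <- which(series$times > s & series$times <= t)
  K <- length(sel)
  P <- array(0, c(m, m, max(K, 1L)), dimnames = list(states, states, NULL))
  acc <- diag(m)
  I <- diag(m)
  for (j in seq_len(K)) {
    fac <- I + series$dA[, , sel[j]]
    if (any(fac < 0))
      stop("factor (I + A(u)) at age ", series$times[sel[j]],
           " has a negative entry: an off-diagonal d/n exceeded 1 ",
           "(check data or weights)")
    acc <- acc %*% fac
    P[, , j] <- acc
  }
  if (K == 0L) P[, , 1L] <- acc
  structure(list(s = s, t_end = t,
                 times = if (K) series$times[sel] else numeric(0),
                 states = states, P = P,
                 dA = if (K) series$dA[, , sel, drop = FALSE] else NULL,
                 n_eff = if (K && !is.null(series$n_eff))
                   series$n_eff[, , sel, drop = FALSE] else NULL,
                 var = NULL, lower = NULL, upper = NULL),
            class = "occupation_curve")
}

#' Greenwood-type covariance of the Aalen-Johansen estimator
#'
#' Attaches estimator variances to every entry of the occupation curve by the
#' recursive covariance update at each event age: the running covariance of
#' vec P(s, t) is propagated through each product factor and a multinomial
#' (Greenwood-type) covariance of the intensity increments, built from the
#' risk-set table, is added. Only the variability of the (baseline) hazard
#' increments is carried; the sampling variability of Cox regression
#' coefficients is not propagated. In the pure-survival special case the
#' recursion reproduces the classical Greenwood Kaplan-Meier variance
#' exactly.
#'
#' @param riskset the `risk_set_table` the curve's intensities were built
#'   from (event ages must match).
#' @param curve an `occupation_curve` from [product_integral].
#' @return The curve with a `var` array (variance of each P entry at each
#'   event age) and the full covariance of vec P(s, t_end) in `vcov_final`.
#' @export
greenwood_covariance <- function(riskset, curve) {
  stopifnot(inherits(riskset, "risk_set_table"),
            inherits(curve, "occupation_curve"))
  states <- curve$states
  m <- length(states)
  K <- length(curve$times)
  V <- array(0, c(m, m, max(K, 1L)), dimnames = list(states, states, NULL))
  if (K == 0L) {
    curve$var <- V
    curve$vcov_final <- matrix(0, m * m, m * m)
    return(curve)
  }
  if (is.null(curve$dA))
    stop("curve carries no intensity increments")
  ki <- vapply(curve$times, function(tt) as.numeric(match_time(tt, riskset$times)),
               numeric(1))
  Sig <- matrix(0, m * m, m * m)
  I <- diag(m)
  P_prev <- I
  for (k in seq_len(K)) {
    D <- curve$dA[, , k]
    nrow_k <- riskset$n[ki[k], states]
    neff_k <- if (!is.null(curve$n_eff)) curve$n_eff[, , k] else
      matrix(NA_real_, m, m)
    Vd <- matrix(0, m * m, m * m)
    for (h in seq_len(m)) {
      p <- D[h, ]
      js <- which(p > 0 & seq_len(m) != h)
      if (!length(js)) next
      n_h <- nrow_k[h]
      C <- matrix(0, m, m)  # covariance of row h of D (entries over j)
      for (a in js) for (b in js) {
        if (a == b) {
          n_ab <- neff_k[h, a]
          if (!is.finite(n_ab)) n_ab <- n_h
          C[a, a] <- p[a] * (1 - p[a]) / n_ab
        } else if (n_h > 0) {
          C[a, b] <- -p[a] * p[b] / n_h
        }
      }
      # diagonal element is minus the row sum of the off-diagonals
      C[h, ] <- -colSums(C[js, , drop = FALSE])
      C[, h] <- -rowSums(C[, js, drop = FALSE])
      C[h, h] <- sum(C[js, js])
      idx <- (seq_len(m) - 1L) * m + h  # vec indices of row h
      Vd[idx, idx] <- C
    }
    Fm <- I + D
    left <- kronecker(t(Fm), I)
    right <- kronecker(I, P_prev)
    Sig <- left %*% Sig %*% t(left) + right %*% Vd %*% t(right)
    V[, , k] <- matrix(pmax(diag(Sig), 0), m, m)
    P_prev <- curve$P[, , k]
  }
  curve$var <- V
  curve$vcov_final <- Sig
  curve
}

#' Pointwise Wald confidence limits for occupation probabilities
#'
#' Plain-scale Wald limits P +/- z * SE per entry and event age, clipped to
#' the unit interval.
#'
#' @param curve an `occupation_curve` with variances attached
#'   (see [greenwood_covariance]).
#' @param level confidence level, default 0.95.
#' @return The curve with `lower` and `upper` arrays and `ci_level` set.
#' @export
pointwise_ci <- function(curve, level = 0.95) {
  stopifnot(inherits(curve, "occupation_curve"))
  if (is.null(curve$var)) stop("no covariance attached; run ",
                               "greenwood_covariance() first")
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(curve$var)
  curve$lower <- pmin(pmax(curve$P - z * se, 0), 1)
  curve$upper <- pmin(pmax(curve$P + z * se, 0), 1)
  curve$ci_level <- level
  curve
}

#' @export
print.occupation_curve <- function(x, ...) {
  cat("Occupation curve P(", x$s, ", t) over ", length(x$times),
      " event ages up to ", x$t_end, "\n", sep = "")
  if (!is.null(x$ci_level))
    cat("  with pointwise ", 100 * x$ci_level, "% limits\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.occupation_curve <- function(x, ...) {
  m <- length(x$states)
  K <- length(x$times)
  if (K == 0L)
    return(data.frame(s = numeric(0), t = numeric(0),
                      from_state = character(0), to_state = character(0),
                      probability = numeric(0)))
  grid <- expand.grid(from_state = x$states, to_state = x$states,
                      k = seq_len(K), stringsAsFactors = FALSE)
  out <- data.frame(s = x$s, t = x$times[grid$k],
                    from_state = grid$from_state, to_state = grid$to_state,
                    probability = x$P[cbind(match(grid$from_state, x$states),
                                            match(grid$to_state, x$states),
                                            grid$k)])
  if (!is.null(x$var))
    out$se <- sqrt(x$var[cbind(match(grid$from_state, x$states),
                               match(grid$to_state, x$states), grid$k)])
  if (!is.null(x$lower)) {
    idx <- cbind(match(grid$from_state, x$states),
                 match(grid$to_state, x$states), grid$k)
    out$lower <- x$lower[idx]
    out$upper <- x$upper[idx]
  }
  out
}
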