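#' Time-indexed intensity matrices
#'
#' An `intensity_series` holds, for each distinct event age, the square
#' matrix A(t) of instantaneous transition quantities: off-diagonal entries
#' are the estimated transition intensities (jump sizes of the cumulative
#' hazards), each transdurable diagonal is minus its row's off-diagonal sum,
#' and absorbing rows are identically zero. Series are sparse in time: only
#' ages at which some transition jumps are stored.
#'
#' [nonparametric_intensities] builds the series from occurrence/exposure
#' ratios d_hj(t)/n_h(t); [cox_intensities] from Breslow baseline increments
#' multiplied by exp(beta'Z) for a covariate profile. Combined-origin
#' transitions are estimated once on the pooled risk set and placed in every
#' origin row — either identically (`combined_mode = "equal"`, the default,
#' i.e. each origin row carries the pooled intensity) or redistributed
#' according to the crude whole-follow-up frequencies of the origin-specific
#' events (`combined_mode = "crude_frequency"`, which preserves the total
#' expected event flow at every age).
#'
#' @param riskset a `risk_set_table` from [build_risk_sets].
#' @param space a [state_space].
#' @param combined_mode `"equal"` or `"crude_frequency"`.
#' @return An `intensity_series`: list with `times`, `states`, `dA`
#'   (states x states x times array) and metadata.
#' @examples
#' eh <- as_event_history(data.frame(
#'   subject_id = 1:10, entry_age = 55, exit_age = 56,
#'   from_state = "W", to_state = c("S", "S", rep(NA, 8))),
#'   danish_labor_market())
#' s <- nonparametric_intensities(build_risk_sets(eh))
#' s$dA["W", "S", 1]  # 2/10
#' @export
nonparametric_intensities <- function(riskset,
                                      space = riskset$space,
                                      combined_mode = c("equal",
                                                        "crude_frequency")) {
  combined_mode <- match.arg(combined_mode)
  ev <- riskset$events
  incr <- data.frame(time = ev$time, trans = ev$trans, value = ev$d / ev$n)
  assemble_matrix_series(incr, space, riskset = riskset,
                         combined_mode = combined_mode)
}

#' @rdname nonparametric_intensities
#' @param fit an `mscox` fit (see [fit_multistate_cox]).
#' @param profile a named list/vector giving a value for every covariate of
#'   the fit (the Z's of the proportional-hazards linear predictor). The
#'   frailty, when present, enters at its mean 1 (population-level
#'   intensities).
#' @param riskset optional `risk_set_table`, required for
#'   `combined_mode = "crude_frequency"` and for the Greenwood covariance
#'   downstream.
#' @export
cox_intensities <- function(fit, profile = NULL,
                            combined_mode = c("equal", "crude_frequency"),
                            riskset = NULL) {
  combined_mode <- match.arg(combined_mode)
  stopifnot(inherits(fit, "mscox"))
  space <- fit$space
  profile <- unlist(profile)
  if (length(fit$covariates)) {
    miss <- setdiff(fit$covariates, names(profile))
    if (length(miss))
      stop("profile is missing covariate(s): ", paste(miss, collapse = ", "))
  }
  pieces <- lapply(names(fit$transitions), function(lab) {
    tr <- fit$transitions[[lab]]
    bh <- tr$basehaz
    if (nrow(bh) == 0L) return(NULL)
    b <- tr$coef
    b[is.na(b)] <- 0
    mult <- if (length(fit$covariates))
      exp(sum(b[fit$covariates] * profile[fit$covariates])) else 1
    data.frame(time = bh$time, trans = lab, value = bh$increment * mult)
  })
  incr <- do.call(rbind, pieces)
  if (is.null(incr))
    incr <- data.frame(time = numeric(0), trans = character(0),
                       value = numeric(0))
  assemble_matrix_series(incr, space, riskset = riskset,
                         combined_mode = combined_mode)
}

#' Assemble per-transition intensity increments into matrix form
#'
#' Places per-transition jump sizes into square matrices per event age,
#' handling combined-origin placement, row-sum-zero diagonals and zeroed
#' absorbing rows.
#'
#' @param increments data.frame with columns `time`, `trans` (transition
#'   label) and `value` (the intensity increment of that transition at that
#'   age).
#' @inheritParams nonparametric_intensities
#' @export
assemble_matrix_series <- function(increments, space, riskset = NULL,
                                   combined_mode = c("equal",
                                                     "crude_frequency")) {
  combined_mode <- match.arg(combined_mode)
  states <- space$states
  m <- length(states)
  times <- sort(unique(increments$time))
  K <- length(times)
  dA <- array(0, c(m, m, K), dimnames = list(states, states, NULL))
  neff <- array(NA_real_, c(m, m, K), dimnames = list(states, states, NULL))
  origins <- lapply(space$transitions, `[[`, "from")
  targets <- vapply(space$transitions, `[[`, "", "to")
  names(origins) <- names(targets) <- transition_labels(space)

  cf <- NULL
  if (combined_mode == "crude_frequency") {
    if (is.null(riskset))
      stop("combined_mode = \"crude_frequency\" needs a riskset")
    cf <- riskset$origin_totals
  }
  ki <- match(increments$time, times)
  for (i in seq_len(nrow(increments))) {
    lab <- increments$trans[i]
    org <- origins[[lab]]
    if (is.null(org)) stop("unknown transition in increments: ", lab)
    to <- targets[[lab]]
    k <- ki[i]
    v <- increments$value[i]
    if (length(org) == 1L || combined_mode == "equal") {
      dA[org, to, k] <- dA[org, to, k] + v
      if (!is.null(riskset)) {
        kk <- match_time(increments$time[i], riskset$times)
        neff[org, to, k] <- sum(riskset$n[kk, org])
      }
    } else {
      tot <- cf[cf$trans == lab, , drop = FALSE]
      kk <- match_time(increments$time[i], riskset$times)
      n_c <- sum(riskset$n[kk, org])
      if (nrow(tot) == 0L || sum(tot$d) == 0) {
        warning("no origin events for ", lab,
                "; falling back to equal placement")
        dA[org, to, k] <- dA[org, to, k] + v
        neff[org, to, k] <- n_c
      } else {
        f <- stats::setNames(rep(0, length(org)), org)
        f[tot$origin] <- tot$d / sum(tot$d)
        for (h in org) {
          n_h <- riskset$n[kk, h]
          if (n_h > 0) {
            dA[h, to, k] <- dA[h, to, k] + v * f[[h]] * n_c / n_h
            neff[h, to, k] <- n_h
          }
        }
      }
    }
  }
  absorbing <- states %in% absorbing_states(space)
  for (k in seq_len(K)) {
    dA[absorbing, , k] <- 0
    diag(dA[, , k]) <- 0
    diag(dA[, , k]) <- -rowSums(dA[, , k])
  }
  structure(list(times = times, states = states, dA = dA, n_eff = neff,
                 combined_mode = combined_mode, space = space),
            class = "intensity_series")
}

# match event ages between two tables built from the same data
match_time <- function(t, times) {
  k <- findInterval(t, times)
  if (k < 1L || abs(times[k] - t) > 1e-9)
    stop("event age ", t, " not found in risk-set table")
  k
}

#' @export
print.intensity_series <- function(x, ...) {
  cat("Intensity-matrix series: ", length(x$times), " event ages, states ",
      paste(x$states, collapse = " "), ", combined mode '",
      x$combined_mode, "'\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.intensity_series <- function(x, ...) {
  m <- length(x$states)
  K <- length(x$times)
  idx <- which(x$dA != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(age = numeric(0), from_state = character(0),
                      to_state = character(0), intensity = numeric(0)))
  out <- data.frame(age = x$times[idx[, 3L]],
                    from_state = x$states[idx[, 1L]],
                    to_state = x$states[idx[, 2L]],
                    intensity = x$dA[idx])
  out[order(out$age, out$from_state, out$to_state), , drop = FALSE]
}
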