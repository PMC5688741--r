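#' Fit the multi-state proportional-hazards model
#'
#' One Cox proportional-hazards model per modeled transition, on the
#' counting-process time scale of age, with transition-specific covariate
#' effects and Breslow handling of ties. A combined-origin transition pools
#' the episodes of all its origin states into one risk set. Episodes carry
#' constant covariates; time-varying covariates are represented by episode
#' splitting upstream. Fitting each transition separately and fitting one
#' model on stacked long-format data stratified by transition give identical
#' estimates; both routes are available.
#'
#' @param records an `event_history` (see [as_event_history]).
#' @param space a [state_space]; defaults to the one attached to `records`.
#' @param covariates character vector of covariate column names entering every
#'   transition's linear predictor (may be empty: baseline-only fit).
#' @param weights optional per-record nonnegative weights (e.g. stabilized
#'   inverse-propensity weights); they enter both the partial-likelihood score
#'   and the Breslow baseline denominator. Defaults to the `weight` column.
#' @param frailty fit a shared per-subject gamma random effect (mean 1,
#'   variance theta) by penalized partial likelihood. Requires
#'   `method = "stacked"` so the frailty is shared across transitions.
#' @param frailty_theta optional fixed value for the frailty variance; by
#'   default theta is estimated by the inner-outer profile iteration.
#' @param method `"per_transition"` (default) or `"stacked"` (one fit
#'   stratified by transition, covariates interacted with transition).
#' @return An object of class `mscox`: per transition the coefficient vector,
#'   standard errors, variance matrix and the Breslow baseline cumulative
#'   hazard (jump ages and increments, evaluated at covariates zero); plus the
#'   frailty variance `theta` when requested. With no covariates the baseline
#'   increments equal the Nelson-Aalen d/n of that transition exactly.
#' @examples
#' cfg <- default_scenario(n_subjects = 500)
#' eh <- simulate_cohort(cfg, seed = 1)
#' fit <- fit_multistate_cox(eh, covariates = c("srh_poor", "male"))
#' summary_table(fit)[1:4, ]
#' @export
fit_multistate_cox <- function(records, space = attr(records, "space"),
                               covariates = character(), weights = NULL,
                               frailty = FALSE, frailty_theta = NULL,
                               method = c("per_transition", "stacked")) {
  method <- match.arg(method)
  stopifnot(inherits(records, "event_history"))
  if (length(covariates)) {
    miss <- setdiff(covariates, names(records))
    if (length(miss))
      stop("covariate(s) not in records: ", paste(miss, collapse = ", "))
  }
  if (frailty && method != "stacked")
    stop("shared frailty requires method = \"stacked\"")
  w <- if (is.null(weights)) records$weight else weights
  if (length(w) != nrow(records)) stop("weights length mismatch")

  labs <- transition_labels(space)
  origins <- lapply(space$transitions, `[[`, "from")
  targets <- vapply(space$transitions, `[[`, "", "to")
  names(origins) <- names(targets) <- labs

  if (method == "stacked") {
    stacked <- stack_transitions(records, space, w)
    fit <- fit_stacked_cox(stacked, covariates, frailty, frailty_theta)
    beta_all <- fit$beta; vcov_all <- fit$vcov; theta <- fit$theta
  } else theta <- NA_real_

  fits <- stats::setNames(vector("list", length(labs)), labs)
  for (lab in labs) {
    idx <- records$from_state %in% origins[[lab]]
    dat <- records[idx, , drop = FALSE]
    wi <- w[idx]
    status <- as.integer(dat$to_state == targets[[lab]])
    if (method == "stacked" && length(covariates)) {
      want <- paste0(lab, ":", covariates)
      have <- intersect(want, names(beta_all))
      beta <- stats::setNames(rep(NA_real_, length(covariates)), covariates)
      vc <- matrix(NA_real_, length(covariates), length(covariates),
                   dimnames = list(covariates, covariates))
      if (length(have)) {
        ci <- covariates[match(have, want)]
        beta[ci] <- beta_all[have]
        vc[ci, ci] <- vcov_all[have, have]
      }
    } else if (length(covariates) && sum(status) > 0 &&
               any(apply(dat[covariates], 2, function(z) length(unique(z))) > 1)) {
      cf <- fit_one_cox(dat, status, wi, covariates, lab)
      beta <- cf$beta; vc <- cf$vcov
    } else {
      beta <- stats::setNames(rep(NA_real_, length(covariates)), covariates)
      vc <- matrix(NA_real_, length(covariates), length(covariates),
                   dimnames = list(covariates, covariates))
    }
    fits[[lab]] <- list(
      coef = beta, vcov = vc,
      se = sqrt(diag(vc))[names(beta)] %||% numeric(0),
      n_events = sum(wi[status == 1L]),
      basehaz = breslow_baseline(dat, status, wi, beta, covariates))
  }
  structure(list(transitions = fits, covariates = covariates,
                 frailty_theta = theta,
                 weighted = !is.null(weights), space = space,
                 method = method),
            class = "mscox")
}

# single-transition coxph wrapper with convergence / separation guards
fit_one_cox <- function(dat, status, wi, covariates, lab) {
  fml <- stats::as.formula(paste(
    "survival::Surv(entry_age, exit_age, status) ~",
    paste(covariates, collapse = " + ")))
  dat$status <- status
  msgs <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, weights = wi, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-11,
                                                      toler.chol = 1e-13,
                                                      iter.max = 100)),
    warning = function(wrn) {
      msgs <<- c(msgs, conditionMessage(wrn))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (any(grepl("did not converge|Ran out of iterations", msgs)))
    stop("transition ", lab, ": partial likelihood did not converge after ",
         fit$iter, " iterations")
  if (any(is.infinite(beta)) || any(abs(beta) > 15, na.rm = TRUE))
    stop("transition ", lab, ": complete separation suspected for ",
         paste(names(beta)[is.infinite(beta) |
                             (!is.na(beta) & abs(beta) > 15)],
               collapse = ", "))
  list(beta = beta, vcov = stats::vcov(fit))
}

# stacked long format: one row per (episode x transition with matching origin)
stack_transitions <- function(records, space, w) {
  labs <- transition_labels(space)
  origins <- lapply(space$transitions, `[[`, "from")
  targets <- vapply(space$transitions, `[[`, "", "to")
  pieces <- lapply(seq_along(labs), function(i) {
    idx <- which(records$from_state %in% origins[[i]])
    if (!length(idx)) return(NULL)
    out <- as.data.frame(records)[idx, , drop = FALSE]
    out$.trans <- labs[i]
    out$.status <- as.integer(out$to_state == targets[[i]])
    out$.w <- w[idx]
    out
  })
  do.call(rbind, pieces)
}

fit_stacked_cox <- function(stacked, covariates, frailty,
                            frailty_theta = NULL) {
  stacked$.trans <- factor(stacked$.trans)
  mm <- NULL
  if (length(covariates)) {
    mm <- do.call(cbind, lapply(levels(stacked$.trans), function(tr) {
      m <- as.matrix(stacked[covariates]) * (stacked$.trans == tr)
      colnames(m) <- paste0(tr, ":", covariates)
      m
    }))
    # drop columns with no variation among that transition's rows
    keep <- apply(mm, 2, function(z) stats::var(z) > 0)
    mm <- mm[, keep, drop = FALSE]
  }
  df <- data.frame(entry = stacked$entry_age, exit = stacked$exit_age,
                   status = stacked$.status, id = stacked$subject_id)
  rhs <- c(if (!is.null(mm) && ncol(mm)) "mm",
           "survival::strata(stacked$.trans)",
           if (frailty && !is.null(frailty_theta))
             "survival::frailty.gamma(id, theta = frailty_theta)"
           else if (frailty) "survival::frailty.gamma(id, eps = 1e-9)")
  fml <- stats::as.formula(paste("survival::Surv(entry, exit, status) ~",
                                 paste(rhs, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, weights = stacked$.w,
                         ties = "breslow",
                         control = survival::coxph.control(
                           eps = 1e-11, toler.chol = 1e-13,
                           iter.max = 100))
  beta <- stats::coef(fit)
  if (!is.null(mm) && length(beta) == ncol(mm)) {
    names(beta) <- colnames(mm)  # coxph drops names of 1-column matrix terms
  } else names(beta) <- sub("^mm", "", names(beta))
  vc <- stats::vcov(fit)
  if (!is.null(dim(vc))) dimnames(vc) <- list(names(beta), names(beta))
  theta <- if (frailty) fit$history[[1]]$theta %||% NA_real_ else NA_real_
  list(beta = beta, vcov = vc, theta = theta)
}

# weighted Breslow baseline at covariates zero; reduces to d/n when beta empty
breslow_baseline <- function(dat, status, wi, beta, covariates) {
  ev <- status == 1L
  if (!any(ev))
    return(data.frame(time = numeric(0), increment = numeric(0),
                      cumulative = numeric(0)))
  r <- if (length(covariates)) {
    b <- beta[covariates]
    b[is.na(b)] <- 0  # unidentified effects are absorbed into the baseline
    exp(as.matrix(dat[covariates]) %*% b)[, 1L]
  } else rep(1, nrow(dat))
  wr <- wi * r
  times <- sort(unique(dat$exit_age[ev]))
  num <- vapply(times, function(t) sum(wi[ev & dat$exit_age == t]),
                numeric(1))
  den <- wcount_less(dat$entry_age, wr, times) -
    wcount_less(dat$exit_age, wr, times)
  inc <- num / den
  data.frame(time = times, increment = inc, cumulative = cumsum(inc))
}

#' Breslow baseline cumulative hazard of one transition
#'
#' @param fit an `mscox` fit.
#' @param transition transition label, e.g. `"W->S"` or `"W+S+U->D"`.
#' @return An object of class `breslow_hazard`: jump ages, increments and the
#'   running cumulative hazard, evaluable at arbitrary ages with
#'   [hazard_at] (right-continuous step function starting at 0).
#' @export
baseline_cumulative_hazard <- function(fit, transition) {
  stopifnot(inherits(fit, "mscox"))
  if (!transition %in% names(fit$transitions))
    stop("unknown transition: ", transition)
  bh <- fit$transitions[[transition]]$basehaz
  structure(list(time = bh$time, increment = bh$increment,
                 cumulative = bh$cumulative, transition = transition),
            class = "breslow_hazard")
}

#' @rdname baseline_cumulative_hazard
#' @param hazard a `breslow_hazard`.
#' @param ages ages at which to evaluate the cumulative hazard.
#' @export
hazard_at <- function(hazard, ages) {
  stopifnot(inherits(hazard, "breslow_hazard"))
  c(0, hazard$cumulative)[findInterval(ages, hazard$time) + 1L]
}

#' @export
print.mscox <- function(x, ...) {
  cat("Multi-state Cox fit (", x$method, ", ties = Breslow)\n", sep = "")
  cat("  transitions:", paste(names(x$transitions), collapse = ", "), "\n")
  if (length(x$covariates))
    cat("  covariates: ", paste(x$covariates, collapse = ", "), "\n")
  if (!is.na(x$frailty_theta))
    cat("  gamma frailty variance:", format(x$frailty_theta, digits = 4), "\n")
  invisible(x)
}

#' Hazard-ratio summary table of a multi-state Cox fit
#'
#' One row per transition and covariate with the hazard ratio, Wald 95%
#' confidence limits and p value — the shape in which transition-specific
#' effects are conventionally reported.
#'
#' @param fit an `mscox` fit.
#' @param level confidence level (default 0.95).
#' @return data.frame with columns `transition`, `covariate`, `HR`, `lower`,
#'   `upper`, `p`.
#' @export
summary_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mscox"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- lapply(names(fit$transitions), function(lab) {
    tr <- fit$transitions[[lab]]
    if (!length(tr$coef)) return(NULL)
    data.frame(transition = lab, covariate = names(tr$coef),
               HR = exp(tr$coef),
               lower = exp(tr$coef - z * tr$se),
               upper = exp(tr$coef + z * tr$se),
               p = 2 * stats::pnorm(-abs(tr$coef / tr$se)),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Stratified cumulative-hazard curves for proportionality checking
#'
#' Nelson-Aalen cumulative hazards per level of a categorical covariate, per
#' transition, for visual assessment of the proportional-hazards assumption;
#' with two or more levels a log-ratio table against the first level is
#' attached (proportional hazards imply a roughly constant log ratio).
#'
#' @param records an `event_history`.
#' @param space a [state_space]; defaults to the attached one.
#' @param covariate name of a categorical/dichotomous covariate column.
#' @return data.frame `transition`, `level`, `time`, `cumhaz`, with attribute
#'   `log_ratio` (data.frame `transition`, `time`, `level`, `log_ratio`) when
#'   more than one level is present. Strata with zero events yield an all-zero
#'   curve and are flagged in attribute `zero_event_strata` with a warning.
#' @export
proportionality_diagnostics <- function(records,
                                        space = attr(records, "space"),
                                        covariate) {
  stopifnot(inherits(records, "event_history"),
            covariate %in% names(records))
  levs <- sort(unique(records[[covariate]]))
  curves <- list(); zero <- character(0)
  for (lv in levs) {
    sub <- records[records[[covariate]] == lv, , drop = FALSE]
    class(sub) <- class(records); attr(sub, "space") <- space
    rs <- build_risk_sets(sub, space)
    for (lab in transition_labels(space)) {
      e <- rs$events[rs$events$trans == lab, , drop = FALSE]
      if (nrow(e) == 0L) {
        zero <- c(zero, paste0(lab, " @ ", covariate, "=", lv))
        curves[[length(curves) + 1L]] <- data.frame(
          transition = lab, level = as.character(lv), time = space$pension_age,
          cumhaz = 0)
      } else {
        curves[[length(curves) + 1L]] <- data.frame(
          transition = lab, level = as.character(lv), time = e$time,
          cumhaz = cumsum(e$d / e$n))
      }
    }
  }
  out <- do.call(rbind, curves)
  if (length(zero))
    warning("zero-event strata: ", paste(zero, collapse = "; "))
  attr(out, "zero_event_strata") <- zero
  if (length(levs) > 1L) {
    ref <- as.character(levs[1L])
    lr <- list()
    for (lab in unique(out$transition)) {
      base <- out[out$transition == lab & out$level == ref, , drop = FALSE]
      if (nrow(base) == 0L || all(base$cumhaz == 0)) next
      bfun <- stats::stepfun(base$time, c(0, base$cumhaz))
      for (lv in as.character(levs[-1L])) {
        cur <- out[out$transition == lab & out$level == lv, , drop = FALSE]
        ok <- cur$cumhaz > 0 & bfun(cur$time) > 0
        if (!any(ok)) next
        lr[[length(lr) + 1L]] <- data.frame(
          transition = lab, time = cur$time[ok], level = lv,
          log_ratio = log(cur$cumhaz[ok] / bfun(cur$time[ok])))
      }
    }
    attr(out, "log_ratio") <- if (length(lr)) do.call(rbind, lr) else NULL
  }
  out
}
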