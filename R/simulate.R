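#' Configure a register-style cohort simulation
#'
#' Defines a multi-state cohort-generating process with piecewise-constant
#' baseline transition intensities, multiplicative (log-hazard-ratio)
#' covariate effects per transition, optional covariate dependence (for
#' confounding scenarios), dynamic no-to-yes covariate flips triggered by
#' completed episodes, optional shared gamma frailty and optional
#' non-administrative censoring. Subjects enter at the lower end of the age
#' window and are administratively censored at the upper end.
#'
#' @param n_subjects cohort size.
#' @param transitions named list keyed by transition label (`"W->S"`,
#'   `"W+S+U->D"`, ...); each element a list with `rates` (per-year
#'   intensities), optional `breaks` (interior ages splitting the window into
#'   `length(rates)` constant pieces) and optional `beta` (named
#'   log-hazard-ratios per covariate). A combined label applies the same
#'   hazard from every origin state.
#' @param covariates named list; each element a list with `prevalence`
#'   (marginal Bernoulli probability) or `intercept` + `coefs` (named
#'   logistic dependence on previously listed covariates).
#' @param age_range entry and administrative-censoring ages, default
#'   `c(55, 65)`.
#' @param dynamic_rules named list keyed by covariate name: each a list with
#'   `state` and `min_duration` (years); the covariate flips to 1 for all
#'   later episodes once the subject completes an episode in `state` longer
#'   than `min_duration`.
#' @param frailty_theta variance of the per-subject gamma frailty (mean 1);
#'   0 disables it.
#' @param censor_rate constant per-year rate of non-administrative loss to
#'   follow-up; 0 disables it.
#' @param start_state state occupied at entry (default `"W"`).
#' @param space optional [state_space]; by default derived from the
#'   transition labels (origin-only states transdurable, target-only states
#'   absorbing, WLE states the intersection with W, S, U).
#' @return A `sim_config`.
#' @export
sim_config <- function(n_subjects, transitions, covariates = list(),
                       age_range = c(55, 65), dynamic_rules = list(),
                       frailty_theta = 0, censor_rate = 0,
                       start_state = "W", space = NULL) {
  stopifnot(n_subjects >= 1, length(age_range) == 2L,
            age_range[1] < age_range[2], frailty_theta >= 0,
            censor_rate >= 0)
  for (lab in names(transitions)) {
    transitions[[lab]]$rates <- as.numeric(unlist(transitions[[lab]]$rates))
    if (!is.null(transitions[[lab]]$breaks))
      transitions[[lab]]$breaks <- as.numeric(unlist(transitions[[lab]]$breaks))
    if (!is.null(transitions[[lab]]$beta))
      transitions[[lab]]$beta <- unlist(transitions[[lab]]$beta)
    tr <- transitions[[lab]]
    if (any(tr$rates < 0)) stop("negative rate in ", lab)
    nb <- length(tr$breaks %||% numeric(0))
    if (length(tr$rates) != nb + 1L)
      stop(lab, ": need length(rates) == length(breaks) + 1")
    if (nb && is.unsorted(tr$breaks, strictly = TRUE))
      stop(lab, ": breaks must be strictly increasing")
  }
  if (is.null(space)) space <- derive_space(names(transitions), age_range[2])
  stopifnot(start_state %in% space$states)
  structure(list(n_subjects = as.integer(n_subjects),
                 transitions = transitions, covariates = covariates,
                 age_range = age_range, dynamic_rules = dynamic_rules,
                 frailty_theta = frailty_theta, censor_rate = censor_rate,
                 start_state = start_state, space = space),
            class = "sim_config")
}

derive_space <- function(labels, pension_age) {
  trans <- lapply(labels, parse_transition)
  froms <- unique(unlist(lapply(trans, `[[`, "from")))
  tos <- unique(vapply(trans, `[[`, "", "to"))
  states <- unique(c(froms, tos))
  roles <- ifelse(states %in% froms, "transdurable", "absorbing")
  state_space(states, roles, labels,
              wle_states = intersect(c("W", "S", "U"), froms),
              pension_age = pension_age)
}

#' A shipped illustrative labor-market scenario
#'
#' A ready-made [sim_config] emulating the structure of a late-career Danish
#' cohort: states W, S, U, D (and E for ERP members, reachable from age 60),
#' self-rated health (10% poor) raising sickness-absence, disability and
#' early-retirement hazards, and gender raising the unemployment hazard. The
#' rates are illustrative — shaped to produce the qualitative orderings of
#' such cohorts (poor health and ERP membership shorten expected work time) —
#' not calibrated to any register.
#'
#' @param n_subjects cohort size (default 2000).
#' @param member ERP-scheme membership: adds the combined early-retirement
#'   transition available from age 60.
#' @param censor_rate non-administrative censoring rate per year.
#' @param frailty_theta shared gamma-frailty variance.
#' @return A `sim_config`.
#' @examples
#' cfg <- default_scenario(n_subjects = 200)
#' eh <- simulate_cohort(cfg, seed = 42)
#' table(eh$from_state, eh$to_state)
#' @export
default_scenario <- function(n_subjects = 2000, member = TRUE,
                             censor_rate = 0.02, frailty_theta = 0) {
  transitions <- list(
    "W->S" = list(rates = 0.12, beta = c(srh_poor = log(2.2))),
    "W->U" = list(rates = 0.10, beta = c(srh_poor = log(1.5),
                                         male = log(1.5))),
    "S->W" = list(rates = 2.0, beta = c(srh_poor = log(0.75))),
    "S->U" = list(rates = 0.10),
    "U->W" = list(rates = 0.80, beta = c(srh_poor = log(0.8))),
    "U->S" = list(rates = 0.10),
    "W+S+U->D" = list(rates = 0.005, beta = c(srh_poor = log(7))))
  if (member)
    transitions[["W+S+U->E"]] <- list(
      breaks = 60, rates = c(0, 0.35), beta = c(srh_poor = log(1.65)))
  sim_config(
    n_subjects = n_subjects, transitions = transitions,
    covariates = list(srh_poor = list(prevalence = 0.10),
                      male = list(prevalence = 0.50)),
    censor_rate = censor_rate, frailty_theta = frailty_theta)
}

# piecewise-constant pieces of a transition over [a0, a1]
piece_grid <- function(tr, a0, a1) {
  br <- c(a0, tr$breaks %||% numeric(0), a1)
  list(lo = br[-length(br)], hi = br[-1L], rate = tr$rates)
}

#' Simulate a multi-state cohort
#'
#' Draws subject trajectories by exact inversion of the piecewise-constant
#' cumulative total-exit hazard: the sojourn in the current state is sampled
#' from the sum of all outgoing transition intensities (baseline x
#' exp(beta'Z) x frailty), and the destination is drawn from the relative
#' intensities at the event age. Trajectories are chained until absorption,
#' non-administrative censoring or the administrative horizon. Same seed,
#' same output.
#'
#' @param config a [sim_config].
#' @param seed integer random seed (mandatory: every stochastic output is
#'   seeded).
#' @return A validated `event_history` with the config's covariate columns.
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  a0 <- config$age_range[1]; a1 <- config$age_range[2]
  space <- config$space
  labs <- names(config$transitions)
  parsed <- lapply(labs, parse_transition)
  targets <- vapply(parsed, `[[`, "", "to")
  pg <- lapply(labs, function(lab)
    piece_grid(config$transitions[[lab]], a0, a1))
  betas <- lapply(labs, function(lab) config$transitions[[lab]]$beta)
  # outgoing transition indices per state
  out_map <- lapply(space$states, function(st)
    which(vapply(parsed, function(p) st %in% p$from, logical(1))))
  names(out_map) <- space$states
  absorbing <- absorbing_states(space)

  n <- config$n_subjects
  covs <- draw_covariates(config$covariates, n)
  cn <- colnames(covs)
  u <- if (config$frailty_theta > 0)
    stats::rgamma(n, shape = 1 / config$frailty_theta,
                  scale = config$frailty_theta) else rep(1, n)
  cens_age <- if (config$censor_rate > 0)
    a0 + stats::rexp(n, config$censor_rate) else rep(Inf, n)

  cap <- n * 6L
  sid <- integer(cap); ent <- exi <- numeric(cap)
  frs <- tos <- character(cap)
  zrec <- matrix(0, cap, length(cn))
  nr <- 0L
  mults <- numeric(length(labs))
  rate_at <- function(j, a) {
    g <- pg[[j]]
    k <- min(max(findInterval(a, g$lo, rightmost.closed = TRUE), 1L),
             length(g$rate))
    g$rate[k] * mults[j]
  }
  for (i in seq_len(n)) {
    age <- a0; state <- config$start_state
    z <- if (length(cn)) as.numeric(covs[i, ]) else numeric(0)
    names(z) <- cn
    recompute <- TRUE
    repeat {
      if (recompute) {
        for (j in seq_along(labs)) {
          b <- betas[[j]]
          mults[j] <- u[i] *
            if (length(b)) exp(sum(b * z[names(b)])) else 1
        }
        recompute <- FALSE
      }
      out_idx <- out_map[[state]]
      ev <- sample_sojourn(pg, out_idx, rate_at, age, a1)
      stop_age <- min(ev$age, cens_age[i], a1)
      to <- if (ev$age <= min(cens_age[i], a1) && !is.na(ev$trans))
        targets[ev$trans] else CENSORED
      if (nr + 1L > cap) {
        cap <- cap * 2L
        sid <- c(sid, integer(cap %/% 2L))
        ent <- c(ent, numeric(cap %/% 2L)); exi <- c(exi, numeric(cap %/% 2L))
        frs <- c(frs, character(cap %/% 2L)); tos <- c(tos, character(cap %/% 2L))
        zrec <- rbind(zrec, matrix(0, cap %/% 2L, length(cn)))
      }
      nr <- nr + 1L
      sid[nr] <- i; ent[nr] <- age; exi[nr] <- stop_age
      frs[nr] <- state; tos[nr] <- to
      if (length(cn)) zrec[nr, ] <- z
      # dynamic covariate flips triggered by the completed episode
      for (cv in names(config$dynamic_rules)) {
        rule <- config$dynamic_rules[[cv]]
        if (state == rule$state && (stop_age - age) > rule$min_duration &&
            z[[cv]] != 1) {
          z[[cv]] <- 1
          recompute <- TRUE
        }
      }
      if (to == CENSORED || to %in% absorbing) break
      age <- stop_age; state <- to
    }
  }
  df <- data.frame(subject_id = sid[seq_len(nr)], entry_age = ent[seq_len(nr)],
                   exit_age = exi[seq_len(nr)], from_state = frs[seq_len(nr)],
                   to_state = tos[seq_len(nr)], stringsAsFactors = FALSE)
  for (j in seq_along(cn)) df[[cn[j]]] <- zrec[seq_len(nr), j]
  as_event_history(df, space)
}

draw_covariates <- function(covariates, n) {
  out <- matrix(0, n, length(covariates),
                dimnames = list(NULL, names(covariates)))
  for (j in seq_along(covariates)) {
    cv <- covariates[[j]]
    if (!is.null(cv$prevalence)) {
      out[, j] <- stats::rbinom(n, 1, cv$prevalence)
    } else {
      lp <- rep(cv$intercept, n)
      for (dep in names(cv$coefs)) lp <- lp + cv$coefs[[dep]] * out[, dep]
      out[, j] <- stats::rbinom(n, 1, stats::plogis(lp))
    }
  }
  as.data.frame(out)
}

# exact inversion sampling of the next event from piecewise-constant total
# hazard; returns the event age and which outgoing transition fired
sample_sojourn <- function(pg, out_idx, rate_at, age, a1) {
  if (!length(out_idx)) return(list(age = Inf, trans = NA_integer_))
  # merged breakpoints in [age, a1]
  brk <- sort(unique(c(age, a1,
                       unlist(lapply(pg[out_idx], function(g) g$lo[-1L])))))
  brk <- brk[brk >= age & brk <= a1]
  target <- stats::rexp(1)
  cum <- 0
  for (p in seq_len(length(brk) - 1L)) {
    lo <- brk[p]; hi <- brk[p + 1L]
    tot <- sum(vapply(out_idx, rate_at, numeric(1), a = (lo + hi) / 2))
    seg <- tot * (hi - lo)
    if (cum + seg >= target && tot > 0) {
      t_ev <- lo + (target - cum) / tot
      rts <- vapply(out_idx, rate_at, numeric(1), a = t_ev)
      pick <- out_idx[sample.int(length(out_idx), 1L, prob = rts)]
      return(list(age = t_ev, trans = pick))
    }
    cum <- cum + seg
  }
  list(age = Inf, trans = NA_integer_)
}

#' Exact occupation probabilities and expectancies of a simulation config
#'
#' Truth oracles for the marginal Markov case: with fixed covariate profile,
#' no dynamic flips and no frailty, the configured process is a
#' time-inhomogeneous Markov chain with piecewise-constant generator, so
#' P(s, t) is the product of matrix exponentials over the constant pieces and
#' the expected durations are their exact integrals (via the augmented-matrix
#' exponential on each piece).
#'
#' @param config a [sim_config] with `frailty_theta = 0` and no
#'   `dynamic_rules`.
#' @param profile named covariate values fixing the subject profile.
#' @param s,t age window.
#' @return [true_occupation]: the exact transition-probability matrix
#'   P(s, t) (rows sum to 1).
#' @export
true_occupation <- function(config, profile = list(), s, t) {
  gen <- check_oracle(config)
  stopifnot(s <= t)
  if (s == t) {
    m <- length(config$space$states)
    return(diag(m))
  }
  pieces <- oracle_pieces(config, s, t)
  P <- diag(length(config$space$states))
  for (p in seq_len(nrow(pieces))) {
    A <- generator_at(config, profile, (pieces$lo[p] + pieces$hi[p]) / 2)
    P <- P %*% as.matrix(Matrix::expm(A * (pieces$hi[p] - pieces$lo[p])))
  }
  dimnames(P) <- list(config$space$states, config$space$states)
  P
}

#' @rdname true_occupation
#' @return [true_wle]: named vector of exact expected durations per state
#'   from `s` to pension age, summing to the horizon.
#' @export
true_wle <- function(config, profile = list(), s) {
  check_oracle(config)
  t_p <- config$space$pension_age
  states <- config$space$states
  m <- length(states)
  pieces <- oracle_pieces(config, s, t_p)
  P <- diag(m)
  E <- matrix(0, m, m)
  for (p in seq_len(nrow(pieces))) {
    d <- pieces$hi[p] - pieces$lo[p]
    A <- generator_at(config, profile, (pieces$lo[p] + pieces$hi[p]) / 2)
    # integral of expm(A v) over [0, d] via the augmented exponential
    aug <- rbind(cbind(A, diag(m)), matrix(0, m, 2 * m))
    ea <- as.matrix(Matrix::expm(aug * d))
    E <- E + P %*% ea[seq_len(m), m + seq_len(m)]
    P <- P %*% ea[seq_len(m), seq_len(m)]
  }
  stats::setNames(E[match(config$start_state, states), ], states)
}

check_oracle <- function(config) {
  if (config$frailty_theta > 0)
    stop("truth oracle requires frailty_theta = 0 (marginal Markov case)")
  if (length(config$dynamic_rules))
    stop("truth oracle requires a config without dynamic covariate rules")
  invisible(TRUE)
}

oracle_pieces <- function(config, s, t) {
  brk <- sort(unique(c(s, t, unlist(lapply(config$transitions, function(tr)
    tr$breaks %||% numeric(0))))))
  brk <- brk[brk >= s & brk <= t]
  data.frame(lo = brk[-length(brk)], hi = brk[-1L])
}

# profile-adjusted generator matrix at one age
generator_at <- function(config, profile, age) {
  states <- config$space$states
  m <- length(states)
  A <- matrix(0, m, m, dimnames = list(states, states))
  for (lab in names(config$transitions)) {
    tr <- config$transitions[[lab]]
    pt <- parse_transition(lab)
    pg <- piece_grid(tr, config$age_range[1], config$age_range[2])
    k <- min(max(findInterval(age, pg$lo, rightmost.closed = TRUE), 1L),
             length(pg$rate))
    mult <- 1
    for (cv in names(tr$beta))
      mult <- mult * exp(tr$beta[[cv]] * (profile[[cv]] %||% 0))
    for (h in pt$from) A[h, pt$to] <- A[h, pt$to] + pg$rate[k] * mult
  }
  A[absorbing_states(config$space), ] <- 0
  diag(A) <- 0
  diag(A) <- -rowSums(A)
  A
}

#' Read / write a simulation config as YAML
#' @param path file path.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(sim_config, y[intersect(names(y), names(formals(sim_config)))])
}

#' @rdname read_sim_config
#' @param config a [sim_config].
#' @export
write_sim_config <- function(config, path) {
  y <- unclass(config)
  y$space <- NULL
  y$n_subjects <- as.integer(y$n_subjects)
  # named vectors must become maps or YAML drops length-1 names
  for (lab in names(y$transitions))
    if (!is.null(y$transitions[[lab]]$beta))
      y$transitions[[lab]]$beta <- as.list(y$transitions[[lab]]$beta)
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}
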