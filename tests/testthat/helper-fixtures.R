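# Shared fixtures built in code.

# two-state pure-survival space
surv_space <- function(pension_age = 65) {
  state_space(c("W", "D"), c("transdurable", "absorbing"), "W->D", "W",
              pension_age)
}

# three-state illness-death space (W <-> S, both -> D)
illness_death_space <- function(pension_age = 60) {
  state_space(c("W", "S", "D"),
              c("transdurable", "transdurable", "absorbing"),
              c("W->S", "S->W", "W->D", "S->D"),
              wle_states = c("W", "S"), pension_age = pension_age)
}

# one well-formed three-episode subject in the Danish space
chain_df <- function() {
  data.frame(subject_id = "A",
             entry_age = c(55, 56, 56.5), exit_age = c(56, 56.5, 58),
             from_state = c("W", "S", "W"), to_state = c("S", "W", NA))
}

# covariate-free variant of the shipped scenario (true marginal Markov chain)
nocov_scenario <- function(n_subjects, member = TRUE, censor_rate = 0.02) {
  trs <- list("W->S" = list(rates = 0.12), "W->U" = list(rates = 0.10),
              "S->W" = list(rates = 2.0), "S->U" = list(rates = 0.10),
              "U->W" = list(rates = 0.80), "U->S" = list(rates = 0.10),
              "W+S+U->D" = list(rates = 0.005))
  if (member)
    trs[["W+S+U->E"]] <- list(breaks = 60, rates = c(0, 0.35))
  sim_config(n_subjects, trs, censor_rate = censor_rate)
}

# intensity series for a constant generator discretized on a uniform grid
discretized_series <- function(A, s, t, steps, space) {
  states <- rownames(A)
  tt <- seq(s, t, length.out = steps + 1L)[-1L]
  dA <- array(rep(A * (t - s) / steps, steps),
              c(nrow(A), nrow(A), steps),
              dimnames = list(states, states, NULL))
  structure(list(times = tt, states = states, dA = dA, n_eff = NULL,
                 combined_mode = "equal", space = space),
            class = "intensity_series")
}

# resample subjects with replacement, renumbering ids
bootstrap_cohort <- function(eh, space) {
  ids <- unique(eh$subject_id)
  samp <- sample(ids, replace = TRUE)
  pieces <- lapply(seq_along(samp), function(i) {
    d <- as.data.frame(eh)[eh$subject_id == samp[i], , drop = FALSE]
    d$subject_id <- i
    d
  })
  as_event_history(do.call(rbind, pieces), space)
}
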