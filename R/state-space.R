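#' Define a multi-state state space
#'
#' A state space names the labor-market states, their roles, the set of
#' modeled transitions (including combined-origin transitions estimated on a
#' pooled risk set), the subset of states whose occupation time counts toward
#' worklife expectancy, and the pension age at which follow-up is
#' administratively censored.
#'
#' Transitions are written `"W->S"` for a plain transition and `"W+S+U->D"`
#' for a combined transition whose hazard is estimated on the pooled risk set
#' of the origin states.
#'
#' @param states character vector of state labels.
#' @param roles character vector, same length as `states`; each element one of
#'   `"transdurable"` (recurrent entry/exit possible), `"absorbing"` (no exit),
#'   or `"auxiliary"` (transdurable but outside the primary analysis).
#'   Auxiliary absorbing states (death) use `"absorbing"` plus exclusion from
#'   `wle_states`.
#' @param transitions character vector of transition labels (see Details).
#' @param wle_states states whose expected occupation time is summed into WLE.
#' @param pension_age administrative censoring age in years.
#' @return An object of class `state_space`.
#' @examples
#' sp <- state_space(
#'   states = c("W", "S", "U", "D", "E"),
#'   roles = c("transdurable", "transdurable", "transdurable",
#'             "absorbing", "absorbing"),
#'   transitions = c("W->S", "W->U", "S->W", "S->U", "U->W", "U->S",
#'                   "W+S+U->D", "W+S+U->E"),
#'   wle_states = c("W", "S", "U"),
#'   pension_age = 65)
#' print(sp)
#' @export
state_space <- function(states, roles, transitions, wle_states, pension_age) {
  stopifnot(is.character(states), length(states) >= 1L,
            length(roles) == length(states),
            is.numeric(pension_age), length(pension_age) == 1L)
  roles <- match.arg(roles, c("transdurable", "absorbing", "auxiliary"),
                     several.ok = TRUE)
  if (anyDuplicated(states))
    stop("duplicate state labels: ",
         paste(unique(states[duplicated(states)]), collapse = ", "))
  names(roles) <- states
  trans <- lapply(transitions, parse_transition)
  for (tr in trans) {
    unknown <- setdiff(c(tr$from, tr$to), states)
    if (length(unknown))
      stop("transition '", tr$label, "' uses unknown state(s): ",
           paste(unknown, collapse = ", "))
    if (any(roles[tr$from] == "absorbing"))
      stop("transition '", tr$label, "' starts in an absorbing state")
    if (length(tr$from) > 1L && any(roles[tr$from] == "absorbing"))
      stop("combined transition '", tr$label, "' has an absorbing origin")
    if (length(tr$from) == 1L && tr$from == tr$to)
      stop("self-transition '", tr$label, "' is not allowed")
  }
  if (anyDuplicated(vapply(trans, `[[`, "", "label")))
    stop("duplicate transitions")
  transdurable <- states[roles != "absorbing"]
  if (!all(wle_states %in% transdurable))
    stop("wle_states must be a subset of the non-absorbing states")
  structure(
    list(states = states, roles = roles,
         transitions = trans, wle_states = wle_states,
         pension_age = as.numeric(pension_age)),
    class = "state_space")
}

parse_transition <- function(x) {
  if (is.list(x)) return(x)
  parts <- strsplit(x, "->", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop("malformed transition label: ", x)
  from <- strsplit(trimws(parts[1L]), "+", fixed = TRUE)[[1L]]
  list(from = trimws(from), to = trimws(parts[2L]),
       label = paste0(paste(trimws(from), collapse = "+"), "->",
                      trimws(parts[2L])))
}

#' @export
print.state_space <- function(x, ...) {
  cat("Multi-state state space (pension age ", x$pension_age, ")\n", sep = "")
  cat("  states:      ",
      paste(sprintf("%s[%s]", x$states, substr(x$roles, 1, 1)),
            collapse = " "), "\n")
  cat("  transitions: ",
      paste(vapply(x$transitions, `[[`, "", "label"), collapse = ", "), "\n")
  cat("  WLE states:  ", paste(x$wle_states, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname state_space
#' @param space a `state_space`.
#' @export
absorbing_states <- function(space) {
  space$states[space$roles == "absorbing"]
}

#' @rdname state_space
#' @export
transdurable_states <- function(space) {
  space$states[space$roles != "absorbing"]
}

transition_labels <- function(space) {
  vapply(space$transitions, `[[`, "", "label")
}

#  (from, to) -> transition label lookup, expanding combined origins.
transition_lookup <- function(space) {
  do.call(rbind, lapply(space$transitions, function(tr) {
    data.frame(from = tr$from, to = tr$to, label = tr$label,
               combined = length(tr$from) > 1L,
               stringsAsFactors = FALSE)
  }))
}

#' The Danish labor-market state space
#'
#' The default five-primary-state model of late-career labor-market
#' affiliation: work (W), sickness absence (S), unemployment (U), disability
#' pension (D) and voluntary early-retirement pension (E), with the eight
#' transitions W->S, W->U, S->W, S->U, U->W, U->S and the combined-origin
#' transitions \{W,S,U\}->D and \{W,S,U\}->E. D and E are absorbing; WLE counts
#' time in W, S and U; pension age is 65.
#'
#' @param erp if `FALSE`, the early-retirement state E and its transition are
#'   dropped (the model for employees without ERP-scheme membership).
#' @param include_death add an absorbing auxiliary `Death` state reachable
#'   from every transdurable state.
#' @param include_temp_out add a transdurable auxiliary `TO` (temporary out)
#'   state exchanging with W, S and U, excluded from WLE.
#' @param pension_age administrative censoring age (years).
#' @return A [state_space].
#' @examples
#' danish_labor_market()
#' danish_labor_market(erp = FALSE)
#' @export
danish_labor_market <- function(erp = TRUE, include_death = FALSE,
                                include_temp_out = FALSE, pension_age = 65) {
  states <- c("W", "S", "U", "D")
  roles <- c("transdurable", "transdurable", "transdurable", "absorbing")
  trans <- c("W->S", "W->U", "S->W", "S->U", "U->W", "U->S", "W+S+U->D")
  if (erp) {
    states <- c(states, "E"); roles <- c(roles, "absorbing")
    trans <- c(trans, "W+S+U->E")
  }
  if (include_temp_out) {
    states <- c(states, "TO"); roles <- c(roles, "auxiliary")
    trans <- c(trans, "W->TO", "S->TO", "U->TO", "TO->W", "TO->S", "TO->U")
  }
  if (include_death) {
    states <- c(states, "Death"); roles <- c(roles, "absorbing")
    from <- c("W", "S", "U", if (include_temp_out) "TO")
    trans <- c(trans, paste0(from, "->Death"))
  }
  state_space(states, roles, trans, wle_states = c("W", "S", "U"),
              pension_age = pension_age)
}

#' Read or write a state space as YAML
#'
#' The sidecar format holds `states` (label/role pairs), `transitions`,
#' `wle_states` and `pension_age`.
#'
#' @param path file path.
#' @return `read_state_space()` returns a [state_space]; `write_state_space()`
#'   returns `path` invisibly.
#' @export
read_state_space <- function(path) {
  y <- yaml::read_yaml(path)
  state_space(states = vapply(y$states, `[[`, "", "label"),
              roles = vapply(y$states, `[[`, "", "role"),
              transitions = unlist(y$transitions),
              wle_states = unlist(y$wle_states),
              pension_age = y$pension_age)
}

#' @rdname read_state_space
#' @param space a [state_space].
#' @export
write_state_space <- function(space, path) {
  y <- list(
    states = unname(Map(function(s, r) list(label = s, role = unname(r)),
                        space$states, space$roles)),
    transitions = as.list(transition_labels(space)),
    wle_states = as.list(space$wle_states),
    pension_age = space$pension_age)
  yaml::write_yaml(y, path)
  invisible(path)
}
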