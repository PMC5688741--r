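#' @keywords internal
CENSORED <- "CENSORED"

#' Construct and validate a multi-state event history
#'
#' An event history is a long-format (counting-process) table: one row per
#' subject-episode with a half-open age interval `[entry_age, exit_age)`, the
#' origin state, the destination state (or the reserved marker `"CENSORED"`),
#' episode-constant covariate values, and an optional nonnegative `weight`
#' (default 1). Episodes of one subject must be time-ordered, non-overlapping
#' and chained: each episode starts in the state the previous one ended in.
#' An event occurs at `exit_age`; episodes reaching the state space's
#' `pension_age` are administratively truncated there and censored.
#'
#' @param data a data.frame with columns `subject_id`, `entry_age`,
#'   `exit_age`, `from_state`, `to_state`, optional `weight`, and any number
#'   of covariate columns.
#' @param space a [state_space] the states and transitions are checked
#'   against.
#' @param truncate_at_pension truncate episodes at `space$pension_age`
#'   (default `TRUE`).
#' @return The validated data.frame with class `event_history` and the state
#'   space attached as attribute `space`. Destination markers `NA`, `""` and
#'   `"CENSORED"` (any case) are normalized to `"CENSORED"`.
#' @examples
#' eh <- as_event_history(data.frame(
#'   subject_id = 1, entry_age = c(55, 56, 56.5),
#'   exit_age = c(56, 56.5, 58),
#'   from_state = c("W", "S", "W"), to_state = c("S", "W", NA)),
#'   danish_labor_market())
#' nrow(eh)
#' @export
as_event_history <- function(data, space, truncate_at_pension = TRUE) {
  req <- c("subject_id", "entry_age", "exit_age", "from_state", "to_state")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$from_state <- as.character(data$from_state)
  data$to_state <- as.character(data$to_state)
  cens <- is.na(data$to_state) | data$to_state == "" |
    toupper(data$to_state) == CENSORED
  data$to_state[cens] <- CENSORED
  if (is.null(data$weight)) data$weight <- rep(1, nrow(data))
  if (any(data$weight < 0)) stop("negative episode weights")

  if (truncate_at_pension) {
    drop <- data$entry_age >= space$pension_age
    data <- data[!drop, , drop = FALSE]
    over <- data$exit_age > space$pension_age
    data$exit_age[over] <- space$pension_age
    data$to_state[over] <- CENSORED
  }
  if (nrow(data) == 0L) {
    class(data) <- c("event_history", class(data))
    attr(data, "space") <- space
    return(data)
  }

  known <- c(space$states, CENSORED)
  bad <- which(!(data$from_state %in% space$states) |
                 !(data$to_state %in% known))
  if (length(bad))
    stop("unknown state label(s) in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (subject ", data$subject_id[bad[1L]], ")")
  bad <- which(data$from_state %in% absorbing_states(space))
  if (length(bad))
    stop("episode starts in absorbing state: subject ",
         data$subject_id[bad[1L]], ", row ", bad[1L])
  bad <- which(data$exit_age <= data$entry_age)
  if (length(bad))
    stop("exit_age <= entry_age: subject ", data$subject_id[bad[1L]],
         ", row ", bad[1L])

  # observed events must be modeled transitions
  lk <- transition_lookup(space)
  ev <- data$to_state != CENSORED
  key <- paste(data$from_state, data$to_state, sep = "->")
  bad <- which(ev & !(key %in% paste(lk$from, lk$to, sep = "->")))
  if (length(bad))
    stop("event ", key[bad[1L]], " (subject ", data$subject_id[bad[1L]],
         ", row ", bad[1L], ") is not a transition of the state space")

  ord <- order(data$subject_id, data$entry_age)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  sid <- data$subject_id
  prev <- c(NA, sid[-length(sid)]) == sid  # row follows same subject
  prev[1L] <- FALSE
  if (any(prev)) {
    i <- which(prev)
    gap <- data$entry_age[i] - data$exit_age[i - 1L]
    if (any(gap < -1e-9))
      stop("overlapping episodes: subject ", sid[i[which(gap < -1e-9)[1L]]])
    pc <- data$to_state[i - 1L] == CENSORED
    if (any(pc))
      stop("episode follows censoring: subject ", sid[i[which(pc)[1L]]])
    broken <- data$from_state[i] != data$to_state[i - 1L]
    if (any(broken))
      stop("broken state chain: subject ", sid[i[which(broken)[1L]]],
           " enters ", data$from_state[i[which(broken)[1L]]],
           " after ending in ", data$to_state[i[which(broken)[1L]] - 1L])
  }
  class(data) <- c("event_history", "data.frame")
  attr(data, "space") <- space
  data
}

#' Read / write an event history as CSV
#'
#' The file is comma-delimited with a header row; destination is empty or
#' `"CENSORED"` for censoring; ages are decimal years. A `schema` renames
#' non-standard column headers to the required ones.
#'
#' @param path CSV file path.
#' @param space a [state_space], or a path to its YAML sidecar
#'   (see [read_state_space]).
#' @param schema optional named character vector mapping required names to
#'   file column names, e.g. `c(subject_id = "id", entry_age = "start")`.
#' @param ... passed to [as_event_history].
#' @return [read_event_history]: a validated `event_history`.
#' @examples
#' csv <- system.file("extdata", "example_cohort.csv", package = "worklife")
#' yml <- system.file("extdata", "example_statespace.yaml",
#'                    package = "worklife")
#' eh <- read_event_history(csv, yml)
#' head(eh)
#' @export
read_event_history <- function(path, space, schema = NULL, ...) {
  if (is.character(space)) space <- read_state_space(space)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(df))
        stop("schema column '", schema[[std]], "' not in file")
      names(df)[names(df) == schema[[std]]] <- std
    }
  }
  if (nrow(df) == 0L)
    return(as_event_history(
      data.frame(subject_id = character(), entry_age = numeric(),
                 exit_age = numeric(), from_state = character(),
                 to_state = character()), space, ...))
  as_event_history(df, space, ...)
}

#' @rdname read_event_history
#' @param records an `event_history`.
#' @export
write_event_history <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

covariate_names <- function(records) {
  setdiff(names(records), c("subject_id", "entry_age", "exit_age",
                            "from_state", "to_state", "weight"))
}

# weighted count of v strictly below each t (v, w episode vectors)
wcount_less <- function(v, w, t) {
  o <- order(v)
  cw <- c(0, cumsum(w[o]))
  cw[findInterval(t, v[o], left.open = TRUE) + 1L]
}

#' Build weighted risk-set and event-count tables
#'
#' For every distinct event age t and modeled transition h->j this tabulates
#' the (weighted) number of transitions d_hj(t) and the (weighted) number at
#' risk n_h(t), where an episode is at risk in its origin state for
#' `entry_age < t <= exit_age`. Combined-origin transitions use the pooled
#' risk set (sum of the origin states' n).
#'
#' @param records an `event_history` (see [as_event_history]).
#' @param space a [state_space]; defaults to the one attached to `records`.
#' @return A `risk_set_table`: list with `times` (sorted distinct event ages),
#'   `states`, `n` (times x states matrix of at-risk weights), `events` (data
#'   frame `time`, `trans`, `d`, `n`) and `origin_totals` (whole-follow-up
#'   event counts per origin for combined transitions).
#' @examples
#' eh <- as_event_history(data.frame(
#'   subject_id = c("A", "B", "C"), entry_age = 55,
#'   exit_age = c(56, 57, 55.5),
#'   from_state = c("W", "W", "S"), to_state = c("S", NA, "W")),
#'   danish_labor_market())
#' rs <- build_risk_sets(eh)
#' subset(rs$events, time == 56)  # n_W = 2, d = 1 for W->S
#' @export
build_risk_sets <- function(records, space = attr(records, "space")) {
  stopifnot(inherits(records, "event_history"))
  w <- records$weight
  states <- space$states
  ev <- records$to_state != CENSORED
  times <- sort(unique(records$exit_age[ev]))
  n <- matrix(0, length(times), length(states),
              dimnames = list(NULL, states))
  for (h in states) {
    in_h <- records$from_state == h
    if (!any(in_h)) next
    n[, h] <- wcount_less(records$entry_age[in_h], w[in_h], times) -
      wcount_less(records$exit_age[in_h], w[in_h], times)
  }
  lk <- transition_lookup(space)
  key <- paste(records$from_state, records$to_state, sep = "->")
  lab <- lk$label[match(key, paste(lk$from, lk$to, sep = "->"))]
  evd <- data.frame(time = records$exit_age[ev], trans = lab[ev],
                    origin = records$from_state[ev], d = w[ev])
  if (nrow(evd) == 0L) {
    events <- data.frame(time = numeric(0), trans = character(0),
                         d = numeric(0), n = numeric(0))
    ot <- data.frame(trans = character(0), origin = character(0),
                     d = numeric(0))
    return(structure(list(times = times, states = states, n = n,
                          events = events, origin_totals = ot,
                          space = space),
                     class = "risk_set_table"))
  }
  events <- stats::aggregate(d ~ time + trans, data = evd, FUN = sum)
  events <- events[order(events$time, events$trans), , drop = FALSE]
  origins <- lapply(space$transitions, `[[`, "from")
  names(origins) <- transition_labels(space)
  ki <- match(events$time, times)
  events$n <- vapply(seq_len(nrow(events)), function(i) {
    sum(n[ki[i], origins[[events$trans[i]]]])
  }, numeric(1))
  if (any(events$d > events$n + 1e-9))
    stop("internal error: d exceeds n in risk-set table")
  ot <- stats::aggregate(d ~ trans + origin, data = evd, FUN = sum)
  ot <- ot[ot$trans %in% names(origins)[vapply(origins, length, 1L) > 1L], ,
           drop = FALSE]
  rownames(events) <- rownames(ot) <- NULL
  structure(list(times = times, states = states, n = n, events = events,
                 origin_totals = ot, space = space),
            class = "risk_set_table")
}

#' @export
print.risk_set_table <- function(x, ...) {
  cat("Risk-set table: ", length(x$times), " event ages, ",
      nrow(x$events), " (time, transition) event rows\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
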