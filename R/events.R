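# Event-log data model, I/O, the 2-second priority rule and sociomatrix
# construction.

# Validate an event data.frame in place; stops with row-numbered messages.
validate_events <- function(events) {
  required <- c("cohort", "day", "actor", "recipient", "behavior")
  missing <- setdiff(required, names(events))
  if (length(missing) > 0L)
    stop("event log is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(events) == 0L) return(invisible(events))
  bad <- which(!events$behavior %in% ethogram())
  if (length(bad) > 0L)
    stop("unknown behavior label(s) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), ": ",
         paste(unique(events$behavior[utils::head(bad, 5L)]), collapse = ", "),
         call. = FALSE)
  self <- which(as.character(events$actor) == as.character(events$recipient))
  if (length(self) > 0L)
    stop("actor equals recipient at row(s) ",
         paste(utils::head(self, 5L), collapse = ", "), call. = FALSE)
  if (any(is.na(events$day)) || any(events$day < 1))
    stop("day must be a 1-based positive integer", call. = FALSE)
  invisible(events)
}

#' Read an agonistic event log
#'
#' Reads a CSV of timed winner/loser interactions. Each row records one
#' agonistic event: the cohort, the observation day (1-based), an optional
#' within-session time in seconds, the winner (`actor`), the loser
#' (`recipient`) and the behavior, one of [ethogram()]. The winner is the
#' animal that fought, chased, mounted, or forced the other to display a
#' subordinate posture or to flee.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping the standard column
#'   names (`cohort`, `day`, `time_s`, `actor`, `recipient`, `behavior`) to
#'   the names used in the file, e.g. `c(actor = "winner", recipient =
#'   "loser")`.
#' @return A data.frame of events with the standard column names, stably
#'   sorted by cohort, day and (when present) time.
#' @seealso [apply_priority_rule()], [build_win_loss_matrix()]
#' @export
read_event_log <- function(path, schema = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  std <- c("cohort", "day", "time_s", "actor", "recipient", "behavior")
  map <- stats::setNames(std, std)
  if (!is.null(schema)) {
    unknown <- setdiff(names(schema), std)
    if (length(unknown) > 0L)
      stop("schema maps unknown field(s): ", paste(unknown, collapse = ", "))
    map[names(schema)] <- schema
  }
  required <- setdiff(std, "time_s")
  for (col in required) {
    if (!map[[col]] %in% names(raw))
      stop("event log is missing required column: ", map[[col]], call. = FALSE)
  }
  events <- data.frame(
    cohort = as.character(raw[[map["cohort"]]]),
    day = as.integer(raw[[map["day"]]]),
    actor = as.character(raw[[map["actor"]]]),
    recipient = as.character(raw[[map["recipient"]]]),
    behavior = as.character(raw[[map["behavior"]]]),
    stringsAsFactors = FALSE
  )
  events$time_s <- if (map[["time_s"]] %in% names(raw))
    as.numeric(raw[[map["time_s"]]]) else NA_real_
  events <- events[, std]
  validate_events(events)
  sort_events(events)
}

# Stable sort by (cohort, day, time_s); NA times sort last within a day.
sort_events <- function(events) {
  if (nrow(events) == 0L) return(events)
  ord <- order(events$cohort, events$day, events$time_s,
               seq_len(nrow(events)), method = "radix")
  out <- events[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve co-occurring behaviors with the priority rule
#'
#' When several behaviors between the same pair of animals co-occur within a
#' short window (2 seconds by default), only a single event is recorded, with
#' priority fighting > chasing > mounting > subordinate posture > induced
#' flee. The window is anchored at the earliest event of each same-dyad
#' cluster and the whole cluster resolves to one event carrying the anchor
#' time, which makes the rule deterministic and idempotent.
#'
#' @param events Event data.frame as returned by [read_event_log()]; all
#'   events must carry `time_s`.
#' @param window_s Co-occurrence window in seconds (default 2).
#' @return The resolved event data.frame, time-sorted.
#' @export
apply_priority_rule <- function(events, window_s = 2) {
  validate_events(events)
  if (nrow(events) == 0L) return(events)
  if (any(is.na(events$time_s)))
    stop("events lack time_s; skip the priority rule for untimed logs",
         call. = FALSE)
  if (window_s < 0) stop("window_s must be non-negative")
  events <- sort_events(events)
  pair <- ifelse(events$actor < events$recipient,
                 paste(events$actor, events$recipient, sep = "|"),
                 paste(events$recipient, events$actor, sep = "|"))
  key <- paste(events$cohort, events$day, pair, sep = "\r")
  prio <- match(events$behavior, ethogram())
  keep <- logical(nrow(events))
  new_time <- events$time_s
  for (k in unique(key)) {
    idx <- which(key == k)               # already time-sorted
    i <- 1L
    while (i <= length(idx)) {
      anchor <- events$time_s[idx[i]]
      in_win <- idx[events$time_s[idx] >= anchor &
                    events$time_s[idx] <= anchor + window_s]
      in_win <- in_win[in_win >= idx[i]]
      best <- in_win[which.min(prio[in_win])]
      keep[best] <- TRUE
      new_time[best] <- anchor
      i <- i + length(in_win)
    }
  }
  out <- events[keep, , drop = FALSE]
  out$time_s <- new_time[keep]
  sort_events(out)
}

#' Build a win/loss sociomatrix from events
#'
#' Counts, for every ordered pair of individuals, the number of events the
#' row individual won against the column individual, optionally restricted
#' to a subset of behaviors.
#'
#' @param events Event data.frame.
#' @param behaviors Behaviors to count; default all of [ethogram()].
#' @param ids Optional fixed ordering of individuals; individuals with no
#'   events still appear. Defaults to the sorted set of ids in `events`.
#' @return An integer matrix with `ids` as dimnames; entry (i, j) is the
#'   number of wins of i over j. Diagonal is zero.
#' @export
build_win_loss_matrix <- function(events, behaviors = ethogram(), ids = NULL) {
  validate_events(events)
  bad <- setdiff(behaviors, ethogram())
  if (length(bad) > 0L)
    stop("unknown behavior(s): ", paste(bad, collapse = ", "))
  ev <- events[events$behavior %in% behaviors, , drop = FALSE]
  seen <- unique(c(events$actor, events$recipient))
  if (is.null(ids)) {
    ids <- sort(seen)
  } else {
    unknown <- setdiff(seen, ids)
    if (length(unknown) > 0L)
      stop("events contain id(s) not in the fixed ordering: ",
           paste(unknown, collapse = ", "))
  }
  n <- length(ids)
  W <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (nrow(ev) > 0L) {
    tab <- table(factor(ev$actor, levels = ids),
                 factor(ev$recipient, levels = ids))
    W <- W + unclass(tab)
    storage.mode(W) <- "integer"
    dimnames(W) <- list(ids, ids)
  }
  W
}

#' Cumulative sociomatrix through a given day
#'
#' @param events Event data.frame.
#' @param d Last day to include (1-based).
#' @param behaviors,ids Passed to [build_win_loss_matrix()]; `ids` defaults
#'   to all individuals in the full log so matrices for successive days are
#'   conformable.
#' @return Win/loss matrix of all events with `day <= d`.
#' @export
cumulative_matrix_through_day <- function(events, d, behaviors = ethogram(),
                                          ids = NULL) {
  if (d < 1) stop("d must be >= 1")
  validate_events(events)
  if (is.null(ids)) ids <- sort(unique(c(events$actor, events$recipient)))
  build_win_loss_matrix(events[events$day <= d, , drop = FALSE],
                        behaviors = behaviors, ids = ids)
}

#' Observation schedule
#'
#' Hours of live observation per day. Groups were observed for a fixed
#' number of hours each day of the housing period (2 h/day over 14 days by
#' default).
#'
#' @param n_days Number of observation days.
#' @param hours_per_day Observed hours per day; either a scalar or a vector
#'   of length `n_days`.
#' @return data.frame with columns `day` and `hours`.
#' @export
observation_schedule <- function(n_days = 14, hours_per_day = 2) {
  if (any(hours_per_day <= 0)) stop("hours_per_day must be positive")
  data.frame(day = seq_len(n_days),
             hours = rep_len(hours_per_day, n_days))
}

#' Hourly behavior rates
#'
#' Events per observed hour, grouped by individual, rank, day or behavior,
#' counting events given (as winner) or received (as loser). Cells with zero
#' events are reported as 0, not dropped.
#'
#' @param events Event data.frame (a single cohort).
#' @param schedule Observation schedule from [observation_schedule()]; must
#'   cover every day present in `events`.
#' @param group_by One of `"individual"`, `"rank"`, `"day"`, `"behavior"`.
#' @param direction `"given"` (count as actor) or `"received"` (as
#'   recipient).
#' @param ranking Ordered vector of ids (rank 1 first); required for
#'   `group_by = "rank"`.
#' @param ids Individuals to report for `group_by = "individual"`; default
#'   all ids present.
#' @return data.frame with the grouping column, `events`, `hours`, `rate`.
#' @export
hourly_rates <- function(events, schedule = observation_schedule(),
                         group_by = c("individual", "rank", "day", "behavior"),
                         direction = c("given", "received"),
                         ranking = NULL, ids = NULL) {
  group_by <- match.arg(group_by)
  direction <- match.arg(direction)
  validate_events(events)
  days_seen <- unique(events$day)
  if (length(setdiff(days_seen, schedule$day)) > 0L)
    stop("event day(s) not covered by the schedule: ",
         paste(setdiff(days_seen, schedule$day), collapse = ", "))
  total_hours <- sum(schedule$hours)
  who <- if (direction == "given") events$actor else events$recipient

  if (group_by == "day") {
    counts <- table(factor(events$day, levels = schedule$day))
    out <- data.frame(day = schedule$day,
                      events = as.integer(counts),
                      hours = schedule$hours)
  } else if (group_by == "behavior") {
    counts <- table(factor(events$behavior, levels = ethogram()))
    out <- data.frame(behavior = ethogram(),
                      events = as.integer(counts),
                      hours = total_hours)
  } else if (group_by == "individual") {
    if (is.null(ids)) ids <- sort(unique(c(events$actor, events$recipient)))
    counts <- table(factor(who, levels = ids))
    out <- data.frame(individual = ids,
                      events = as.integer(counts),
                      hours = total_hours)
  } else { # rank
    if (is.null(ranking)) stop("group_by = 'rank' requires a ranking")
    rk <- match(who, ranking)
    if (any(is.na(rk)))
      stop("events contain individuals missing from the ranking")
    counts <- table(factor(rk, levels = seq_along(ranking)))
    out <- data.frame(rank = seq_along(ranking),
                      individual = ranking,
                      events = as.integer(counts),
                      hours = total_hours)
  }
  out$rate <- out$events / out$hours
  rownames(out) <- NULL
  out
}
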