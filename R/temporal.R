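# Hierarchy emergence by day and estrous-state descriptive summaries.

#' Hierarchy emergence day by day
#'
#' For each observation day, computes Landau's modified h' and triangle
#' transitivity on the win/loss matrix aggregated up to that day, with
#' randomization p-values, and flags days on which the cumulative hierarchy
#' is significantly linear. `first_stable_day` is the earliest day from
#' which the h' significance flag holds through the final day (NA if never):
#' a significant day followed by loss of significance does not qualify.
#'
#' @param events Event data.frame (one cohort).
#' @param n_days Number of days to evaluate; default the schedule length
#'   implied by the data (max observed day).
#' @param M Randomizations per p-value.
#' @param n_resolutions Random resolutions for h'.
#' @param alpha Significance level for the flags (default 0.05).
#' @param behaviors Behaviors entering the matrix.
#' @param seed Optional RNG seed.
#' @return Object of class `emergence_table`: data.frame with columns `day`,
#'   `n_events`, `h_prime`, `p_h`, `ttri`, `p_ttri`, `sig_h`, `sig_ttri`,
#'   with attribute `first_stable_day`.
#' @export
emergence_by_day <- function(events, n_days = NULL, M = 1000,
                             n_resolutions = 100, alpha = 0.05,
                             behaviors = ethogram(), seed = NULL) {
  validate_events(events)
  if (length(unique(events$cohort)) > 1L)
    stop("emergence_by_day expects a single cohort")
  if (is.null(n_days)) n_days <- max(events$day, 1L)
  ids <- sort(unique(c(events$actor, events$recipient)))
  seeds <- derive_seeds(seed, 2L * n_days)
  rows <- lapply(seq_len(n_days), function(d) {
    W <- cumulative_matrix_through_day(events, d, behaviors = behaviors,
                                       ids = ids)
    row <- data.frame(day = d, n_events = sum(W),
                      h_prime = NA_real_, p_h = NA_real_,
                      ttri = NA_real_, p_ttri = NA_real_)
    if (length(ids) >= 3L && sum(W) > 0) {
      row$h_prime <- landaus_h_prime(W, n_resolutions, seed = seeds[2 * d - 1])
      row$p_h <- as.numeric(randomization_p(
        W, "h_prime", M = M, seed = seeds[2 * d - 1],
        n_resolutions = n_resolutions))
      tt <- triangle_transitivity(W)
      row$ttri <- tt$ttri
      if (!is.na(tt$ttri))
        row$p_ttri <- as.numeric(randomization_p(W, "ttri", M = M,
                                                 seed = seeds[2 * d]))
    }
    row
  })
  out <- do.call(rbind, rows)
  out$sig_h <- !is.na(out$p_h) & out$p_h <= alpha
  out$sig_ttri <- !is.na(out$p_ttri) & out$p_ttri <= alpha
  # earliest day whose h' significance persists through the final day
  stable <- NA_integer_
  for (d in rev(seq_len(n_days))) {
    if (out$sig_h[d]) stable <- d else break
  }
  structure(out, first_stable_day = stable, alpha = alpha,
            class = c("emergence_table", "data.frame"))
}

#' @export
print.emergence_table <- function(x, digits = 3, ...) {
  cat("Hierarchy emergence by day (alpha =", attr(x, "alpha"), ")\n")
  print.data.frame(x, digits = digits, row.names = FALSE, ...)
  fsd <- attr(x, "first_stable_day")
  cat("First stable day (h' significant through the end):",
      if (is.na(fsd)) "never" else fsd, "\n")
  invisible(x)
}

estrus_states <- function() {
  c("proestrus", "estrus", "metestrus", "diestrus", "undetermined")
}

validate_estrus <- function(records) {
  required <- c("cohort", "individual", "day", "state")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L)
    stop("estrus log is missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(!records$state %in% estrus_states())
  if (length(bad) > 0L)
    stop("unknown estrus state at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  key <- paste(records$cohort, records$individual, records$day)
  if (anyDuplicated(key))
    stop("duplicate (cohort, individual, day) estrus records")
  invisible(records)
}

#' Read an estrous-state log
#'
#' CSV with columns cohort, individual, day, state; one daily vaginal-smear
#' call per animal, state one of proestrus, estrus, metestrus, diestrus or
#' undetermined.
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
read_estrus_log <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  rec$day <- as.integer(rec$day)
  validate_estrus(rec)
  rec
}

#' Per-individual estrous-state proportions
#'
#' Proportion of determined smear days each individual spent in each of the
#' four cycle states. Undetermined days are excluded from the denominator
#' and reported separately; an individual with only undetermined smears gets
#' NA proportions.
#'
#' @param records Estrus record data.frame.
#' @return data.frame, one row per (cohort, individual), with the four state
#'   proportions, `n_determined` and `n_undetermined`.
#' @export
estrus_proportions <- function(records) {
  validate_estrus(records)
  states <- setdiff(estrus_states(), "undetermined")
  key <- unique(records[, c("cohort", "individual")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    rec <- records[records$cohort == key$cohort[i] &
                   records$individual == key$individual[i], ]
    det <- rec$state[rec$state != "undetermined"]
    props <- if (length(det) > 0)
      as.numeric(table(factor(det, levels = states))) / length(det)
    else rep(NA_real_, length(states))
    out <- data.frame(cohort = key$cohort[i], individual = key$individual[i],
                      n_determined = length(det),
                      n_undetermined = sum(rec$state == "undetermined"),
                      stringsAsFactors = FALSE)
    out[states] <- as.list(props)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank-by-state day-count crosstab
#'
#' Counts determined individual-days in each estrous state per dominance
#' rank. Margins equal the total number of determined days.
#'
#' @param records Estrus record data.frame (one cohort).
#' @param ranking Ordered ids (rank 1 = most dominant); must cover every
#'   individual in `records`.
#' @return Integer matrix ranks x states (four determined states).
#' @export
estrus_rank_crosstab <- function(records, ranking) {
  validate_estrus(records)
  if (!all(unique(records$individual) %in% ranking))
    stop("ranking must cover every individual in the records")
  det <- records[records$state != "undetermined", ]
  states <- setdiff(estrus_states(), "undetermined")
  tab <- table(rank = factor(match(det$individual, ranking),
                             levels = seq_along(ranking)),
               state = factor(det$state, levels = states))
  unclass(tab)
}

#' Hourly behavior rates by estrous state
#'
#' Assigns every individual-day's hourly rate of each behavior (given or
#' received) to that day's estrous state and summarises the rates per state
#' and behavior with medians and interquartile ranges. Days without an
#' estrus record are excluded (count reported in the `n_excluded_days`
#' attribute). Purely descriptive: no model is fitted.
#'
#' @param events Event data.frame (one cohort).
#' @param records Estrus record data.frame for the same cohort.
#' @param schedule Observation schedule covering the event days.
#' @param direction `"given"` or `"received"`.
#' @param behaviors Behaviors to summarise.
#' @return data.frame with columns `state`, `behavior`, `n_days`, `median`,
#'   `q1`, `q3`.
#' @export
rates_by_estrus_state <- function(events, records,
                                  schedule = observation_schedule(),
                                  direction = c("given", "received"),
                                  behaviors = ethogram()) {
  direction <- match.arg(direction)
  validate_events(events)
  validate_estrus(records)
  days_seen <- unique(events$day)
  if (length(setdiff(days_seen, schedule$day)) > 0L)
    stop("event day(s) not covered by the schedule")
  ids <- sort(unique(c(events$actor, events$recipient)))
  who <- if (direction == "given") events$actor else events$recipient
  # one cell per individual-day-behavior; attach that day's state
  grid <- expand.grid(individual = ids, day = schedule$day,
                      behavior = behaviors, stringsAsFactors = FALSE)
  cnt <- table(factor(who, levels = ids),
               factor(events$day, levels = schedule$day),
               factor(events$behavior, levels = behaviors))
  grid$count <- as.vector(cnt)
  grid$hours <- schedule$hours[match(grid$day, schedule$day)]
  grid$rate <- grid$count / grid$hours
  key <- paste(records$individual, records$day)
  grid$state <- records$state[match(paste(grid$individual, grid$day), key)]
  excluded <- sum(is.na(grid$state)) / length(behaviors)
  grid <- grid[!is.na(grid$state) & grid$state != "undetermined", ]
  states <- setdiff(estrus_states(), "undetermined")
  cells <- expand.grid(state = states, behavior = behaviors,
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    r <- grid$rate[grid$state == cells$state[i] &
                   grid$behavior == cells$behavior[i]]
    qs <- if (length(r) > 0) stats::quantile(r, c(0.25, 0.5, 0.75),
                                             names = FALSE)
          else rep(NA_real_, 3)
    data.frame(state = cells$state[i], behavior = cells$behavior[i],
               n_days = length(r), median = qs[2], q1 = qs[1], q3 = qs[3],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, n_excluded_days = excluded)
}
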