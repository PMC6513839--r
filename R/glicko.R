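# Event-by-event Glicko ratings: every behavioral interaction is one rating
# period, so the deviation-inflation constant applies per event to all group
# members and the two participants receive the standard one-game update.

#' Glicko configuration
#'
#' All individuals start at rating 2200 with deviation 300; before each
#' rating period every deviation is inflated by the constant `c` (capped at
#' `deviation_cap`) so that ratings of inactive animals become less certain
#' over time. `q = ln(10)/400` is the Glicko scale constant.
#'
#' @param initial_rating Starting rating (default 2200).
#' @param initial_deviation Starting rating deviation (default 300).
#' @param c Per-period deviation inflation constant (default 3).
#' @param deviation_cap Upper bound on deviation (default 350).
#' @return list of class `glicko_config`.
#' @export
glicko_config <- function(initial_rating = 2200, initial_deviation = 300,
                          c = 3, deviation_cap = 350) {
  stopifnot(initial_rating > 0, initial_deviation > 0, c >= 0,
            initial_deviation <= deviation_cap)
  structure(list(initial_rating = initial_rating,
                 initial_deviation = initial_deviation,
                 c = c, deviation_cap = deviation_cap,
                 q = log(10) / 400),
            class = "glicko_config")
}

#' Initialise Glicko states
#'
#' @param ids Unique individual labels.
#' @param config A [glicko_config()].
#' @return list with named numeric vectors `rating` and `deviation`.
#' @export
glicko_init <- function(ids, config = glicko_config()) {
  if (anyDuplicated(ids)) stop("duplicate ids")
  list(rating = stats::setNames(rep(config$initial_rating, length(ids)), ids),
       deviation = stats::setNames(rep(config$initial_deviation,
                                       length(ids)), ids))
}

#' One Glicko rating period (one event)
#'
#' Every individual's deviation is first inflated to
#' \eqn{min(\sqrt{RD^2 + c^2}, cap)}; the winner and loser then receive the
#' standard Glicko one-game update with scores 1 and 0:
#' \eqn{g(RD) = 1/\sqrt{1 + 3 q^2 RD^2/\pi^2}},
#' \eqn{E = 1/(1 + 10^{-g(RD_{opp})(r - r_{opp})/400})},
#' \eqn{d^{-2} = q^2 g(RD_{opp})^2 E (1-E)},
#' \eqn{r' = r + \frac{q}{RD^{-2} + d^{-2}} g(RD_{opp}) (s - E)},
#' \eqn{RD' = \sqrt{1/(RD^{-2} + d^{-2})}}. Non-participants keep their
#' inflated deviation and unchanged rating.
#'
#' @param states States from [glicko_init()] or a previous update.
#' @param winner,loser Ids of the two participants.
#' @param config A [glicko_config()].
#' @return Updated states.
#' @export
glicko_update <- function(states, winner, loser, config = glicko_config()) {
  ids <- names(states$rating)
  if (!winner %in% ids || !loser %in% ids)
    stop("unknown id in event: ", winner, " vs ", loser)
  if (winner == loser) stop("winner and loser must differ")
  q <- config$q
  rd <- pmin(sqrt(states$deviation^2 + config$c^2), config$deviation_cap)
  r <- states$rating
  g <- function(x) 1 / sqrt(1 + 3 * q^2 * x^2 / pi^2)
  upd <- function(self, opp, score) {
    gopp <- g(rd[opp])
    E <- 1 / (1 + 10^(-gopp * (r[self] - r[opp]) / 400))
    dinv2 <- q^2 * gopp^2 * E * (1 - E)
    denom <- 1 / rd[self]^2 + dinv2
    c(rating = unname(r[self] + q / denom * gopp * (score - E)),
      deviation = unname(sqrt(1 / denom)))
  }
  w <- upd(winner, loser, 1)
  l <- upd(loser, winner, 0)
  states$deviation <- rd
  states$rating[winner] <- w["rating"]
  states$deviation[winner] <- w["deviation"]
  states$rating[loser] <- l["rating"]
  states$deviation[loser] <- l["deviation"]
  states
}

#' Glicko rating trajectory over an event log
#'
#' Applies [glicko_update()] sequentially over an ordered event log,
#' recording every individual's rating and deviation after each event, plus
#' the rank order by current rating (ties broken by rating, then total wins
#' so far, then label).
#'
#' @param events Ordered event data.frame (one cohort).
#' @param config A [glicko_config()].
#' @param ids Individuals to track; default all ids in `events`.
#' @return Object of class `glicko_trajectory`: list with matrices `rating`
#'   and `deviation` ((n_events + 1) x N, row 1 = initial state), the final
#'   `states`, the `final_order` (ids, most dominant first) and the events'
#'   winner/loser columns.
#' @export
glicko_trajectory <- function(events, config = glicko_config(), ids = NULL) {
  validate_events(events)
  if (length(unique(events$cohort)) > 1L)
    stop("glicko_trajectory expects a single cohort; split the log first")
  if (is.null(ids)) ids <- sort(unique(c(events$actor, events$recipient)))
  events <- sort_events(events)
  states <- glicko_init(ids, config)
  ne <- nrow(events)
  ratings <- matrix(NA_real_, ne + 1L, length(ids),
                    dimnames = list(NULL, ids))
  deviations <- ratings
  ratings[1L, ] <- states$rating
  deviations[1L, ] <- states$deviation
  wins <- stats::setNames(numeric(length(ids)), ids)
  for (e in seq_len(ne)) {
    states <- glicko_update(states, events$actor[e], events$recipient[e],
                            config)
    wins[events$actor[e]] <- wins[events$actor[e]] + 1
    ratings[e + 1L, ] <- states$rating
    deviations[e + 1L, ] <- states$deviation
  }
  final_order <- order_ids(ids, states$rating, wins)
  structure(list(rating = ratings, deviation = deviations,
                 states = states, final_order = final_order,
                 wins = wins, ids = ids,
                 events = events[, c("day", "actor", "recipient",
                                     "behavior")],
                 config = config),
            class = "glicko_trajectory")
}

#' @export
print.glicko_trajectory <- function(x, ...) {
  cat("Glicko trajectory:", length(x$ids), "individuals,",
      nrow(x$rating) - 1L, "events\n")
  cat("Final order:", paste(x$final_order, collapse = " > "), "\n")
  fr <- x$states$rating[x$final_order]
  print(round(fr))
  invisible(x)
}

#' Long-format trajectory table
#'
#' @param x A `glicko_trajectory`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments.
#' @return data.frame with columns `event_index` (0 = initial state),
#'   `individual`, `rating`, `deviation`, `rank`.
#' @export
as.data.frame.glicko_trajectory <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  ne <- nrow(x$rating)
  n <- length(x$ids)
  rk <- t(apply(x$rating, 1L, function(r) rank(-r, ties.method = "min")))
  data.frame(event_index = rep(0:(ne - 1L), each = n),
             individual = rep(x$ids, times = ne),
             rating = as.vector(t(x$rating)),
             deviation = as.vector(t(x$deviation)),
             rank = as.vector(t(rk)),
             row.names = row.names, stringsAsFactors = FALSE)
}

#' Select the most dominant and most subordinate individuals
#'
#' Picks the top-k and bottom-k animals by final Glicko rating and checks
#' whether the same sets arise from the normalised David's-score ordering;
#' on disagreement both candidate sets are reported.
#'
#' @param trajectory A [glicko_trajectory()].
#' @param ds A [davids_scores()] table for the same individuals.
#' @param k Number of animals at each end (default 2).
#' @return list with `dominant`, `subordinate` (Glicko-based), `agreement`
#'   flag, and the David's-score candidates `dominant_ds`, `subordinate_ds`.
#' @export
select_dom_sub <- function(trajectory, ds, k = 2) {
  ids <- trajectory$ids
  if (k > length(ids) / 2) stop("k must be at most N/2")
  if (k == 0)
    return(list(dominant = character(0), subordinate = character(0),
                agreement = TRUE,
                dominant_ds = character(0), subordinate_ds = character(0)))
  g_order <- trajectory$final_order
  ds_order <- ds$id[order(ds$ds_rank)]
  top_g <- g_order[seq_len(k)]
  bot_g <- rev(g_order)[seq_len(k)]
  top_d <- ds_order[seq_len(k)]
  bot_d <- rev(ds_order)[seq_len(k)]
  list(dominant = top_g, subordinate = bot_g,
       agreement = setequal(top_g, top_d) && setequal(bot_g, bot_d),
       dominant_ds = top_d, subordinate_ds = bot_d)
}
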