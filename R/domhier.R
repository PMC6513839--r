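# The central model object: fit the whole dominance-hierarchy analysis to
# one cohort's event log.

#' Fit a dominance hierarchy to an agonistic event log
#'
#' One call runs the full group-level analysis for a single cohort: builds
#' the win/loss sociomatrix from the selected behaviors, computes David's
#' scores and the I&SI rank order, all sociomatrix metrics (Landau's
#' modified h', triangle transitivity, steepness, directional consistency,
#' despotism, Gini coefficients) with randomization p-values, and tracks
#' Glicko ratings event by event, identifying the most dominant and most
#' subordinate individuals under both rating systems.
#'
#' @param events Event data.frame (see [read_event_log()]) for one cohort.
#' @param behaviors Behaviors entering the sociomatrix; default all five of
#'   [ethogram()].
#' @param ids Optional fixed individual ordering.
#' @param priority_window If non-NULL, apply [apply_priority_rule()] with
#'   this window (seconds) before analysis; default NULL (logs are assumed
#'   already resolved, as when the rule is applied at recording time).
#' @param M Randomizations per p-value (default 1000).
#' @param n_resolutions Random resolutions for h' (default 1000).
#' @param n_isi_tries Restarts for the I&SI search (default 50).
#' @param dyadic_correction Use the sample-size-corrected dyadic win
#'   proportion in David's scores (default FALSE).
#' @param glicko A [glicko_config()].
#' @param seed Optional RNG seed controlling every randomized step.
#' @return Object of class `domhier` with components `matrix`, `davids`,
#'   `isi_ranking`, `metrics` (a `metrics_report`), `glicko` (a
#'   `glicko_trajectory`), `dom_sub`, `events`, `ids`, `call`.
#' @examples
#' sim <- simulate_colony(synthetic_config(), seed = 1)
#' fit <- domhier(sim$events, M = 200, n_resolutions = 200, seed = 1)
#' summary(fit)
#' coef(fit)
#' @export
domhier <- function(events, behaviors = ethogram(), ids = NULL,
                    priority_window = NULL, M = 1000, n_resolutions = 1000,
                    n_isi_tries = 50, dyadic_correction = FALSE,
                    glicko = glicko_config(), seed = NULL) {
  cl <- match.call()
  validate_events(events)
  if (length(unique(events$cohort)) > 1L)
    stop("domhier fits one cohort at a time; split the log by cohort ",
         "(see run_analyze for multi-cohort runs)")
  if (!is.null(priority_window))
    events <- apply_priority_rule(events, priority_window)
  # individuals are defined by the whole log so that behavior filtering
  # cannot silently shrink the group
  if (is.null(ids)) ids <- sort(unique(c(events$actor, events$recipient)))
  ev <- events[events$behavior %in% behaviors, , drop = FALSE]
  W <- build_win_loss_matrix(ev, behaviors = behaviors, ids = ids)
  if (nrow(W) < 3) stop("need at least 3 individuals")
  if (sum(W) == 0) stop("no events for the selected behaviors")
  seeds <- derive_seeds(seed, 2L)
  ds <- davids_scores(W, dyadic_correction)
  metrics <- full_report(W, M = M, n_resolutions = n_resolutions,
                         dyadic_correction = dyadic_correction,
                         seed = seeds[1])
  traj <- glicko_trajectory(ev, config = glicko, ids = rownames(W))
  out <- list(call = cl,
              cohort = unique(events$cohort) %||% NA_character_,
              events = ev,
              matrix = W,
              ids = rownames(W),
              davids = ds,
              isi_ranking = rank_isi(W, n_tries = n_isi_tries,
                                     seed = seeds[2]),
              metrics = metrics,
              glicko = traj,
              dom_sub = select_dom_sub(traj, ds, k = min(2L, nrow(W) %/% 2L)),
              behaviors = behaviors,
              seed = seed)
  class(out) <- "domhier"
  out
}

#' @export
print.domhier <- function(x, ...) {
  cat("Dominance hierarchy fit: cohort", x$cohort, "-",
      length(x$ids), "individuals,", sum(x$matrix), "events\n")
  cat(sprintf("  h' = %.3f (p = %.3g), ttri = %.3f, DC = %.3f, despotism = %.3f\n",
              x$metrics$h_prime, x$metrics$p_h_prime,
              x$metrics$ttri, x$metrics$dc, x$metrics$despotism))
  cat("  I&SI order:", paste(x$isi_ranking, collapse = " > "), "\n")
  invisible(x)
}

#' Summarise a dominance hierarchy fit
#'
#' @param object A `domhier` fit.
#' @param ... Unused.
#' @return list of class `summary.domhier` with the metrics report, the
#'   individual table (David's scores, final Glicko ratings, ranks) and the
#'   dominant/subordinate selection.
#' @export
summary.domhier <- function(object, ...) {
  ds <- object$davids
  final <- object$glicko$states$rating[ds$id]
  tab <- data.frame(id = ds$id,
                    wins = rowSums(object$matrix)[ds$id],
                    losses = colSums(object$matrix)[ds$id],
                    NormDS = ds$NormDS,
                    ds_rank = ds$ds_rank,
                    glicko = unname(final),
                    glicko_rank = match(ds$id, object$glicko$final_order),
                    isi_rank = match(ds$id, object$isi_ranking))
  tab <- tab[order(tab$isi_rank), ]
  rownames(tab) <- NULL
  structure(list(cohort = object$cohort, metrics = object$metrics,
                 individuals = tab, dom_sub = object$dom_sub),
            class = "summary.domhier")
}

#' @export
print.summary.domhier <- function(x, digits = 3, ...) {
  cat("Cohort", x$cohort, "\n\n")
  print(x$metrics, digits = digits)
  cat("\nIndividuals (I&SI order):\n")
  tab <- x$individuals
  tab$NormDS <- round(tab$NormDS, digits)
  tab$glicko <- round(tab$glicko)
  print(tab, row.names = FALSE)
  cat("\nMost dominant:", paste(x$dom_sub$dominant, collapse = ", "),
      "| most subordinate:", paste(x$dom_sub$subordinate, collapse = ", "),
      if (x$dom_sub$agreement) "(Glicko and David's scores agree)"
      else "(Glicko and David's scores disagree)", "\n")
  invisible(x)
}

#' Extract dominance scores
#'
#' @param object A `domhier` fit.
#' @param type `"davids"` for normalised David's scores (default) or
#'   `"glicko"` for final Glicko ratings.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
coef.domhier <- function(object, type = c("davids", "glicko"), ...) {
  type <- match.arg(type)
  if (type == "davids")
    stats::setNames(object$davids$NormDS, object$davids$id)
  else
    object$glicko$states$rating
}

#' Predicted dyadic win probabilities
#'
#' Expected probability that the row individual beats the column individual
#' in their next encounter, from the final Glicko ratings (the rating
#' system's expected-score formula, using the opponent's deviation).
#'
#' @param object A `domhier` fit.
#' @param ... Unused.
#' @return N x N probability matrix with NA diagonal; P + t(P) = 1 off the
#'   diagonal up to deviation asymmetry.
#' @export
predict.domhier <- function(object, ...) {
  r <- object$glicko$states$rating
  rd <- object$glicko$states$deviation
  q <- object$glicko$config$q
  g <- 1 / sqrt(1 + 3 * q^2 * rd^2 / pi^2)
  n <- length(r)
  P <- matrix(NA_real_, n, n, dimnames = list(names(r), names(r)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    P[i, j] <- 1 / (1 + 10^(-g[j] * (r[i] - r[j]) / 400))
  P
}

#' Simulate event logs from a fitted hierarchy
#'
#' Parametric bootstrap of the sociomatrix: each dyad's observed interaction
#' total n_ij is kept and its outcomes are redrawn as Binomial(n_ij, P_ij)
#' with P_ij the observed dyadic win proportion. Returns win/loss matrices,
#' not timed logs (timing and behavior labels are not part of the fitted
#' dyadic model).
#'
#' @param object A `domhier` fit.
#' @param nsim Number of simulated matrices.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return list of `nsim` win/loss matrices.
#' @export
simulate.domhier <- function(object, nsim = 1, seed = NULL, ...) {
  W <- object$matrix
  n_ij <- W + t(W)
  up <- which(upper.tri(W), arr.ind = TRUE)
  lo <- up[, 2:1, drop = FALSE]
  p <- ifelse(n_ij[up] > 0, W[up] / n_ij[up], 0.5)
  with_seed(seed, {
    lapply(seq_len(nsim), function(k) {
      out <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
      wins <- stats::rbinom(nrow(up), n_ij[up], p)
      out[up] <- wins
      out[lo] <- n_ij[up] - wins
      out
    })
  })
}

#' Plot Glicko rating trajectories
#'
#' Rating of every individual against successive behavioral events, colored
#' from black (eventual most dominant) to red (eventual most subordinate).
#'
#' @param x A `domhier` fit.
#' @param ... Further arguments passed to [graphics::matplot()].
#' @export
plot.domhier <- function(x, ...) {
  traj <- x$glicko
  ord <- match(traj$ids, traj$final_order)
  cols <- grDevices::colorRampPalette(c("black", "red"))(length(traj$ids))
  graphics::matplot(0:(nrow(traj$rating) - 1L), traj$rating, type = "l",
                    lty = 1, col = cols[ord],
                    xlab = "Event", ylab = "Glicko rating",
                    main = paste("Cohort", x$cohort), ...)
  invisible(x)
}
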