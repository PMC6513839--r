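# Orchestration: from event/estrus logs (real or simulated) to the standard
# output tables, with manifests recording seeds and settings.

#' Write simulated cohorts to disk
#'
#' Emits a standard event-log CSV, an estrus CSV and the ground truth as
#' JSON, plus a manifest recording the configuration and seed.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_cohorts Number of cohorts (default 8).
#' @param seed RNG seed (recorded in the manifest).
#' @return Invisibly, the paths written.
#' @export
run_simulate <- function(config = synthetic_config(), out_dir,
                         n_cohorts = 8, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohorts(config, n_cohorts = n_cohorts, seed = seed)
  paths <- c(events = file.path(out_dir, "events.csv"),
             estrus = file.path(out_dir, "estrus.csv"),
             truth = file.path(out_dir, "truth.json"),
             manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(sim$events, paths["events"], row.names = FALSE)
  utils::write.csv(sim$estrus, paths["estrus"], row.names = FALSE)
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(list(command = "simulate",
                            config = unclass(config),
                            n_cohorts = n_cohorts, seed = seed,
                            package_version =
                              as.character(utils::packageVersion("domhier"))),
                       paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# Fit one cohort defensively: degenerate cohorts (< 3 individuals or no
# events) yield an all-NA metrics row with a warning instead of an error.
analyze_cohort <- function(ev, behaviors, M, n_resolutions, seed) {
  ids <- sort(unique(c(ev$actor, ev$recipient)))
  if (length(ids) < 3L || sum(ev$behavior %in% behaviors) == 0L) {
    warning("cohort ", unique(ev$cohort),
            ": fewer than 3 individuals or no events; metrics undefined")
    return(NULL)
  }
  domhier(ev, behaviors = behaviors, M = M, n_resolutions = n_resolutions,
          seed = seed)
}

#' Analyse event (and optional estrus) logs across cohorts
#'
#' Runs the full pipeline per cohort and writes: a per-cohort metrics table
#' (columns in the conventional order h', ttri, steepness, DC, despotism,
#' Gini wins, Gini losses plus p-values), a per-behavior DC/Gini table, a
#' QAP pairwise table for the fighting/chasing/mounting sociomatrices,
#' long-format Glicko trajectories, a day-by-day emergence table, hourly
#' rates by rank and day, estrus summaries when an estrus log is supplied,
#' and a manifest with the seeds and settings used.
#'
#' @param events Event data.frame or path to an event-log CSV.
#' @param out_dir Output directory.
#' @param estrus Optional estrus data.frame or CSV path.
#' @param behaviors Behaviors entering the dominance matrix (default all).
#' @param M Randomizations per p-value.
#' @param n_resolutions Random resolutions for h'.
#' @param n_qap QAP permutations (default 1000).
#' @param alpha Significance level for emergence flags.
#' @param schedule Observation schedule; default 14 days x 2 h.
#' @param seed RNG seed controlling all randomized steps.
#' @return Invisibly, a list with the fitted `domhier` objects and the
#'   output tables.
#' @export
run_analyze <- function(events, out_dir, estrus = NULL,
                        behaviors = ethogram(), M = 1000,
                        n_resolutions = 1000, n_qap = 1000, alpha = 0.05,
                        schedule = NULL, seed = NULL) {
  if (is.character(events)) events <- read_event_log(events)
  validate_events(events)
  if (is.character(estrus)) estrus <- read_estrus_log(estrus)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohorts <- sort(unique(events$cohort))
  if (is.null(schedule))
    schedule <- observation_schedule(n_days = max(events$day))
  seeds <- derive_seeds(seed, 3L * length(cohorts))
  names(seeds) <- NULL

  fits <- list(); metrics <- list(); behav <- list(); qap <- list()
  traj <- list(); emerg <- list(); rates <- list(); est_sum <- list()
  for (i in seq_along(cohorts)) {
    co <- cohorts[i]
    ev <- events[events$cohort == co, , drop = FALSE]
    fit <- analyze_cohort(ev, behaviors, M, n_resolutions, seeds[3 * i - 2])
    if (is.null(fit)) {
      metrics[[co]] <- data.frame(cohort = co, h_prime = NA, ttri = NA,
                                  steepness = NA, dc = NA, despotism = NA,
                                  gini_wins = NA, gini_losses = NA,
                                  p_h_prime = NA, p_ttri = NA,
                                  p_steepness = NA, p_dc = NA,
                                  n_events = nrow(ev),
                                  n_individuals =
                                    length(unique(c(ev$actor, ev$recipient))))
      next
    }
    fits[[co]] <- fit
    metrics[[co]] <- cbind(cohort = co, as.data.frame(fit$metrics))

    # per-behavior DC and Gini (given and received) for the three
    # dominance behaviors
    behav[[co]] <- do.call(rbind, lapply(
      c("fighting", "chasing", "mounting"), function(b) {
        Wb <- build_win_loss_matrix(ev, behaviors = b, ids = fit$ids)
        ok <- sum(Wb) > 0
        data.frame(cohort = co, behavior = b, n_events = sum(Wb),
                   dc = if (ok) directional_consistency(Wb) else NA_real_,
                   gini_given = if (ok && sum(rowSums(Wb)) > 0)
                     gini(rowSums(Wb)) else NA_real_,
                   gini_received = if (ok && sum(colSums(Wb)) > 0)
                     gini(colSums(Wb)) else NA_real_)
      }))

    # QAP between behavior-specific sociomatrices
    pairs <- utils::combn(c("fighting", "chasing", "mounting"), 2)
    qseeds <- derive_seeds(seeds[3 * i - 1], ncol(pairs))
    qap[[co]] <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      A <- build_win_loss_matrix(ev, behaviors = pairs[1, k], ids = fit$ids)
      B <- build_win_loss_matrix(ev, behaviors = pairs[2, k], ids = fit$ids)
      res <- tryCatch(qap_correlation(A, B, n_perm = n_qap,
                                      seed = qseeds[k]),
                      error = function(e) NULL)
      data.frame(cohort = co, behavior_a = pairs[1, k],
                 behavior_b = pairs[2, k],
                 r = if (is.null(res)) NA_real_ else res$r,
                 p_greater = if (is.null(res)) NA_real_ else res$p_greater,
                 p_lower = if (is.null(res)) NA_real_ else res$p_lower,
                 n_perm = n_qap)
    }))

    traj[[co]] <- cbind(cohort = co, as.data.frame(fit$glicko))
    emerg[[co]] <- cbind(cohort = co,
                         as.data.frame(emergence_by_day(
                           ev, n_days = max(schedule$day), M = M,
                           n_resolutions = min(n_resolutions, 100),
                           alpha = alpha, behaviors = behaviors,
                           seed = seeds[3 * i])))
    rates[[co]] <- cbind(cohort = co,
                         hourly_rates(ev, schedule, group_by = "rank",
                                      ranking = fit$isi_ranking))
    if (!is.null(estrus)) {
      est <- estrus[estrus$cohort == co, , drop = FALSE]
      if (nrow(est) > 0) {
        ct <- estrus_rank_crosstab(est, fit$isi_ranking)
        est_sum[[co]] <- cbind(cohort = co, rank = seq_len(nrow(ct)),
                               as.data.frame(ct))
      }
    }
  }

  tables <- list(
    metrics = do.call(rbind, c(metrics, list(make.row.names = FALSE))),
    behavior_dc_gini = do.call(rbind, c(behav, list(make.row.names = FALSE))),
    qap = do.call(rbind, c(qap, list(make.row.names = FALSE))),
    glicko_trajectories = do.call(rbind, c(traj,
                                           list(make.row.names = FALSE))),
    emergence = do.call(rbind, c(emerg, list(make.row.names = FALSE))),
    hourly_rates_by_rank = do.call(rbind, c(rates,
                                            list(make.row.names = FALSE))),
    estrus_rank_crosstab = if (length(est_sum) > 0)
      do.call(rbind, c(est_sum, list(make.row.names = FALSE))) else NULL
  )
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]]))
      utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  jsonlite::write_json(
    list(command = "analyze", behaviors = behaviors, M = M,
         n_resolutions = n_resolutions, n_qap = n_qap, alpha = alpha,
         seed = seed, cohorts = cohorts,
         package_version =
           as.character(utils::packageVersion("domhier"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(fits = fits, tables = tables))
}

#' Compare two groups of metrics reports descriptively
#'
#' Per-metric medians and interquartile ranges for two groups of cohorts
#' (e.g. females vs males) and their median differences. Descriptive only;
#' no tests are performed.
#'
#' @param group_a,group_b data.frames of per-cohort metrics (as written by
#'   [run_analyze()] in `metrics.csv`) or paths to such CSVs.
#' @param labels Length-2 group labels.
#' @return data.frame with one row per metric: group medians, IQRs and the
#'   difference of medians (A - B).
#' @export
run_compare <- function(group_a, group_b, labels = c("A", "B")) {
  load_grp <- function(g) {
    if (is.character(g)) g <- utils::read.csv(g, stringsAsFactors = FALSE)
    if (nrow(g) == 0) stop("empty group of metrics reports")
    g
  }
  a <- load_grp(group_a); b <- load_grp(group_b)
  metrics <- c("h_prime", "ttri", "steepness", "dc", "despotism",
               "gini_wins", "gini_losses")
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE,
                                    names = FALSE)
  out <- do.call(rbind, lapply(metrics, function(m) {
    qa <- qs(a[[m]]); qb <- qs(b[[m]])
    data.frame(metric = m,
               median_a = qa[2], q1_a = qa[1], q3_a = qa[3],
               median_b = qb[2], q1_b = qb[1], q3_b = qb[3],
               median_diff = qa[2] - qb[2])
  }))
  names(out) <- sub("_a$", paste0("_", labels[1]),
                    sub("_b$", paste0("_", labels[2]), names(out)))
  names(out)[names(out) == "median_diff"] <- "median_diff"
  rownames(out) <- NULL
  out
}
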