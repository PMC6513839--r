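test_that("a consistent hierarchy is significantly linear from day 1", {
  # perfectly consistent colony with plenty of day-1 events
  cfg <- synthetic_config(consistency = 1, base_event_rate = 30, n_days = 4)
  sim <- simulate_colony(cfg, seed = 12)
  expect_gte(sum(sim$events$day == 1), 30)
  em <- emergence_by_day(sim$events, M = 200, n_resolutions = 50, seed = 2)
  expect_equal(attr(em, "first_stable_day"), 1L)
  expect_true(all(em$sig_h))
  # flags are consistent with their p-values at alpha
  expect_equal(em$sig_h, em$p_h <= 0.05)
  expect_equal(em$sig_ttri[!is.na(em$p_ttri)],
               em$p_ttri[!is.na(em$p_ttri)] <= 0.05)
})

test_that("emergence handles empty days and matches the full-matrix metrics", {
  ev <- make_events("A", "B", day = 3L)
  ev <- rbind(ev, make_events("B", "C", day = 3L),
              make_events("A", "C", day = 3L))
  em <- emergence_by_day(ev, n_days = 3, M = 100, seed = 5)
  expect_true(all(is.na(em$ttri[1:2])))      # no events yet
  W <- build_win_loss_matrix(ev)
  expect_equal(em$ttri[3], triangle_transitivity(W)$ttri)
  expect_equal(em$h_prime[3], landaus_h(W))
  expect_equal(em$n_events, c(0, 0, 3))
  # days without metrics cannot be significant, so stability cannot start
  # before day 3 here
  fsd <- attr(em, "first_stable_day")
  expect_true(is.na(fsd) || fsd == 3L)
})

test_that("estrus proportions are normalised over determined days", {
  rec <- data.frame(cohort = "A", individual = "f1", day = 1:14,
                    state = c(rep("estrus", 7), rep("diestrus", 7)),
                    stringsAsFactors = FALSE)
  pr <- estrus_proportions(rec)
  expect_equal(pr$estrus, 0.5)
  expect_equal(pr$diestrus, 0.5)
  expect_equal(pr$proestrus + pr$metestrus, 0)

  rec$state <- "metestrus"
  expect_equal(estrus_proportions(rec)$metestrus, 1)

  # undetermined days leave the denominator
  rec$state <- c(rep("estrus", 6), rep("undetermined", 8))
  pr <- estrus_proportions(rec)
  expect_equal(pr$estrus, 1)
  expect_equal(pr$n_undetermined, 8)

  rec$state <- "undetermined"
  expect_true(is.na(estrus_proportions(rec)$estrus))

  # proportions sum to one for simulated colonies
  cfg <- synthetic_config()
  sim <- simulate_colony(cfg, seed = 3)
  est <- simulate_estrus(cfg, sim$truth, seed = 4)
  pr <- estrus_proportions(est)
  ok <- pr$n_determined > 0
  sums <- rowSums(pr[ok, c("proestrus", "estrus", "metestrus", "diestrus")])
  expect_equal(unname(sums), rep(1, sum(ok)), tolerance = 1e-12)

  expect_error(estrus_proportions(rbind(rec, rec)), "duplicate")
})

test_that("rank-by-state crosstab conserves determined days", {
  cfg <- synthetic_config()
  sim <- simulate_colony(cfg, seed = 23)
  est <- simulate_estrus(cfg, sim$truth, seed = 24)
  ct <- estrus_rank_crosstab(est, sim$truth$latent_order)
  expect_equal(sum(ct), sum(est$state != "undetermined"))
  expect_equal(nrow(ct), 12)

  one <- est[est$individual == sim$truth$ids[1], ]
  ct1 <- estrus_rank_crosstab(one, sim$truth$ids[1])
  expect_equal(sum(ct1), sum(one$state != "undetermined"))
  expect_error(estrus_rank_crosstab(est, "nobody"), "cover")
})

test_that("rates by estrous state assign each individual-day to its state", {
  sched <- observation_schedule(n_days = 4, hours_per_day = 2)
  rec <- expand.grid(individual = c("A", "B"), day = 1:4,
                     stringsAsFactors = FALSE)
  rec$cohort <- "A"
  # A is in estrus on days 1-2, diestrus 3-4; B always diestrus
  rec$state <- ifelse(rec$individual == "A" & rec$day <= 2,
                      "estrus", "diestrus")
  # mounting received by A only on A's estrus days
  ev <- make_events(actor = rep("B", 6), recipient = rep("A", 6),
                    behavior = "mounting", day = c(1, 1, 1, 2, 2, 2))
  out <- rates_by_estrus_state(ev, rec, sched, direction = "received",
                               behaviors = "mounting")
  est_med <- out$median[out$state == "estrus"]
  die_med <- out$median[out$state == "diestrus"]
  expect_equal(est_med, 1.5)       # 3 mounts / 2 h on each estrus day
  expect_equal(die_med, 0)         # full day denominators, zero events
  expect_gte(est_med, die_med)
  expect_equal(out$n_days[out$state == "estrus"], 2)      # A days 1-2
  expect_equal(out$n_days[out$state == "diestrus"], 6)    # A 3-4 + B 1-4

  # days without an estrus record are excluded and counted
  rec2 <- rec[rec$day <= 3, ]
  out2 <- rates_by_estrus_state(ev, rec2, sched, direction = "received",
                                behaviors = "mounting")
  expect_equal(attr(out2, "n_excluded_days"), 2)

  # relabeling states permutes the summary rows identically
  rec3 <- rec
  rec3$state <- ifelse(rec3$state == "estrus", "proestrus", "metestrus")
  out3 <- rates_by_estrus_state(ev, rec3, sched, direction = "received",
                                behaviors = "mounting")
  expect_equal(out3$median[out3$state == "proestrus"], est_med)
  expect_equal(out3$median[out3$state == "metestrus"], die_med)
})
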