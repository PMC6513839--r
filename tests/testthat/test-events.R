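test_that("event logs round-trip through CSV with validation", {
  path <- withr::local_tempfile(fileext = ".csv")
  ev <- make_events(actor = c("B", "A", "A"), recipient = c("A", "C", "B"),
                    behavior = c("chasing", "fighting", "mounting"),
                    day = c(2L, 1L, 1L), time_s = c(5, 30, 10))
  write.csv(ev, path, row.names = FALSE)
  got <- read_event_log(path)
  expect_equal(nrow(got), 3L)
  # stably sorted by (cohort, day, time)
  expect_equal(got$actor, c("A", "A", "B"))
  expect_equal(got$time_s, c(10, 30, 5))

  # empty file with header
  write.csv(ev[0, ], path, row.names = FALSE)
  expect_equal(nrow(read_event_log(path)), 0L)

  # schema mapping winner/loser column names
  ev2 <- ev
  names(ev2)[names(ev2) == "actor"] <- "winner"
  names(ev2)[names(ev2) == "recipient"] <- "loser"
  write.csv(ev2, path, row.names = FALSE)
  got2 <- read_event_log(path, schema = c(actor = "winner",
                                          recipient = "loser"))
  expect_equal(got2$actor, c("A", "A", "B"))
})

test_that("malformed logs are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  ev <- make_events("A", "B", behavior = "grooming")
  write.csv(ev, path, row.names = FALSE)
  expect_error(read_event_log(path), "behavior")

  ev <- make_events("A", "A")
  write.csv(ev, path, row.names = FALSE)
  expect_error(read_event_log(path), "actor equals recipient")

  write.csv(make_events("A", "B")[, -1], path, row.names = FALSE)
  expect_error(read_event_log(path), "cohort")
})

test_that("priority rule keeps the highest-priority event of a dyad cluster", {
  # fight then chase within 2 s, same pair: fight survives
  ev <- make_events(actor = c("A", "A"), recipient = c("B", "B"),
                    behavior = c("fighting", "chasing"),
                    time_s = c(10.0, 11.5))
  out <- apply_priority_rule(ev)
  expect_equal(nrow(out), 1L)
  expect_equal(out$behavior, "fighting")
  expect_equal(out$time_s, 10.0)

  # lower priority first: the later, higher-priority event wins the cluster
  ev <- make_events(actor = c("A", "A"), recipient = c("B", "B"),
                    behavior = c("chasing", "fighting"),
                    time_s = c(10.0, 11.5))
  out <- apply_priority_rule(ev)
  expect_equal(out$behavior, "fighting")

  # gap wider than the window: both kept
  ev <- make_events(actor = c("A", "A"), recipient = c("B", "B"),
                    behavior = c("chasing", "mounting"),
                    time_s = c(10.0, 13.0))
  expect_equal(nrow(apply_priority_rule(ev)), 2L)

  # different dyads co-occurring are untouched
  ev <- make_events(actor = c("A", "C"), recipient = c("B", "D"),
                    behavior = c("chasing", "fighting"),
                    time_s = c(10, 10))
  expect_equal(nrow(apply_priority_rule(ev)), 2L)

  # missing times are an error directing the caller to skip the rule
  expect_error(apply_priority_rule(make_events("A", "B")), "time_s")
})

test_that("priority rule is idempotent and order-independent", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 40
    ids <- c("A", "B", "C", "D")
    a <- sample(ids, n, replace = TRUE)
    b <- vapply(a, function(x) sample(setdiff(ids, x), 1), character(1))
    ev <- make_events(a, b, behavior = sample(ethogram(), n, replace = TRUE),
                      time_s = runif(n, 0, 60))
    once <- apply_priority_rule(ev)
    twice <- apply_priority_rule(once)
    expect_equal(twice, once)
    # shuffling input rows does not change the outcome
    shuffled <- apply_priority_rule(ev[sample(n), ])
    expect_equal(shuffled, once)
  }
})

test_that("win/loss matrices count retained events exactly", {
  ev <- make_events(actor = c("A", "A", "B"), recipient = c("B", "B", "C"))
  W <- build_win_loss_matrix(ev, ids = c("A", "B", "C"))
  expect_equal(unname(W), rbind(c(0, 2, 0), c(0, 0, 1), c(0, 0, 0)))

  # empty events with fixed ids give a zero matrix of the right shape
  W0 <- build_win_loss_matrix(ev[0, ], ids = c("A", "B"))
  expect_equal(unname(W0), matrix(0L, 2, 2))

  # behavior filtering
  ev2 <- make_events(actor = c("A", "B"), recipient = c("B", "A"),
                     behavior = c("mounting", "fighting"))
  Wm <- build_win_loss_matrix(ev2, behaviors = "mounting")
  expect_equal(sum(Wm), 1)
  expect_equal(Wm["A", "B"], 1L)

  # unknown id under a fixed ordering is an error
  expect_error(build_win_loss_matrix(ev, ids = c("A", "B")), "id")

  # conservation: total cells = retained events
  sim <- simulate_colony(synthetic_config(), seed = 11)
  W <- build_win_loss_matrix(sim$events)
  expect_equal(sum(W), nrow(sim$events))
})

test_that("cumulative matrices are monotone and total at the last day", {
  sim <- simulate_colony(synthetic_config(n_days = 5), seed = 2)
  full <- build_win_loss_matrix(sim$events, ids = sim$truth$ids)
  expect_equal(cumulative_matrix_through_day(sim$events, 5,
                                             ids = sim$truth$ids), full)
  prev <- cumulative_matrix_through_day(sim$events, 1, ids = sim$truth$ids)
  for (d in 2:5) {
    cur <- cumulative_matrix_through_day(sim$events, d, ids = sim$truth$ids)
    expect_true(all(cur >= prev))
    prev <- cur
  }
  ev2 <- make_events("A", "B", day = 2L)
  expect_equal(sum(cumulative_matrix_through_day(ev2, 1)), 0)
  expect_error(cumulative_matrix_through_day(ev2, 0), ">= 1")
})

test_that("hourly rates divide counts by observed hours and conserve totals", {
  sched <- observation_schedule(n_days = 2, hours_per_day = 2)
  ev <- make_events(rep("A", 6), rep("B", 6), behavior = "chasing")
  by_day <- hourly_rates(ev, sched, group_by = "day")
  expect_equal(by_day$rate, c(3, 0))

  ev4 <- make_events(rep("A", 4), rep("B", 4), day = c(1, 1, 2, 2))
  by_beh <- hourly_rates(ev4, sched, group_by = "behavior")
  expect_equal(by_beh$rate[by_beh$behavior == "fighting"], 1.0)
  expect_equal(sum(by_beh$rate[by_beh$behavior != "fighting"]), 0)

  # given and received totals agree over the whole cohort
  sim <- simulate_colony(synthetic_config(n_days = 3), seed = 5)
  sched3 <- observation_schedule(n_days = 3)
  g <- hourly_rates(sim$events, sched3, group_by = "individual",
                    direction = "given")
  r <- hourly_rates(sim$events, sched3, group_by = "individual",
                    direction = "received")
  expect_equal(sum(g$events), sum(r$events))
  # rates times hours recover counts exactly
  expect_equal(g$rate * g$hours, as.numeric(g$events))

  expect_error(hourly_rates(ev4, observation_schedule(n_days = 1)),
               "schedule")
})
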