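test_that("David's scores match hand-evaluated values and sum to zero", {
  W <- perfect_matrix(3)
  ds <- davids_scores(W)
  expect_equal(ds$DS, c(3, 0, -3))
  expect_equal(ds$NormDS, c(2, 1, 0))
  expect_equal(ds$ds_rank, 1:3)

  # evenly split dyads: all scores zero
  E <- matrix(2L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(E) <- 0L
  expect_equal(davids_scores(E)$DS, rep(0, 4))

  # sum-zero identity on random matrices
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    W <- matrix(rpois(n^2, 2), n, n)
    diag(W) <- 0
    dimnames(W) <- list(letters[1:n], letters[1:n])
    expect_equal(sum(davids_scores(W)$DS), 0, tolerance = 1e-9)
    expect_equal(sum(davids_scores(W, dyadic_correction = TRUE)$DS), 0,
                 tolerance = 1e-9)
    expect_true(all(davids_scores(W)$NormDS >= -1e-9 &
                    davids_scores(W)$NormDS <= n - 1 + 1e-9))
  }

  # the dyadic correction shrinks one-observation dyads toward 0.5
  W1 <- perfect_matrix(3)
  dsc <- davids_scores(W1, dyadic_correction = TRUE)
  expect_lt(dsc$DS[1], 3)
  expect_gt(dsc$DS[3], -3)

  expect_error(davids_scores(matrix(0, 1, 1)), "at least 2")
})

test_that("steepness is the absolute OLS slope of sorted NormDS on rank", {
  expect_equal(steepness(perfect_matrix(3)), 1.0)
  expect_equal(steepness(perfect_matrix(12)), 1.0)
  E <- matrix(2L, 4, 4); diag(E) <- 0L
  dimnames(E) <- list(letters[1:4], letters[1:4])
  expect_equal(steepness(E), 0.0)
  # invariant to relabeling
  set.seed(3)
  W <- matrix(rpois(49, 2), 7, 7); diag(W) <- 0
  dimnames(W) <- list(letters[1:7], letters[1:7])
  p <- sample(7)
  expect_equal(steepness(W[p, p]), steepness(W))
})

test_that("Landau's h equals the dominance-vector brute force on all small tournaments", {
  expect_equal(landaus_h(perfect_matrix(3)), 1.0)
  cyc <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  cyc["a", "b"] <- 1L; cyc["b", "c"] <- 1L; cyc["c", "a"] <- 1L
  expect_equal(landaus_h(cyc), 0.0)
  expect_equal(landaus_h(perfect_matrix(8)), 1.0)

  for (n in 3:5) {
    for (W in all_tournaments(n)) {
      expect_equal(landaus_h(W), oracle_h(W))
    }
  }

  # undecided dyads are rejected
  U <- perfect_matrix(4)
  U["m01", "m02"] <- 0L
  expect_error(landaus_h(U), "landaus_h_prime")
})

test_that("h' averages random resolutions and is exact with none", {
  W <- perfect_matrix(12)
  expect_equal(landaus_h_prime(W, 5, seed = 1), 1.0)
  expect_equal(landaus_h_prime(W, 500, seed = 99), landaus_h(W))

  # all-unknown 3-individual matrix: expectation 0.75 (6 of 8 random
  # tournaments are transitive with h = 1, 2 cyclic with h = 0)
  Z <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(landaus_h_prime(Z, 20000, seed = 4), 0.75, tolerance = 0.02)

  # determinism under seed
  U <- perfect_matrix(6); U["m01", "m02"] <- 0L
  expect_identical(landaus_h_prime(U, 200, seed = 7),
                   landaus_h_prime(U, 200, seed = 7))
  expect_error(landaus_h_prime(W, 0), "n_resolutions")
})

test_that("triangle transitivity agrees with explicit triad enumeration", {
  expect_equal(triangle_transitivity(perfect_matrix(3))$ttri, 1.0)
  cyc <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  cyc["a", "b"] <- 1L; cyc["b", "c"] <- 1L; cyc["c", "a"] <- 1L
  tt <- triangle_transitivity(cyc)
  expect_equal(tt$Pt, 0)
  expect_equal(tt$ttri, -3)

  set.seed(10)
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    W <- matrix(rpois(n^2, 0.8), n, n)  # sparse: ties and unknowns occur
    diag(W) <- 0
    dimnames(W) <- list(letters[1:n], letters[1:n])
    got <- triangle_transitivity(W)
    want <- oracle_ttri(W)
    expect_equal(got$Pt, want$Pt)
    expect_equal(got$ttri, want$ttri)
  }

  # no complete triads: undefined marker
  Z <- matrix(0L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(is.na(triangle_transitivity(Z)$ttri))
})

test_that("directional consistency follows the dyadic majority formula", {
  expect_equal(directional_consistency(perfect_matrix(5, wins = 3L)), 1.0)
  W <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  W["a", "b"] <- 3L; W["b", "a"] <- 1L
  expect_equal(directional_consistency(W), 0.5)
  # dyads {5-0, 2-2} -> (5 + 0) / 9
  W3 <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W3["a", "b"] <- 5L; W3["b", "c"] <- 2L; W3["c", "b"] <- 2L
  expect_equal(directional_consistency(W3), 5 / 9)
  expect_error(directional_consistency(W3 * 0L), "no events")
})

test_that("despotism is the alpha's share of wins", {
  W <- matrix(0L, 12, 12,
              dimnames = list(sprintf("m%02d", 1:12), sprintf("m%02d", 1:12)))
  W[1, 2:12] <- 3L
  expect_equal(despotism(W), 1.0)

  # equal win counts: despotism 1/12 whatever the ranking
  E <- matrix(1L, 12, 12); diag(E) <- 0L
  dimnames(E) <- dimnames(W)
  expect_equal(despotism(E), 1 / 12)

  # only the top of the ranking matters
  W2 <- perfect_matrix(4)
  r1 <- c("m03", "m01", "m02", "m04")
  r2 <- c("m03", "m04", "m02", "m01")
  expect_equal(despotism(W2, r1), despotism(W2, r2))
  expect_error(despotism(W2 * 0L), "no events")
})

test_that("gini matches the pairwise brute force and is scale invariant", {
  expect_equal(gini(c(1, 1, 1, 1)), 0.0)
  expect_equal(gini(c(4, 0, 0, 0)), 0.75)
  set.seed(5)
  for (rep in 1:20) {
    x <- rpois(sample(2:20, 1), 3)
    if (sum(x) == 0) x[1] <- 1
    expect_equal(gini(x), oracle_gini(x))
    expect_equal(gini(7.3 * x), gini(x))
  }
  expect_error(gini(c(0, 0)), "all-zero")
  expect_error(gini(5), "at least 2")
})

test_that("I&SI ordering matches exhaustive search on small matrices", {
  # perfectly linear: true order with no inconsistencies
  W <- perfect_matrix(6)
  ord <- rank_isi(W, n_tries = 5, seed = 1)
  expect_equal(as.character(ord), rownames(W))
  expect_equal(attr(ord, "I"), 0)
  expect_equal(attr(ord, "SI"), 0)

  # one planted reversal, N = 4 and 5: heuristic reaches the exhaustive
  # optimum and never does worse than its David's-score start
  set.seed(8)
  for (n in 4:5) {
    for (rep in 1:5) {
      W <- perfect_matrix(n, wins = 2L)
      i <- sample(n - 1, 1)
      W[i + 1, i] <- 5L   # reversal against the linear order
      ord <- rank_isi(W, n_tries = 20, seed = rep)
      got <- c(attr(ord, "I"), attr(ord, "SI"))
      want <- oracle_isi_best(W)
      expect_equal(got[1], unname(want[1]))
      expect_equal(got[2], unname(want[2]))
      start <- oracle_isi_objective(W, match(rank_davids(W), rownames(W)))
      expect_true(got[1] < start[1] ||
                  (got[1] == start[1] && got[2] <= start[2]))
    }
  }
})

test_that("full report hits fixed points and is label invariant", {
  W <- perfect_matrix(12)
  rep1 <- full_report(W, M = 200, n_resolutions = 200, seed = 42)
  expect_equal(rep1$h_prime, 1.0)
  expect_equal(rep1$ttri, 1.0)
  expect_equal(rep1$dc, 1.0)
  expect_equal(rep1$steepness, 1.0)
  ps <- c(rep1$p_h_prime, rep1$p_ttri, rep1$p_steepness, rep1$p_dc)
  expect_true(all(ps >= 1 / 201 & ps <= 1))

  # permuting labels leaves every metric unchanged
  sim <- simulate_colony(synthetic_config(), seed = 21)
  W <- build_win_loss_matrix(sim$events)
  p <- sample(nrow(W))
  a <- full_report(W, M = 50, n_resolutions = 100, seed = 9)
  b <- full_report(W[p, p], M = 50, n_resolutions = 100, seed = 9)
  for (f in c("ttri", "steepness", "dc", "despotism", "gini_wins",
              "gini_losses", "n_events"))
    expect_equal(a[[f]], b[[f]], info = f)
  expect_equal(a$h_prime, b$h_prime, tolerance = 0.05)
})
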