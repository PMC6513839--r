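# Shared fixtures and independent oracles used across the suite.

# Perfectly linear win/loss matrix: one win per ordered dyad above the
# diagonal, in rank order.
perfect_matrix <- function(n, wins = 1L) {
  ids <- sprintf("m%02d", seq_len(n))
  W <- matrix(0L, n, n, dimnames = list(ids, ids))
  W[upper.tri(W)] <- wins
  W
}

# Minimal event data.frame builder.
make_events <- function(actor, recipient, behavior = "fighting",
                        day = 1L, time_s = NA_real_, cohort = "A") {
  data.frame(cohort = cohort, day = as.integer(day), time_s = time_s,
             actor = actor, recipient = recipient, behavior = behavior,
             stringsAsFactors = FALSE)
}

# All binary tournaments on n individuals, as win/loss matrices.
all_tournaments <- function(n) {
  ids <- letters[seq_len(n)]
  up <- which(upper.tri(diag(n)), arr.ind = TRUE)
  k <- nrow(up)
  lapply(seq_len(2^k) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(k)]
    W <- matrix(0L, n, n, dimnames = list(ids, ids))
    W[up] <- bits
    W[up[, 2:1, drop = FALSE]] <- 1L - bits
    W
  })
}

# Independent h oracle: dominance vector read straight off a complete binary
# tournament (row a dominates b iff W[a,b] > W[b,a]).
oracle_h <- function(W) {
  n <- nrow(W)
  V <- vapply(seq_len(n), function(a)
    sum(W[a, ] > W[, a]), numeric(1))
  (12 / (n^3 - n)) * sum((V - (n - 1) / 2)^2)
}

# Independent triangle-transitivity oracle: explicit triad enumeration.
oracle_ttri <- function(W) {
  n <- nrow(W)
  complete <- 0L; transitive <- 0L
  for (tri in utils::combn(n, 3, simplify = FALSE)) {
    S <- W[tri, tri]
    decided <- TRUE
    for (a in 1:2) for (b in (a + 1):3)
      if (S[a, b] == S[b, a]) decided <- FALSE
    if (!decided) next
    complete <- complete + 1L
    v <- vapply(1:3, function(a) sum(S[a, ] > S[, a]), numeric(1))
    if (setequal(v, 0:2)) transitive <- transitive + 1L
  }
  if (complete == 0L) return(list(Pt = NA_real_, ttri = NA_real_))
  Pt <- transitive / complete
  list(Pt = Pt, ttri = 4 * (Pt - 0.75), n_triads = complete)
}

# Pairwise-difference Gini oracle.
oracle_gini <- function(x) {
  s <- 0
  for (i in seq_along(x)) for (j in seq_along(x))
    s <- s + abs(x[i] - x[j])
  s / (2 * length(x)^2 * mean(x))
}

# All permutations of 1..n (n <= 6).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Independent (I, SI) objective and exhaustive I&SI search.
oracle_isi_objective <- function(W, ord) {
  n <- length(ord)
  I <- 0L; SI <- 0L
  for (p in seq_len(n - 1)) for (q in (p + 1):n) {
    hi <- ord[p]; lo <- ord[q]
    if (W[lo, hi] > W[hi, lo]) { # lower-ranked dominates higher-ranked
      I <- I + 1L
      SI <- SI + (q - p)
    }
  }
  c(I = I, SI = SI)
}

oracle_isi_best <- function(W) {
  best <- c(I = Inf, SI = Inf)
  for (p in all_perms(nrow(W))) {
    obj <- oracle_isi_objective(W, p)
    if (obj[1] < best[1] || (obj[1] == best[1] && obj[2] < best[2]))
      best <- obj
  }
  best
}

# Direct evaluation of the Glicko single-game equations, independent of the
# package's update code.
oracle_glicko_pair <- function(r_w, rd_w, r_l, rd_l, cfg = glicko_config()) {
  q <- log(10) / 400
  rd_w <- min(sqrt(rd_w^2 + cfg$c^2), cfg$deviation_cap)
  rd_l <- min(sqrt(rd_l^2 + cfg$c^2), cfg$deviation_cap)
  g <- function(x) 1 / sqrt(1 + 3 * q^2 * x^2 / pi^2)
  one <- function(r, rd, ro, rdo, s) {
    E <- 1 / (1 + 10^(-g(rdo) * (r - ro) / 400))
    d2 <- q^2 * g(rdo)^2 * E * (1 - E)
    den <- 1 / rd^2 + d2
    c(r + q / den * g(rdo) * (s - E), sqrt(1 / den))
  }
  list(winner = one(r_w, rd_w, r_l, rd_l, 1),
       loser = one(r_l, rd_l, r_w, rd_w, 0))
}
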