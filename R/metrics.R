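# Sociomatrix-level dominance statistics: David's scores, steepness,
# Landau's modified h', triangle transitivity, directional consistency,
# despotism, Gini coefficients and rank orderings.

# Check a win/loss matrix: square, non-negative, zero diagonal, dimnames.
check_matrix <- function(W, min_n = 2L) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("W must be a square matrix", call. = FALSE)
  if (nrow(W) < min_n)
    stop("matrix must have at least ", min_n, " individuals", call. = FALSE)
  if (any(W < 0)) stop("win counts must be non-negative", call. = FALSE)
  if (any(diag(W) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (is.null(rownames(W))) {
    ids <- paste0("id", seq_len(nrow(W)))
    dimnames(W) <- list(ids, ids)
  }
  W
}

#' Dominance relation matrix
#'
#' Binarizes a win/loss frequency matrix dyad by dyad: entry (i, j) is 1 when
#' i won more often than j, 0 when it lost more often, 0.5 for a tied dyad
#' with at least one interaction, and NA for a never-interacting (unknown)
#' dyad. The diagonal is NA.
#'
#' @param W Win/loss frequency matrix.
#' @return Numeric matrix of the same shape.
#' @export
dominance_relation <- function(W) {
  W <- check_matrix(W)
  Tm <- t(W)
  R <- matrix(NA_real_, nrow(W), ncol(W), dimnames = dimnames(W))
  n_ij <- W + Tm
  R[W > Tm] <- 1
  R[W < Tm] <- 0
  R[W == Tm & n_ij > 0] <- 0.5
  diag(R) <- NA_real_
  R
}

#' David's scores
#'
#' A win-proportion dominance measure adjusted for the strength of opponents.
#' For each dyad the win proportion is \eqn{P_{ij} = s_{ij}/n_{ij}} (0 for
#' never-interacting dyads); each individual accumulates \eqn{w = \sum_j
#' P_{ij}}, \eqn{w_2 = \sum_j P_{ij} w_j}, \eqn{l = \sum_j P_{ji}} and
#' \eqn{l_2 = \sum_j P_{ji} l_j}, giving \eqn{DS = w + w_2 - l - l_2} and the
#' normalisation \eqn{NormDS = (DS + N(N-1)/2)/N} on the 0..N-1 scale.
#'
#' @param W Win/loss frequency matrix (at least 2 individuals).
#' @param dyadic_correction If TRUE, each \eqn{P_{ij}} is replaced by the
#'   sample-size-corrected \eqn{D_{ij} = P_{ij} - (P_{ij} - 0.5)/(n_{ij}+1)},
#'   which shrinks sparsely observed dyads toward 0.5.
#' @return data.frame (one row per individual, input order) with columns
#'   `id`, `w`, `w2`, `l`, `l2`, `DS`, `NormDS`, `ds_rank`. David's scores
#'   always sum to zero.
#' @export
davids_scores <- function(W, dyadic_correction = FALSE) {
  W <- check_matrix(W, min_n = 2L)
  n <- nrow(W)
  n_ij <- W + t(W)
  P <- matrix(0, n, n, dimnames = dimnames(W))
  nz <- n_ij > 0
  P[nz] <- W[nz] / n_ij[nz]
  if (dyadic_correction)
    P[nz] <- P[nz] - (P[nz] - 0.5) / (n_ij[nz] + 1)
  diag(P) <- 0
  w <- rowSums(P)
  l <- colSums(P)
  w2 <- as.vector(P %*% w)
  l2 <- as.vector(t(P) %*% l)
  DS <- w + w2 - l - l2
  NormDS <- (DS + n * (n - 1) / 2) / n
  ids <- rownames(W)
  ord <- order_ids(ids, NormDS, rowSums(W))
  data.frame(id = ids, w = w, w2 = w2, l = l, l2 = l2,
             DS = DS, NormDS = NormDS,
             ds_rank = match(ids, ord),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' David's-score rank order
#'
#' @param W Win/loss matrix.
#' @param dyadic_correction Passed to [davids_scores()].
#' @return Ids ordered from most to least dominant by normalised David's
#'   score, ties broken by total wins then label.
#' @export
rank_davids <- function(W, dyadic_correction = FALSE) {
  ds <- davids_scores(W, dyadic_correction)
  ds$id[order(ds$ds_rank)]
}

#' Hierarchy steepness
#'
#' Absolute slope of the ordinary least-squares fit of normalised David's
#' scores (sorted descending) against rank position 1..N. Steepness 1 means
#' dominance falls off as fast as possible down the hierarchy; 0 means all
#' individuals hold equal power.
#'
#' @inheritParams davids_scores
#' @return Steepness in [0, 1].
#' @export
steepness <- function(W, dyadic_correction = FALSE) {
  ds <- davids_scores(W, dyadic_correction)
  y <- sort(ds$NormDS, decreasing = TRUE)
  x <- seq_along(y)
  abs(sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2))
}

# h on a completed binary tournament given the dominance vector V.
h_from_V <- function(V, n) {
  (12 / (n^3 - n)) * sum((V - (n - 1) / 2)^2)
}

#' Landau's h for a fully decided tournament
#'
#' Linearity of a complete dominance relation: with \eqn{V_a} the number of
#' individuals that a dominates, \eqn{h = \frac{12}{N^3-N}\sum_a (V_a -
#' \frac{N-1}{2})^2}; 1 for a perfectly linear order, 0 when every individual
#' dominates the same number of others.
#'
#' @param W Win/loss matrix whose every dyad is strictly decided.
#' @return h in [0, 1].
#' @seealso [landaus_h_prime()] for matrices with tied or unknown dyads.
#' @export
landaus_h <- function(W) {
  R <- dominance_relation(W)
  und <- which(upper.tri(R) & (is.na(R) | R == 0.5))
  if (length(und) > 0L)
    stop("matrix has tied or unknown dyads; use landaus_h_prime()",
         call. = FALSE)
  V <- rowSums(R == 1, na.rm = TRUE)
  h_from_V(V, nrow(R))
}

#' Landau's modified h'
#'
#' Linearity index for matrices with tied or never-interacting dyads: every
#' undecided dyad is directed at random (probability 0.5 each way), Landau's
#' h is computed on the completed tournament, and h' is the mean over
#' `n_resolutions` independent resolutions. With no undecided dyads the value
#' equals [landaus_h()] exactly for any seed.
#'
#' @param W Win/loss matrix, at least 3 individuals.
#' @param n_resolutions Number of random resolutions (default 1000).
#' @param seed Optional RNG seed for reproducibility.
#' @return h' in [0, 1].
#' @export
landaus_h_prime <- function(W, n_resolutions = 1000, seed = NULL) {
  W <- check_matrix(W, min_n = 3L)
  if (n_resolutions < 1) stop("n_resolutions must be >= 1")
  R <- dominance_relation(W)
  n <- nrow(R)
  up <- which(upper.tri(R), arr.ind = TRUE)
  und <- up[is.na(R[up]) | R[up] == 0.5, , drop = FALSE]
  baseV <- rowSums(R == 1, na.rm = TRUE)
  k <- nrow(und)
  if (k == 0L) return(h_from_V(baseV, n))
  with_seed(seed, {
    # bits[r, d] = 1 when, in resolution r, the row member of undecided
    # dyad d wins; V per resolution via two sparse-style indicator products.
    bits <- matrix(stats::runif(n_resolutions * k) < 0.5,
                   n_resolutions, k)
    Ii <- matrix(0, k, n); Ii[cbind(seq_len(k), und[, 1])] <- 1
    Ij <- matrix(0, k, n); Ij[cbind(seq_len(k), und[, 2])] <- 1
    V <- matrix(baseV, n_resolutions, n, byrow = TRUE) +
      bits %*% Ii + (1 - bits) %*% Ij
    mean((12 / (n^3 - n)) * rowSums((V - (n - 1) / 2)^2))
  })
}

#' Triangle transitivity
#'
#' Proportion of fully decided triads that are transitive (A beats B, B beats
#' C implies A beats C), rescaled so that 0 is the random-tournament
#' expectation (3/4 of triads transitive) and 1 means all triads transitive:
#' \eqn{t_{tri} = 4 (P_t - 0.75)}. Triads containing a tied or unknown dyad
#' are excluded.
#'
#' @param W Win/loss matrix.
#' @return list with `Pt`, `ttri` and `n_triads` (the number of complete
#'   triads); `Pt` and `ttri` are NA when no complete triad exists.
#' @export
triangle_transitivity <- function(W) {
  R <- dominance_relation(W)
  D <- (R == 1)
  D[is.na(D)] <- FALSE
  storage.mode(D) <- "numeric"
  U <- D + t(D)                      # 1 iff the dyad is strictly decided
  complete <- sum(diag(U %*% U %*% U)) / 6
  if (complete == 0)
    return(list(Pt = NA_real_, ttri = NA_real_, n_triads = 0L))
  cyclic <- sum(diag(D %*% D %*% D)) / 3
  Pt <- (complete - cyclic) / complete
  list(Pt = Pt, ttri = 4 * (Pt - 0.75), n_triads = as.integer(round(complete)))
}

#' Directional consistency
#'
#' Fraction of all interactions that flow in each dyad's majority direction:
#' \eqn{DC = \sum_{dyads} (max(s_{ij}, s_{ji}) - min(s_{ij}, s_{ji})) /
#' \sum_{dyads} (s_{ij} + s_{ji})}. 1 means every interaction runs from the
#' more dominant to the more subordinate member of its pair.
#'
#' @param W Win/loss matrix with at least one event.
#' @return DC in [0, 1].
#' @export
directional_consistency <- function(W) {
  W <- check_matrix(W)
  total <- sum(W)
  if (total == 0) stop("directional consistency undefined: no events")
  sum(abs(W - t(W))) / 2 / total
}

#' Despotism
#'
#' Share of all recorded wins performed by the top-ranked (alpha)
#' individual: 1 when the alpha performs every aggressive act in the group.
#'
#' @param W Win/loss matrix with at least one event.
#' @param ranking Ordered ids (rank 1 first); defaults to the David's-score
#'   order [rank_davids()].
#' @return Despotism in [0, 1].
#' @export
despotism <- function(W, ranking = NULL) {
  W <- check_matrix(W)
  if (sum(W) == 0) stop("despotism undefined: no events")
  if (is.null(ranking)) ranking <- rank_davids(W)
  if (!all(rownames(W) %in% ranking))
    stop("ranking must cover every individual in the matrix")
  sum(W[ranking[1], ]) / sum(W)
}

#' Gini coefficient
#'
#' Inequality of a non-negative frequency vector (e.g. wins per animal):
#' \eqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x)}; 0 for perfect
#' equality, approaching 1 when one individual holds everything.
#'
#' @param x Non-negative numeric vector, length >= 2, not all zero.
#' @return Gini coefficient in [0, 1).
#' @export
gini <- function(x) {
  if (length(x) < 2) stop("gini needs at least 2 values")
  if (any(x < 0)) stop("gini requires non-negative values")
  if (sum(x) == 0) stop("gini undefined for an all-zero vector")
  sum(abs(outer(x, x, "-"))) / (2 * length(x)^2 * mean(x))
}

# (I, SI) objective of an ordering: I counts dyads where the lower-ranked
# individual dominates the higher-ranked one; SI sums their rank distances.
isi_objective <- function(R, ord) {
  Ro <- R[ord, ord]
  inc <- which(lower.tri(Ro) & !is.na(Ro) & Ro == 1, arr.ind = TRUE)
  c(I = nrow(inc), SI = if (nrow(inc)) sum(inc[, 1] - inc[, 2]) else 0)
}

isi_better <- function(a, b) {
  a[1] < b[1] || (a[1] == b[1] && a[2] < b[2])
}

# Pairwise-swap hill climbing from a starting order.
isi_climb <- function(R, ord) {
  obj <- isi_objective(R, ord)
  n <- length(ord)
  repeat {
    improved <- FALSE
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        cand <- ord
        cand[c(a, b)] <- cand[c(b, a)]
        co <- isi_objective(R, cand)
        if (isi_better(co, obj)) {
          ord <- cand; obj <- co; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(ord = ord, obj = obj)
}

#' I&SI rank order
#'
#' Orders individuals to minimise, lexicographically, the number of
#' inconsistencies I (dyads in which a lower-ranked individual dominates a
#' higher-ranked one) and their total strength SI (sum of the rank distances
#' of inconsistent dyads). Uses pairwise-swap hill climbing started from the
#' David's-score order, with randomised restarts.
#'
#' @param W Win/loss matrix.
#' @param n_tries Number of restarts (the first always starts from the
#'   David's-score order).
#' @param seed Optional RNG seed.
#' @return Character vector of ids in rank order, with attributes `I` and
#'   `SI` holding the achieved objective.
#' @export
rank_isi <- function(W, n_tries = 50, seed = NULL) {
  W <- check_matrix(W)
  R <- dominance_relation(W)
  ids <- rownames(W)
  start <- match(rank_davids(W), ids)
  with_seed(seed, {
    best <- isi_climb(R, start)
    for (t in seq_len(max(0L, n_tries - 1L))) {
      pert <- best$ord
      sw <- sample(length(pert), 2L)
      pert[sw] <- pert[rev(sw)]
      cand <- isi_climb(R, pert)
      if (isi_better(cand$obj, best$obj)) best <- cand
    }
    structure(ids[best$ord], I = unname(best$obj[1]), SI = unname(best$obj[2]))
  })
}

#' Full sociomatrix metrics report
#'
#' Computes every group-level hierarchy measure on one win/loss matrix —
#' Landau's modified h', triangle transitivity, steepness, directional
#' consistency, despotism (alpha = rank 1 of the David's-score order) and
#' Gini coefficients of wins and losses — together with randomization
#' p-values for h', ttri, steepness and DC.
#'
#' @param W Win/loss matrix (>= 3 individuals, >= 1 event).
#' @param M Number of randomizations for each p-value.
#' @param n_resolutions Random resolutions for h' (point estimate); the
#'   randomization test for h' uses `null_resolutions` per replicate.
#' @param null_resolutions Resolutions per replicate inside the h' null.
#' @param dyadic_correction Passed to [davids_scores()].
#' @param seed Optional RNG seed.
#' @return Object of class `metrics_report`: a list with the metric values,
#'   p-values, `n_events`, `n_individuals` and the configuration used.
#' @export
full_report <- function(W, M = 1000, n_resolutions = 1000,
                        null_resolutions = 100,
                        dyadic_correction = FALSE, seed = NULL) {
  W <- check_matrix(W, min_n = 3L)
  tt <- triangle_transitivity(W)
  ranking <- rank_davids(W, dyadic_correction)
  seeds <- derive_seeds(seed, 4L)
  out <- list(
    h_prime = landaus_h_prime(W, n_resolutions, seed = seeds[1]),
    p_h_prime = randomization_p(W, "h_prime", M = M, seed = seeds[1],
                                n_resolutions = null_resolutions),
    ttri = tt$ttri,
    p_ttri = if (is.na(tt$ttri)) NA_real_ else
      randomization_p(W, "ttri", M = M, seed = seeds[2]),
    steepness = steepness(W, dyadic_correction),
    p_steepness = randomization_p(W, "steepness", M = M, seed = seeds[3],
                                  dyadic_correction = dyadic_correction),
    dc = directional_consistency(W),
    p_dc = randomization_p(W, "dc", M = M, seed = seeds[4]),
    despotism = despotism(W, ranking),
    gini_wins = gini(rowSums(W)),
    gini_losses = gini(colSums(W)),
    n_events = sum(W),
    n_individuals = nrow(W),
    config = list(M = M, n_resolutions = n_resolutions,
                  null_resolutions = null_resolutions,
                  dyadic_correction = dyadic_correction, seed = seed)
  )
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("Dominance hierarchy metrics (", x$n_individuals, " individuals, ",
      x$n_events, " events)\n", sep = "")
  m <- c("h'" = x$h_prime, ttri = x$ttri, steepness = x$steepness,
         DC = x$dc, despotism = x$despotism,
         "Gini wins" = x$gini_wins, "Gini losses" = x$gini_losses)
  p <- c(x$p_h_prime, x$p_ttri, x$p_steepness, x$p_dc, NA, NA, NA)
  tab <- data.frame(value = round(m, digits),
                    p = ifelse(is.na(p), "", format.pval(p, digits = 2)))
  print(tab, ...)
  invisible(x)
}

#' Convert a metrics report to a one-row data.frame
#'
#' Columns follow the conventional reporting order: h', ttri, steepness, DC,
#' despotism, Gini of wins, Gini of losses, then the p-values and sizes.
#'
#' @param x A `metrics_report`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments.
#' @export
as.data.frame.metrics_report <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(h_prime = x$h_prime, ttri = x$ttri, steepness = x$steepness,
             dc = x$dc, despotism = x$despotism,
             gini_wins = x$gini_wins, gini_losses = x$gini_losses,
             p_h_prime = x$p_h_prime, p_ttri = x$p_ttri,
             p_steepness = x$p_steepness, p_dc = x$p_dc,
             n_events = x$n_events, n_individuals = x$n_individuals,
             row.names = row.names)
}
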