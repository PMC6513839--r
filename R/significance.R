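# Randomization-based inference: null schemes for sociomatrix metrics and
# the QAP matrix-correlation test.

#' Randomize a sociomatrix under a null scheme
#'
#' Two null schemes are available. `dyad_bernoulli` keeps each dyad's total
#' interaction count n_ij and redistributes its outcomes as Binomial(n_ij,
#' 0.5) — the natural null for frequency-based metrics (DC, steepness).
#' `tournament_uniform` keeps only which dyads interacted and redirects each
#' interacting dyad uniformly at random as a binary tournament — the natural
#' null for order-based metrics (h', ttri).
#'
#' @param W Win/loss matrix.
#' @param scheme `"dyad_bernoulli"` or `"tournament_uniform"`.
#' @return A randomized matrix of the same shape (integer counts for
#'   `dyad_bernoulli`; binary for `tournament_uniform`).
#' @export
randomize_matrix <- function(W,
                             scheme = c("dyad_bernoulli",
                                        "tournament_uniform")) {
  scheme <- match.arg(scheme)
  W <- check_matrix(W)
  n <- nrow(W)
  up <- which(upper.tri(W), arr.ind = TRUE)
  lo <- up[, 2:1, drop = FALSE]
  n_ij <- W[up] + W[lo]
  out <- matrix(0, n, n, dimnames = dimnames(W))
  if (scheme == "dyad_bernoulli") {
    wins_upper <- stats::rbinom(nrow(up), n_ij, 0.5)
    out[up] <- wins_upper
    out[lo] <- n_ij - wins_upper
  } else {
    dir_upper <- stats::runif(nrow(up)) < 0.5
    out[up] <- as.numeric(n_ij > 0 & dir_upper)
    out[lo] <- as.numeric(n_ij > 0 & !dir_upper)
  }
  out
}

# Named metric functions usable as randomization statistics.
metric_function <- function(statistic) {
  switch(statistic,
    h_prime = function(W, n_resolutions = 100, ...)
      landaus_h_prime(W, n_resolutions = n_resolutions),
    ttri = function(W, ...) triangle_transitivity(W)$ttri,
    dc = function(W, ...) directional_consistency(W),
    steepness = function(W, dyadic_correction = FALSE, ...)
      steepness(W, dyadic_correction),
    despotism = function(W, ...) despotism(W),
    gini_wins = function(W, ...) gini(rowSums(W)),
    gini_losses = function(W, ...) gini(colSums(W)),
    stop("unknown statistic: ", statistic)
  )
}

# Default null scheme per statistic: order-based metrics are tested against
# uniform tournaments, frequency-based metrics against within-dyad Bernoulli
# redistribution.
default_scheme <- function(statistic) {
  if (statistic %in% c("h_prime", "ttri")) "tournament_uniform"
  else "dyad_bernoulli"
}

#' Randomization p-value for a sociomatrix metric
#'
#' One-sided permutation p-value: the proportion of `M` randomized matrices
#' whose statistic is greater than or equal to the observed value, with the
#' add-one correction \eqn{p = (1 + \#\{rand \ge obs\})/(M + 1)} so p is
#' never exactly zero.
#'
#' @param W Win/loss matrix.
#' @param statistic Either a metric name (`"h_prime"`, `"ttri"`, `"dc"`,
#'   `"steepness"`, `"despotism"`, `"gini_wins"`, `"gini_losses"`) or a
#'   function `W -> numeric`.
#' @param M Number of randomizations.
#' @param scheme Null scheme (see [randomize_matrix()]); defaults to
#'   `tournament_uniform` for h'/ttri and `dyad_bernoulli` otherwise.
#' @param seed Optional RNG seed.
#' @param ... Passed to the statistic function (e.g. `n_resolutions` for
#'   h').
#' @return p-value in [1/(M+1), 1], with attributes `observed`, `scheme`,
#'   `M`.
#' @export
randomization_p <- function(W, statistic, M = 1000, scheme = NULL,
                            seed = NULL, ...) {
  if (M < 1) stop("M must be >= 1")
  if (is.character(statistic)) {
    if (is.null(scheme)) scheme <- default_scheme(statistic)
    stat_fun <- metric_function(statistic)
    stat_name <- statistic
  } else {
    stat_fun <- match.fun(statistic)
    stat_name <- "custom"
    if (is.null(scheme)) scheme <- "dyad_bernoulli"
  }
  observed <- stat_fun(W, ...)
  if (is.na(observed))
    stop("statistic '", stat_name, "' is undefined on this matrix")
  with_seed(seed, {
    null_vals <- vapply(seq_len(M), function(r) {
      stat_fun(randomize_matrix(W, scheme), ...)
    }, numeric(1))
    exceed <- sum(null_vals >= observed, na.rm = TRUE)
    structure((1 + exceed) / (M + 1),
              observed = observed, scheme = scheme, M = M)
  })
}

#' QAP matrix correlation test
#'
#' Quadratic Assignment Procedure: Pearson correlation of the off-diagonal
#' cells of two sociomatrices over the same individuals, with a permutation
#' null built by applying the same random vertex-label permutation to the
#' rows and columns of the second matrix (preserving its dyadic structure)
#' and recomputing the correlation.
#'
#' @param A,B Square matrices sharing ids and ordering.
#' @param n_perm Number of Monte Carlo permutations (default 1000).
#' @param seed Optional RNG seed.
#' @return Object of class `qap`: list with `r`, `p_greater`, `p_lower`
#'   (add-one-corrected tails) and `n_perm`.
#' @export
qap_correlation <- function(A, B, n_perm = 1000, seed = NULL) {
  A <- check_matrix(A); B <- check_matrix(B)
  if (nrow(A) != nrow(B) || !identical(rownames(A), rownames(B)))
    stop("A and B must share ids and ordering")
  a <- offdiag(A)
  b <- offdiag(B)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("QAP undefined: off-diagonal cells have zero variance")
  r <- stats::cor(a, b)
  n <- nrow(A)
  with_seed(seed, {
    r_perm <- vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      stats::cor(a, offdiag(B[p, p]))
    }, numeric(1))
    out <- list(r = r,
                p_greater = (1 + sum(r_perm >= r)) / (n_perm + 1),
                p_lower = (1 + sum(r_perm <= r)) / (n_perm + 1),
                n_perm = n_perm)
    class(out) <- "qap"
    out
  })
}

#' @export
print.qap <- function(x, ...) {
  cat("QAP matrix correlation\n")
  cat(sprintf("  r = %.3f  (%d permutations)\n", x$r, x$n_perm))
  cat(sprintf("  p(perm >= r) = %.4g   p(perm <= r) = %.4g\n",
              x$p_greater, x$p_lower))
  invisible(x)
}
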