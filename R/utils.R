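#' @keywords internal
"_PACKAGE"

#' The five-behavior ethogram
#'
#' Behavior labels recognised in agonistic event logs, in priority order
#' (highest first) for the co-occurrence priority rule: an animal wins an
#' encounter by fighting, chasing, mounting, or by forcing the other to show
#' a subordinate posture or to flee.
#'
#' @return Character vector of the five behavior labels.
#' @export
ethogram <- function() {
  c("fighting", "chasing", "mounting", "subordinate_posture", "induced_flee")
}

# Run code with a temporarily seeded RNG; restores (or removes) .Random.seed
# afterwards so seeded calls do not perturb the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed) || (length(seed) == 1L && is.na(seed)))
    return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Off-diagonal cells of a square matrix as a vector (column-major order).
offdiag <- function(m) {
  m[row(m) != col(m)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive n child seeds from one master seed (kept below 2^31 so they are
# valid R integer seeds); random child seeds when the master is NULL.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# Deterministic rank order used throughout: by score descending, then total
# wins descending, then label. Returns ids in rank order (rank 1 first).
order_ids <- function(ids, score, wins) {
  ids[order(-score, -wins, ids)]
}
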