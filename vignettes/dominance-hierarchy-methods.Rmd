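---
title: "Methods: dominance-hierarchy metrics, randomization inference and the synthetic colony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominance-hierarchy metrics, randomization inference and the synthetic colony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domhier)
```

`domhier` analyses dominance structure in stable groups of animals from
logs of timed winner/loser interactions. This vignette explains the models
and statistics, the tunable parameters and their defaults, the numerical
choices, what the synthetic generator does and does not emulate, and the
package's known limitations.

## The data model

An event log is one row per agonistic interaction: cohort, 1-based
observation day, optional within-session time in seconds, winner (`actor`),
loser (`recipient`), and one of five behaviors — fighting, chasing,
mounting, subordinate posture, induced flee. The winner is always the
animal that *forced* the outcome: for subordinate-posture and induced-flee
events the actor is the animal that elicited the display or flight, not the
displaying animal. Days are session-relative; the default observation
schedule is 14 days at 2 observed hours per day, and all hourly rates use
these observed hours as denominators.

When several behaviors between the same pair co-occur within a short window
(2 s by default), field protocols record only the highest-priority one
(fighting > chasing > mounting > subordinate posture > induced flee).
`apply_priority_rule()` reproduces this on raw logs. Because chains of
co-occurrence are ambiguous, the window is anchored at the *earliest* event
of each same-dyad cluster, the whole cluster resolves to the single
highest-priority event, and the kept event carries the anchor time. This
makes the rule deterministic, independent of input row order, and
idempotent (re-running it never merges further events), all of which are
property-tested.

## Sociomatrix metrics

All group-level metrics operate on the win/loss frequency sociomatrix
`W[i, j]` = wins of row `i` over column `j`, or on its dyadic binarization
(win / loss / tie / unknown).

**David's scores.** `P_ij = s_ij / n_ij` is the dyadic win proportion
(0 for unobserved dyads); each individual accumulates `w = Σ P_ij`,
`w2 = Σ P_ij w_j`, `l = Σ P_ji`, `l2 = Σ P_ji l_j`, and
`DS = w + w2 − l − l2`, normalised as `NormDS = (DS + N(N−1)/2) / N` onto
`[0, N−1]`. David's scores sum to zero by construction; the suite checks
this to 1e-9 absolute. The literature also uses a sample-size-corrected
proportion `D_ij = P_ij − (P_ij − 0.5)/(n_ij + 1)` that shrinks sparsely
observed dyads toward 0.5. Raw `P_ij` is the default here because the
score is defined as a win-proportion measure; the correction is available
as `dyadic_correction = TRUE`, and both variants are tested. **Steepness**
is the absolute OLS slope of descending NormDS against rank 1..N — exactly
1 for a perfectly linear, fully decided matrix, 0 when all scores tie.

**Landau's modified h′.** For a complete binary tournament,
`h = 12/(N³−N) · Σ_a (V_a − (N−1)/2)²` with `V_a` the number of animals
that `a` dominates. Real matrices contain tied and never-observed dyads, so
h′ directs each undecided dyad at random (probability 0.5 each way) and
averages h over `n_resolutions` independent resolutions (default 1000,
vectorised over resolutions so this is cheap). With no undecided dyads the
value equals h exactly, regardless of seed. The closed-form tie correction
is not used: the resolution average is simple, seedable, and converges to
the same quantity. A 3-individual sanity point is exact by enumeration:
random tournaments are transitive 6/8 of the time, so E[h] = 0.75, which
both the enumeration and the resolution average reproduce in the suite.

**Triangle transitivity.** Among triads whose three dyads are all strictly
decided, `P_t` is the transitive fraction and `ttri = 4(P_t − 0.75)`, so 0
is the random-tournament expectation and 1 means no cycles. Triads
containing a tie or unknown dyad are excluded; with no complete triad the
statistic is reported as NA rather than a number. Internally the count uses
the directed-trace identity (cycles = tr(D³)/3 on the decided adjacency),
verified against explicit triad enumeration for N ≤ 6.

**Directional consistency, despotism, Gini.**
`DC = Σ_dyads (max − min) / Σ_dyads (s_ij + s_ji)`: tied dyads contribute 0
to the numerator but their events to the denominator. Despotism is the
top-ranked animal's share of all wins; "top-ranked" defaults to rank 1 of
the David's-score order because that ranking is intrinsic to the matrix
(ties broken by total wins, then label, so results are deterministic).
Gini uses the pairwise-difference form `Σ|x_i − x_j| / (2 n² mean(x))` on
win (or loss) counts; it errors on all-zero vectors rather than returning
a conventional value.

**I&SI ranking.** The I&SI order minimises, lexicographically, the number
of inconsistent dyads (a lower-ranked animal dominating a higher-ranked
one) and then their summed rank distances. This is a combinatorial problem;
the package uses pairwise-swap hill climbing started from the David's-score
order with randomised restarts (default 50). The heuristic can in principle
miss the global optimum on large, noisy matrices, but it never does worse
than its starting order, and it matches exhaustive permutation search on
all tested matrices up to N = 5.

## Randomization inference

P-values are one-sided Monte-Carlo tail probabilities: the proportion of
randomized matrices whose statistic is at least the observed value, with
the add-one correction `p = (1 + #{rand ≥ obs}) / (M + 1)` so p is never 0
and the minimum attainable p is `1/(M+1)`. Two null schemes are provided:

* `dyad_bernoulli` keeps every dyad's interaction total `n_ij` and redraws
  outcomes as Binomial(`n_ij`, 0.5) — the default null for frequency-based
  statistics (DC, steepness; steepness has no canonical published null, so
  this choice is explicit and configurable).
* `tournament_uniform` keeps only which dyads interacted and redirects each
  as a fair binary coin — the default null for order-based statistics
  (h′, ttri).

Inside the h′ randomization test, each null replicate evaluates h′ with 100
resolutions (the point estimate uses 1000): the observed value entering the
comparison is computed with the same resolution count as the null
replicates, so the test compares like with like; the suite's calibration
checks (p roughly uniform when the data are generated under the null, at
M = 1000) pass under this setting. The QAP test correlates the off-diagonal
cells of two behavior-specific matrices and permutes vertex labels jointly
on rows and columns — never cells independently — preserving dyadic
structure; both tails are returned since published uses report either.

## Glicko ratings

Each behavioral event is one rating period: every individual's deviation is
first inflated to `min(√(RD² + c²), 350)` and the two participants then
receive the standard Glicko one-game update (scores 1/0). Defaults: initial
rating 2200, initial deviation 300, c = 3, cap 350, `q = ln(10)/400`. The
per-event reading of the inflation constant is the natural interpretation
of recalculating ratings after every interaction; since c is small relative
to the deviations, batching choices barely move the trajectories, and all
four constants are configuration fields. Rank ties at any point break by
(rating, total wins so far, label) so trajectories are deterministic. The
most-dominant / most-subordinate selection takes the top-k and bottom-k by
final Glicko rating and flags whether the David's-score order selects the
same sets; on disagreement both candidate sets are reported rather than
silently preferring one system.

## Emergence and estrous summaries

`emergence_by_day()` recomputes h′ and ttri with randomization p-values on
the cumulative matrix through each day. "Significantly linear" means
p ≤ 0.05 for h′ (ttri significance is tracked in parallel), and
`first_stable_day` is the earliest day from which the h′ flag holds through
the final day — a day of significance followed by a lapse does not count.
Estrous summaries are purely descriptive: per-individual state proportions
over determined smear days (undetermined days leave the denominator and are
reported separately), rank-by-state day-count crosstabs against any
supplied ranking (the caller chooses the ranking; the I&SI order is what
the bundled pipeline passes), and median/IQR hourly rates per behavior and
cycle state, assigning each individual-day's rate to that day's state. No
regression models are fitted on these tables.

## The synthetic colony generator

The generator exists so every stage of the pipeline can run, be tested, and
demonstrate parameter recovery without external data. Defaults describe one
study-design condition and were fixed once:

| parameter | default | meaning |
|---|---|---|
| `n_individuals` | 12 | females per cohort |
| `n_days` × `hours_per_day` | 14 × 2 h | observation schedule |
| `base_event_rate` | 12 /h | group-level day-1 event rate |
| `fight_decay` | 0.85 | daily multiplicative decline of fighting only |
| `consistency` | 0.9 | P(higher latent rank wins a dyadic encounter) |
| `despotism_weight` | 0.25 | initiator weight ∝ exp(−α(rank−1)) |
| `behavior_mix` | 0.35/0.45/0.20 | fighting/chasing/mounting |
| `mount_prop` | 0.5 | fraction of females that ever mount |
| `estrus_dwell` | P1 E2 M1 D2 days | mean dwell per cycle state |
| `estrus_gradient` | +1 day | extra mean estrus dwell, bottom→top rank |

Event counts are Poisson per day with the day-adjusted mix (only fighting
decays — chasing and mounting rates are stable); the initiator is sampled
by the despotism weights, the partner uniformly, and the winner is the
higher-ranked member of the dyad with probability `consistency` (a
rank-threshold Bernoulli rather than a distance-based model, because it
keeps DC analytically predictable: E[DC] → 2·consistency − 1 in the
many-events limit; a logistic option exists). Behaviors are drawn from the
adjusted mix, and a mounting draw whose winner is outside the
mount-propensity subset redraws between fighting and chasing — mounting
inequality is thus a propensity-subset effect, reproducing a high mounting
Gini qualitatively without targeting any particular value. Estrous
sequences cycle proestrus → estrus → metestrus → diestrus with geometric
dwells (support ≥ 1 day); the estrus dwell mean rises linearly with rank by
`estrus_gradient`, emulating extended estrus in dominant group-housed
females, and each daily smear is unreadable with probability 0.02.

What the generator does *not* emulate: within-day temporal clustering of
events (times are uniform within sessions, so the priority rule rarely
fires on simulated logs), coalitions or audience effects, rank changes over
time (the latent order is fixed), body-mass covariates, and any coupling
between estrous state and behavior rates. Passing tests therefore show that
the estimators recover the structure this generator builds in — linearity,
directional consistency, despotism gradients, estrus-dwell gradients — not
that real colonies satisfy those structural assumptions.

Parameter recovery judges monotonicity where the quantity is identifiable:
DC and ttri across the consistency grid at the least concentrated
initiation (extreme concentration leaves low-rank dyads unsampled and makes
transitivity estimates degenerate), and despotism across the concentration
grid at the strongest hierarchy (without a hierarchy there is no
well-defined alpha whose share could grow). The Glicko-vs-truth agreement
check uses Spearman correlation of the final rating order with the latent
order.

## Numerical choices and degenerate inputs

* Σ DS = 0 and similar identities are asserted at 1e-9 absolute tolerance.
* h′ resolutions: 1000 for point estimates, 100 per replicate inside
  randomization nulls; both configurable.
* All randomized procedures take explicit seeds; a master seed derives
  per-component child seeds (kept below 2³¹) so multi-cohort runs are
  exactly reproducible and components can be re-run independently.
* Matrices with no complete triad report ttri as NA; cohorts with fewer
  than 3 individuals or no usable events produce an all-NA metrics row
  with a warning in the bundled pipeline rather than an error.
* DC, despotism and Gini error on empty input rather than guessing; an
  all-undetermined smear series yields NA proportions.
* Rank ties anywhere break by (score, total wins, label).

The test suite runs the full pipeline at reduced Monte-Carlo sizes —
typically M = 100–1000 randomizations, 20–200 h′ resolutions, cohorts of 12
over 3–14 days, and 12–40 simulation replicates per property — sizes chosen
so the whole suite exercises every code path in well under a minute of
statistical computation while keeping Monte-Carlo error far from the
asserted bounds.

## Limitations

* The I&SI search is heuristic; global optimality is only guaranteed where
  it was verified exhaustively (small N).
* h′ inference treats resolutions as exchangeable Monte-Carlo draws; for
  very sparse matrices (most dyads unknown) the resolution variance
  dominates and h′ is close to its null mean by construction.
* Despotism depends on the supplied ranking's first element only; with a
  weak hierarchy the David's-score alpha is unstable and despotism should
  be read descriptively.
* The estrous summaries are descriptive; modelling rank or rate effects on
  cycle state is out of scope, as are eigenvector/Elo rating alternatives
  and network visualisation.
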