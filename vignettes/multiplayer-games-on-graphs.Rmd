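---
title: "Weak-selection analysis of multiplayer games on regular graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak-selection analysis of multiplayer games on regular graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphgames)
```

## The model

A population of `N` haploid individuals sits on the vertices of a connected
`k`-regular graph. Each individual plays one of two strategies, `A`
("cooperate") or `B` ("defect"), and collects its payoff from a single
symmetric `d`-player game with its `k` immediate neighbors, so `d = k + 1`.
The payoff table is indexed by the number `j = 0, ..., d - 1` of `A`-players
among the `d - 1` co-players: an `A`-player receives `a_j`, a `B`-player
`b_j`.

Evolution follows a Moran death-Birth process: at each time step a uniformly
random individual dies, and its `k` neighbors compete to place a copy of
themselves on the vacated vertex with probability proportional to fitness
`1 - w + w * payoff`, where `w >= 0` is the intensity of selection. Without
mutation the process has two absorbing states (all-`A`, all-`B`). Writing
`rho_A` for the fixation probability of a single `A` mutant in a `B`
population and `rho_B` for the converse, we say `A` is favored over `B` when
`rho_A > rho_B`.

## The sigma rule and structure coefficients

Under weak selection (`w << 1`) the comparison `rho_A > rho_B` reduces to a
linear condition on the payoffs, the *sigma rule*:

$$\sum_{j=0}^{d-1} \varsigma_j f_j \;>\; 0, \qquad
  f_j = a_j - b_{d-1-j},$$

where the `f_j` are the *gains from flipping* — the payoff change a focal
`B`-player with `j` cooperating co-players would experience if everyone in
the group swapped strategies simultaneously — and the normalized structure
coefficients `varsigma_0, ..., varsigma_{d-1}` are nonnegative constants
summing to one that depend on the population structure and update rule but
not on the payoffs. Because they are normalized, the coefficients define a
probability distribution over the number `J` of co-players using the focal
strategy, and the rule reads: `A` is favored when the expected gains from
flipping `E[f(J)]` are positive.

The package computes these coefficients for four structures:

* `wellmixed_coefficients(N, d)` — random group formation in an unstructured
  population: `varsigma_j = N / (d(N-1))` for `j <= d - 2` and
  `(N-d)/(d(N-1))` for `j = d - 1`; uniform `1/d` as `N -> Inf`.
* `cycle_coefficients(N)` — the cycle (`k = 2`), where the coefficients are
  exact: `(1, N-2, N-3) / (2(N-2))`, tending to `(0, 1/2, 1/2)`. In the
  large-`N` limit the sigma rule becomes `a_1 + a_2 > b_1 + b_0`, the
  condition for the boundary between a cluster of `A`s and a cluster of `B`s
  to advance; configurations in which a player faces two opposite-strategy
  neighbors never matter, which is why `f_0` drops out.
* `regular_graph_coefficients(k)` — a large-`N` pair-approximation /
  diffusion-approximation estimate for degree `k >= 3`, the analytical core
  of the package (next section).
* `cycle_overlapping_coefficients(N)` — the cycle again, but under the
  alternative convention in which payoffs accumulate over the `k + 1` games
  centered on the focal player and on each of its neighbors.

## The regular-graph approximation and how it is pinned down

For `k >= 3` the coefficients are computed from a closed-form expression
involving two auxiliary binomial sums, with the convention that a binomial
coefficient with an out-of-range lower index is zero and that the single
negative power of `k - 2` arising at `j = k` is an ordinary reciprocal
(`k - 2 >= 1` throughout). The algebra behind the expression assumes the
graph is locally tree-like (a Bethe lattice), `N >> k`, and `w k << 1`.

Because a typeset formula of this shape is easy to mis-transcribe, the
implementation is pinned by three independent anchors, all enforced in the
test suite:

1. at `k = 3` the normalized vector equals `(7, 31, 61, 45) / 144` to
   `1e-12`;
2. the mean identity `sum_j j * varsigma_j = (k + 1)/2` holds for every
   `k = 3..100` to `1e-9`;
3. the reciprocal of the last coefficient equals
   `k(k+1)(k-2) / ((k-1)^2 - (k-1)^{1-k})` for every `k = 3..100` to `1e-9`.

Any grouping of the terms that fails one of these checks is rejected. The
normalization constant in the formula already makes the coefficients sum to
one; the implementation renormalizes anyway so that the class invariant does
not depend on that algebraic fact.

### Numeric representation

The cycle, well-mixed and overlapping-cycle coefficients are ratios of small
integers, and the thresholds derived from them are meaningful as exact
fractions; these carry an exact rational representation (integer numerators
over a common denominator, reduced with Euclid's algorithm on machine
integers), and `critical_bc_vd(sc, exact = TRUE)` returns a fraction object.
All integers involved stay far below 2^53 for every supported `N`, so the
arithmetic is exact. The `k >= 3` approximation is evaluated in double
precision: its binomial terms reach magnitudes like `C(99, 49)` against
powers `98^{-99}`, which are exactly representable only in big-integer
rationals, and every check on that vector carries a `1e-9` (or `1e-12` at
`k = 3`) tolerance that double precision meets with orders of magnitude to
spare.

## Thresholds and the containment order

For the volunteer's dilemma (one cooperator produces a public good `B` at
personal cost `C`; payoffs `a_j = B - C`, `b_0 = 0`, `b_j = B` for
`j >= 1`) the sigma rule collapses to `B/C > 1/varsigma_{d-1}`:
`2(N-2)/(N-3)` on the cycle (tending to 2), `k + 1` in a large well-mixed
population. With the cost shared among cooperators
(`a_j = B - C/(j+1)`) the threshold becomes
`(1/varsigma_{d-1}) * sum_j varsigma_j/(j+1)`, which is `5/6` on a large
cycle — below one, so cooperation can be favored even when the benefit is
smaller than the nominal cost. Both closed forms are verified in the tests
against an independent bisection of the sigma rule on the payoff
constructors themselves.

Two sanity reductions are implemented as their own predicates: for sums of
pairwise games the multiplayer rule collapses (via the mean identity) to
`(k+1)α + (k-1)β - (k-1)γ - (k+1)δ > 0`, hence `B/C > k` for the donation
game, and for payoffs linear in `j` it collapses to `2B + D(k+1) > 2Ck`.

One structure promotes cooperation more than another when its set of
cooperation games (payoffs nondecreasing in `j` for both strategies)
favoring `A` contains the other's — the *containment order*. A single
`-` to `+` sign change in the difference of coefficient vectors is
sufficient. `containment_scan()` verifies this for regular graphs of degree
`k = 3..100` against the well-mixed baseline. Two conventions are fixed
here, both genuinely open choices:

* the well-mixed baseline is the large-population limit (uniform `1/d`),
  matching the large-graph limit built into the `k >= 3` approximation;
  finite-`N` scans are possible but compare structures at different
  population sizes, which the containment argument does not license;
* zeros are skipped when counting sign changes — `varsigma_0 = 0` occurs
  exactly at the large-`N` cycle, and a zero entry neither creates nor
  breaks a run of like signs.

Exact zero of the sigma-rule left-hand side is reported as "not favored"
with an explicit boundary flag, since the favorability condition is a strict
inequality.

## Simulation design

`fixation_probability()` estimates `rho_A` (or `rho_B`) as the fraction of
independent realizations, each started from a single mutant at a uniformly
random vertex, that end in the mutant's absorbing state. The placement
convention matters only on graphs that are not vertex-transitive (random
regular graphs). Design choices:

* **Dying individual counts.** Competing neighbors' payoffs are evaluated on
  the state before the focal death. The empty site exists only notionally
  within one update, and this matches the standard death-Birth formulation.
  The choice is isolated in one place (`db_step()` and the compiled loop)
  so its sensitivity can be probed.
* **Fitness positivity** (`1 - w + w * payoff > 0` over the whole table) is
  checked up front and violation is a configuration error, never a runtime
  clamp.
* **Determinism.** The compiled loop consumes R's own RNG stream, so a
  single `set.seed()` reproduces every run bit for bit. Runs execute
  sequentially in one stream; per-run counter-derived substreams would allow
  order-independent parallel execution, but no parallel path exists in the
  package and the single stream keeps the machinery minimal.
* **No-op skipping.** A death at a vertex whose neighbors all share its
  strategy replaces it with an identical copy regardless of fitness values.
  The compiled core draws the dying vertex uniformly from the complementary
  "active" set instead of from all vertices. The embedded jump chain over
  state changes is identical, so fixation probabilities are unchanged
  exactly — not approximately — while runs on large sparse graphs skip the
  vast majority of updates. The R-level `db_step()` keeps the plain
  uniform-death semantics and serves as the reference implementation.

`exact_fixation()` is the oracle: for `N <= 14` it assembles the full
`2^N`-state transition matrix and solves the absorption system with a sparse
LU factorization. One solve yields both `rho_A` and `rho_B` (the latter from
the single-`B` states). Monte Carlo estimates are required, in the tests, to
sit within three binomial standard errors of the exact values both at
neutrality and under selection — this is the cross-check that ties the
compiled path, the R reference dynamics and the theory together.

### Problem sizes

The validation suite works at desk scale: exact chains up to `N = 10`,
Monte Carlo runs of `10^5` per point, and a cycle of `N = 100` for the
simulated threshold crossing at `w = 0.01`, `C = 1`, `B/C` in
`{1.8, 2.0, 2.2}` (analytic crossing at `2(98)/97 ≈ 2.02`). A binomial
standard error at `10^5` runs resolves differences of order `10^-3` in
fixation probabilities, which is enough to pin the sign pattern around the
crossing; mapping out entire sweep curves with visually smooth symbols, as
in large simulation studies of this model, takes run counts two orders of
magnitude larger and adds nothing to the correctness argument.

## What the generated inputs do and do not emulate

Graphs are generated, not measured: rings place each vertex between `k/2`
neighbors on either side; lattices are periodic (toroidal), because open
boundaries would break exact regularity, which the theory requires; the
6-neighbor "hexagonal" tiling is built as the triangular lattice on a torus;
random regular graphs come from uniform sampling with rejection of
disconnected draws (retry cap `10^4`). These are the idealized families the
theory speaks about. Passing tests therefore show agreement between the
analytics and the model's own dynamics — they say nothing about
heterogeneous-degree networks, weighted or dynamic interactions, mutation,
or strong selection, all of which are outside the model. The pair
approximation itself is expected to be biased on rings with `k >= 4` and on
lattices, whose short loops violate the tree-likeness assumption; the
package's simulator is precisely the tool for measuring that bias, and the
exact cycle formulas bound it from the `k = 2` side.

## Degenerate inputs and tie-breaks

* `normalize_coefficients()` rejects all-zero and negative input rather than
  guessing.
* `sign_changes()` on an all-zero vector is an error (no pattern exists).
* A threshold with `varsigma_{d-1} = 0` is reported as `Inf`: cooperation in
  the volunteer's dilemma is never favored under such coefficients.
* Rings require `N >= k + 2` and the degree-8 Moore lattice a side of at
  least 4; smaller sizes would wrap neighbors onto duplicates (or, for the
  3-sided Moore torus, collapse the lattice into a complete graph).
* The exact-chain solver refuses `N > 14` (state space `2^N`).

## Known limitations

* The `k >= 3` coefficients are a large-`N` approximation; there is no
  finite-`N` correction implemented, and no exact method for general graphs
  (coalescent-based routes exist but are out of scope).
* Only death-Birth updating is covered; Birth-death and imitation rules have
  different — and for cooperation, much less favorable — coefficients.
* Two strategies, symmetric payoffs, no mutation.
* The containment test is one-sided: "incomparable_by_this_test" means the
  sufficient condition failed, not that the structures are provably
  incomparable.
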