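---
title: "The structural coefficient of group-structured populations: model, closed forms, and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The structural coefficient of group-structured populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupsigma)
```

## The model

A population of `N` individuals is distributed over `M` groups arranged on a
circle. Each individual plays one of two strategies, A or B, and plays a
2x2 game with every other member of its own group (optionally also with
itself), accumulating a total payoff `p_i`. Fitness is `1 + w * p_i`; the
regime of interest is weak selection, `w -> 0`.

Reproduction follows the frequency-dependent Moran process. In each
elementary generation one individual is chosen to reproduce proportionally
to fitness and one individual (possibly the parent) is chosen uniformly to
die and is replaced by the offspring. The offspring keeps the parent's
strategy with probability `1 - u`, otherwise it mutates to a strategy drawn
uniformly from {A, B} — so the effective switch probability is `u/2`. It
stays in the parent's group with probability `1 - v`, otherwise it migrates
to a group drawn uniformly from the groups reachable by a single migration
step.

Migration is *isotropic*: the set of reachable displacements looks the same
from every group. An isotropic kernel is fully described by its structure
function `f(x)`, `x = 1..M` — the Fourier spectrum of the displacement
distribution — with `f(M) = 1` (displacement 0 under the periodic boundary)
and `f(x) = f(M - x)`. Two families are built in:

* **range-`r` migration** (`range_pattern`): destinations uniform over all
  groups within circular distance `r`, giving
  `f(x) = (1/r) * sum_{k=1}^{r} cos(2 pi k x / M)`; `r = 1` is
  nearest-neighbour ("local") dispersal. For even `M` with `r = M/2` the
  antipodal group is reachable one way only and the kernel coincides with
  global dispersal.
* **global migration** (`global_pattern`): destinations uniform over the
  other `M - 1` groups, `f(x) = 1` at `x = M` and `-1/(M - 1)` elsewhere.

The two-strategy mutation walk has the analogous spectrum
`g(x) = 1/2 + cos(pi x)/2` (`mutation_structure`), which is what forces the
"uniform over both strategies" mutation convention above: it is the unique
symmetric kernel on a 2-cycle with eigenvalue 0 at the odd mode.

## The structural coefficient

Under weak selection the entire effect of population structure and update
rule on two-strategy competition collapses into one number, the structural
coefficient `sigma`: strategy A is more abundant than B on average in the
mutation-selection stationary distribution iff

```
sigma * a + b > c + sigma * d
```

for payoffs `[[a, b], [c, d]]` (`favors_A`). `sigma` itself is
payoff-independent and is defined under *neutrality* (`w = 0`) as

```
sigma = <I_AA * N_B>_0 / <I_AB * N_B>_0
```

where `I_AA` is the number of A-with-A games (each unordered pair counted
twice, self-games included or not — see below), `I_AB` the number of
A-with-B games, `N_B` the number of B players, and `<.>_0` the neutral
stationary average. Applied to the prisoner's dilemma `[b-c, -c; b, 0]` and
the snowdrift game `[b-c/2, b-c; b, 0]` this yields the critical
cost-to-benefit ratios `(sigma-1)/(sigma+1)` and `2 sigma/(sigma+2)`
(`critical_ratios`), both strictly increasing in `sigma`: larger `sigma`
means more room for cooperation.

### Closed forms

All closed forms are built from scalar kernels evaluated at the structure
values `f(x)` (`pair_kernels`, `triple_kernels`, `mutation_alpha`): the pair
kernels `Psi1`, `Psi2`, the triple kernels `Phi1..Phi3` and the pair
strategy-identity coefficient `alpha1 = (1-u)/(1+(N-1)u)`. These arise as
stationary identity-by-descent-style probabilities of coalescing random
walks of two or three lineages under mutation and migration; each is a
ratio with denominator bounded below by 1 (pair) or 2 (triple), so the
arithmetic needs no numerical guards. With
`Theta = Phi1*Psi2 + Phi2*Psi1 + Phi3*alpha1`, the exact coefficient for
any isotropic pattern is

```
sigma = (N-2) * sum_x (3 Psi1 + 3 Psi2 - 2 Theta)   /   N * sum_x (3 Psi1 - 3 Psi2)
```

without self-interaction (`sigma_exact(..., include_self = FALSE)`);
including self-interaction adds `6 M (1 - alpha1)` to the numerator. The
added term is `24 M * Pr(s1 = 1, s2 = 0)` with the pair probability
`(1 - alpha1)/4`. A note on that normalization: a derivation that tracks
only the two-lineage mutation walk produces the unnormalized weight
`1 - alpha1`; dividing by the `2^2` strategy assignments of an ordered pair
gives the probability, and our exact-chain oracle confirms
`Pr(s1=1, s2=0) = (1 - alpha1)/4` directly
(`pair_probability_by_definition`).

For global migration the sum collapses (`sigma_global_closed`) to a
rational expression in `alpha1..alpha3` and `tau1..tau3`
(`global_coefficients`); the `tau`s are the triple kernels at the
off-diagonal structure value `f = -1/(M-1)`, listed in reverse order of the
`Phi` index (`tau1 = Phi3`, `tau2 = Phi2`, `tau3 = Phi1`), which is the
order in which they pair with `alpha1..alpha3` in the closed form. The
collapse uses the identity `Theta(f = 1) = 3 * alpha1`; we verified it
symbolically (both sides reduce to
`2 (1-u)(3+(N-2)u) / (1+(N-1)u)` after clearing the common denominator) and
it is asserted numerically in the tests.

The package also provides the classical large-population approximation
`sigma_ap` for global migration (`sigma_approx`), a rational function of
`M` and the scaled rates `mu = N u`, `nu = N v` derived by treating
coalescence times as exponential and mutation/migration counts along a
lineage as Poisson. `relative_difference` measures
`|sigma_ac - sigma_ap| / sigma_ac`; it shrinks with growing `N`, with
fewer groups, and with small `u`, `v` — which is precisely the regime the
Poisson/exponential approximations assume.

### Which variant where

At `v = 0` migration never happens and the state in which all individuals
share one group is absorbing, so the long-run population is effectively
well-mixed: the exclude-self form gives exactly `(N-2)/N < 1` while the
include-self form gives exactly 1. Because the migration-effects analyses
(optimal range, interior maximum in `v`) show `sigma < 1` at `v = 0`, they
are carried out on the exclude-self variant; comparisons with the
approximate coefficient use the include-self variant, which is the
convention under which `sigma_ap` was derived. The choice is exposed as
`include_self` everywhere rather than hidden.

### Behaviour in the parameters

Three qualitative facts, each asserted as a property test:

* `sigma` strictly decreases in the mutation probability `u`. The tilt
  `(sigma-1)/(sigma+1)` (`sigma_tilt`) makes this visible analytically.
* `sigma(v)` rises from its `v = 0` value to an interior maximum and then
  falls: a little migration lets a strategy seed new groups (raising
  `I_AA N_B - I_AB N_B` through uneven occupancy), while heavy migration
  homogenizes the distribution of each strategy over groups.
* The migration range `r` maximizing `sigma` moves from the longest range
  at low `v`, through intermediate ranges in a narrow band of medium `v`,
  to `r = 1` at high `v`.

The single-group pair identity (`single_group_paired`) and the two-group
quartet identity (`two_group_quartet`) are the counting engine behind the
second point: summed over symmetry-related states,
`I_AA N_B - I_AB N_B = (k+m)(x-y)^2 + 2N(k-m)^2 - 4xy` and
`I_AB N_B = N(2xy - (k+m)N + 4km)`, so occupying a second group
(`k, m > 0`) and occupying it unevenly (`|k - m|` large) both push `sigma`
up. Both identities are re-verified against brute-force `game_counts`
aggregation on every call.

## Tunable parameters

| parameter | meaning | constraint | typical values |
|---|---|---|---|
| `N` | population size (individuals) | `>= 3` | 20-1000 |
| `M` | number of groups on the circle | `>= 1` | 2-49 |
| `u` | strategy mutation probability per birth | `(0, 1]` for `sigma` | 0.01-0.1 |
| `v` | migration probability per birth | `[0, 1]` | 0-1 |
| `r` | migration range | `1..floor(M/2)` | 1-4 |
| `w` | selection intensity (simulator only) | `>= 0`, small | 0 for `sigma` |
| `include_self` | self-games in `I_AA` / payoffs | logical | see above |

`u = 0` is a genuine 0/0 (the neutral stationary distribution is
monomorphic, both averages vanish) and raises a typed error rather than
returning `NaN`.

## The simulator

`run_neutral_sigma` estimates `sigma` as the ratio of time averages of
`I_AA * N_B` and `I_AB * N_B` over a neutral Moran trajectory. One
"generation" is one birth-death event, matching the oracle's chain step.
Design conventions (the estimator itself fixes none of these):

* burn-in defaults to 5% of the run;
* the standard error comes from 100 batch means — the batchwise ratio
  estimates are treated as approximately independent, which is adequate at
  the run lengths used here;
* the hot loop is compiled (O(1) per event via incremental group-count and
  `sum a_g^2`, `sum a_g b_g` updates) but draws from R's RNG, so a single
  `seed` makes whole runs bit-reproducible.

The default study condition used in the tests is `N = 20`, `M = 5`,
`u = 0.1`, `r = 1` over 2 x 10^6 generations. At that length the
Monte-Carlo standard error is about 1% of `sigma`, small enough to detect a
wrong closed form while keeping the whole suite fast; the agreement
criterion is |estimate - closed form| < 3 SE. The simulator emulates
exactly the model above — it is not a model of any empirical biological
data, so passing tests certify the mathematics, not the applicability of
the Moran/group-structure idealization to a given natural population.

`run_occupancy` records per-group `(count_A, count_B)` snapshots, which is
how the absorbing behaviour at `v = 0` and the full, nearly uniform
occupancy at `v = 1` can be observed directly. The simulator supports
`w > 0` (fitness-proportional reproduction with a configuration error if
`1 + w p_i` goes negative), but the `sigma` estimator deliberately refuses
`w != 0`: the definition of `sigma` lives at neutrality.

## The exact oracle

For tiny `(N, M)` the neutral chain is enumerated exactly
(`oracle_chain`). Individuals are exchangeable, so the vector of counts
over the `2M` (strategy, group) categories is itself a Markov chain; this
exact lumping shrinks, e.g., `(N, M) = (3, 2)` from 64 labelled states to
20 count states. The raw labelled chain is also implemented and the two are
cross-validated. The stationary distribution is a dense linear solve of
`pi P = pi` with a normalization row (state spaces are capped at 10^5 raw
states), with the residual checked at 1e-12.

`sigma_by_definition` and `triplet_probability_by_definition` then compute
`sigma` and the triplet identity probabilities directly from their
definitions — stationary-weighted sums over all states — with no closed
form anywhere in the path. This is the package's ground truth: the closed
forms agree with it to 1e-8 (in practice to machine precision) over a grid
of small instances, both self-interaction variants, and the triplet
probabilities satisfy the bridging identities that connect the raw
triple-index sums to ordered-distinct-triple probabilities, including the
`N^2 (N-1)` (rather than `N (N-1) (N-2)`) factor on the mixed-pair term,
which absorbs the dier-equals-neighbour coincidence.

At `v = 0` the oracle refuses to run: group occupancy is then absorbing
(an emptied group is never repopulated), the chain is reducible, and the
stationary distribution is not unique. The `v = 0` values are handled
analytically instead (`(N-2)/N` and 1, see above).

## Numerical choices

* Structure functions are evaluated as the explicit finite cosine sums
  (via `cospi`, exact at integer arguments), with the analytic global
  closed form `-1/(M-1)` used only as a cross-check; this keeps the
  implementation aligned with the defining sums.
* Closed-form-vs-closed-form identities are tested at 1e-12; closed-form
  vs linear-solver oracle at 1e-8; "the approximation is good in its
  regime" claims at 1% relative difference (the comparison is inherently
  graphical in origin, so the 1% threshold is our own fixed choice).
* The kernels are bounded by 1 in magnitude but are *not* confined to
  `[0, 1]`: at strongly negative structure values (two groups, `v > 1/2`)
  their shared numerator `1 - v + v f` goes negative. This is harmless —
  they are spectral coefficients, not probabilities — and the closed forms
  still match the oracle to machine precision there.
* Displacement indexing is 1-based with `x = M` playing displacement 0,
  matching the periodic boundary `j + lM = j`.

## Limitations

* The closed forms cover two strategies on the circular group lattice with
  isotropic migration; graphs, sets, phenotype spaces, anisotropic or
  weighted kernels are out of scope.
* The oracle is exact but tiny (raw state space `(2M)^N <= 10^5`); for
  realistic sizes the verification chain is closed form vs Monte Carlo.
* `sigma_approx` is only defined for global migration and inherits its
  large-`N`, small-rate validity envelope; use `relative_difference` to
  check before trusting it.
* The simulator's abundance dynamics under selection (`w > 0`) are
  implemented but not part of the verified surface; the weak-selection
  condition itself enters only through `favors_A`.
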