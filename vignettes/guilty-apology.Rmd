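---
title: "Modeling the evolution of guilty apology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the evolution of guilty apology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(meaculpa)
```

## The model

Two players repeatedly play a prisoner's dilemma. Each round both choose
cooperate or defect; the stage payoffs are the classic T = 3 (defect against a
cooperator), R = 2 (mutual cooperation), P = 1 (mutual defection), S = 0
(cooperate against a defector). After every round the encounter continues with
probability $n$, so the number of rounds is geometric with mean $1/(1-n)$:
at $n = 0.95$ an encounter lasts 20 rounds on average.

Play is noisy: with probability $a$ a player's realized action is the opposite
of its intended one. Noise is what makes reciprocating strategies fragile — a
single accidental defection locks two grim triggers into mutual punishment —
and it is what gives apology a job to do.

Five behavioral strategies compete:

| id | behavior |
|----|----------|
| C  | always cooperate |
| D  | always defect |
| GT | grim trigger: cooperate until the partner defects, then defect forever |
| GP | guilt-prone grim trigger: play grim trigger, apologize after own defections (cost $c$), and forgive partners whose apologies it believes |
| F  | faker: always defect, apologize after own defections (cost $d$) |

Apologies by GP are always believed — guilt is treated as an honest,
hard-to-fake signal. A faker's apology is believed with probability $p$
("fakeability"), independently per apology. A believed apology received in the
same round as the partner's defection prevents the receiver (GP only; GT
ignores apologies) from switching to punishment. The five scalars $(n, a, p,
c, d)$ are bundled by `model_params()`.

## Apology conventions

The strategy descriptions above leave three behavioral details open, and they
matter quantitatively. The package fixes defaults and exposes the alternatives
as switches, so the consequences of each convention can be examined directly.

**When does GP apologize?** Default: after *every* realized defection,
including intended punitive ones (`gp_apology_policy = "always"`). We read
guilt as an involuntary disposition — it does not switch off while punishing.
This choice is also what gives the apology cost its bite: a guilt-prone player
locked in mutual punishment with a defector keeps paying $c$ almost every
round, so its payoff against D-like partners falls roughly linearly in $c$.
Under the alternative (`"cooperative_mode_only"`), GP apologizes only for
accidental defections committed while still cooperative; its expected cost is
then only $a\,c$ per round (about $0.01c$ at the study's error rate), so the
cost parameter can punish fakers but essentially cannot touch GP — and the
trade-off that produces an *interior* optimal cost disappears.

**When does F apologize?** Default: after every realized defection
(`faker_apology_policy = "always"`), mirroring GP. The alternative
(`"if_partner_cooperated"`) is an economical faker that never wastes an
apology on a partner who also defected; it pays roughly $a\,d$ per round
against defectors instead of $(1-a)\,d$.

**Is forgiveness renewable?** No: once GP disbelieves an apology it punishes
for the rest of the encounter. Re-entry would require an unstated forgiveness
budget; grim-on-apologies is the minimal reading, and it is what makes low
fakeability costly for fakers in long encounters.

Other conventions: execution errors apply to cooperate/defect actions only
(apology reliability is modeled separately, by $p$); the apology cost is paid
whenever the apology is issued, believed or not; apologies resolve at the end
of the round and mode updates take effect the following round; belief draws
are independent per apology event; all conditional strategies start
cooperative.

## Exact expected payoffs

Given the rules, an encounter between two strategies is a time-homogeneous
Markov chain on the pair of player modes — at most $2 \times 2$ states, since
only GT and GP carry a mode. `build_pair_process()` enumerates, per state, the
four realized-action combinations, the apology events and their costs, and the
belief outcomes, yielding the transition matrix $T$ and each player's expected
per-round reward vector $r$ (stage payoff minus expected apology cost).

The expected *total* payoff over the geometrically distributed encounter
satisfies $v = r + n\,T\,v$, solved exactly by `expected_pair_payoffs()` as
$(I - nT)^{-1} r$ and read off at the all-cooperative starting state.
Discounting by $n$ is mathematically identical to averaging undiscounted sums
over Geometric($1-n$) encounter lengths. We report totals rather than
per-round averages; every downstream conclusion (ESS status, replicator
attractors) is invariant to that positive rescaling by $1/(1-n)$.

```{r}
params <- model_params(n = 0.95, a = 0.01, p = 0.95, c = 0.4, d = 0.4)
build_payoff_matrix(params = params)
```

A deliberately independent Monte-Carlo simulator (`mc_pair_payoffs()`)
replays encounters round by round with explicit random draws; the test suite
holds the two engines to agreement within four standard errors across a
parameter grid, and to closed-form enumerations for the simple pairs (for
example a GP–GP round at $a = 0.01$, $c = 0.2$ is worth
$2(1-a)^2 + 3a(1-a) + a^2 - a c = 1.988$, i.e. 39.76 per encounter at
$n = 0.95$). Simulated encounters cap at $10^4$ rounds; the truncated tail
has probability $n^{10^4}$, negligible for $n \le 0.99$.

## Stability

`is_ess()` applies the Maynard-Smith conditions to the payoff matrix: resident
$S$ resists invader $T$ if $E(S,S) > E(T,S)$, or $E(S,S) = E(T,S)$ and
$E(S,T) > E(T,T)$. Payoff ties are resolved with an absolute tolerance of
$10^{-9}$, comfortably above the linear-solver error and far below any real
payoff gap in this game. The report retains the per-invader margins, because
at exactly $c = 0$ the GT-vs-GP comparison is a true tie: free apology makes
GP behaviorally identical to GT against GT, and the verdict rests on the
tie-breaker (GP out-earns GT in a GP population, so GT is not an ESS there).

The two boundary finders, `min_cost_for_ess_vs_faker()` and
`min_continuation_for_ess()`, first scan the search range coarsely (25
points), verify that ESS status crosses monotonically from failing to
holding, and then bisect the bracket to a tolerance of $10^{-4}$; a
non-monotone scan falls back to a fine grid search with a message. Both are
cross-checked against brute-force grid scans in the tests.

## Replicator dynamics and basins of attraction

Evolvability is assessed with the discrete-time replicator map: fitness
$f_i = \sum_j (A_{ij} + s)\,x_j$ and update $x_i' = x_i f_i / \bar f$. The
uniform shift $s = \max(0, 1 - \min A)$ keeps fitness positive; because
discrete-time *trajectories* (unlike rest points) depend on the shift, it is
computed once per payoff matrix and shared across all runs of an experiment,
and the tests confirm that attractor assignments are insensitive to it.

`estimate_basin()` draws initial populations uniformly from the simplex
(symmetric Dirichlet with concentration 1, via normalized exponentials) and
iterates each until one strategy's share exceeds 0.999 or $10^6$ steps have
passed. Runs hitting the cap are reported as `unresolved` — never silently
dropped — so the reported fractions always partition the sample; in practice
convergence at the study's parameters takes hundreds of steps, and unresolved
runs are rare to nonexistent. Each estimate carries a 95% binomial interval
and is fully reproducible from its seed.

The headline question — which apology cost most favors the evolution of
guilt? — is answered by `optimal_cost()`: sweep $c = d$ over a grid, estimate
the GP basin with strategies $\{C, D, GP, F\}$ at each cost, return the
argmax (ties broken toward the smaller cost, the conservative claim). At
$n = 0.95$, $a = 0.01$ the sweep locates the optimum at cost 0.4 for
$p = 0.95$ and 0.2 for $p = 0.9$, while for hard-to-fake guilt (small $p$)
any cost only shrinks the basin. The mechanism is the trade-off described
above: moderate costs price fakers out of the apology market; high costs also
bleed guilt-prone players in their (error-induced) punishing phases.

```{r, eval = FALSE}
sweep <- optimal_cost(p = 0.95, samples = 10000, seed = 1)
sweep$optimal_cost
#> [1] 0.4
```

## Problem sizes and reproducibility

The basin analyses behind the headline sweeps use 10,000 simplex starts per
cost — large enough that the ~0.01–0.02 gaps between neighboring grid costs
are several standard errors wide. The routine test suite scales down where
precision is not the point: 400–600 starts for monotonicity checks (asserted
with explicit sampling-error slack), 4,000 Monte-Carlo encounters per grid
point for the engine cross-validation, and $10^5$ encounters for the
full-matrix agreement check at the study's central parameter set. Every
stochastic result in the package — simulations, basin estimates, experiment
tables — is reproducible from a single integer seed, and experiment rows
carry their own derived seed so any row can be recomputed in isolation.

`run_experiment()` packages the four standard analyses as presets
(`min_cost`, `min_n`, `basin_cost`, `basin_faker_cost`), writing flat CSV
tables with a JSON metadata sidecar; `plot_results()` renders the matching
figures.

## What the model does and does not capture

All inputs are generated by the model itself; there is no empirical data.
Within its scope the tests verify internal consistency (analytic vs simulated
payoffs, bisection vs grid scans, invariances) and the qualitative comparative
statics of stability and evolvability. The model deliberately omits much that
matters for real guilt: populations are infinite and well-mixed (no
assortment, no finite-population drift, no mutation); strategies have no
memory beyond the current mode and cannot recognize partners across
encounters; guilt is a fixed behavioral disposition, not a represented
emotion, and the costs $c, d$ stand in for whatever reparations, self-punishment
or lost opportunities guilt imposes; apology reliability is a single
probability rather than a strategic signaling choice. Conclusions are
therefore comparative-static conditionals about this strategy ecology — e.g.
"harder-to-fake apology enlarges the basin of guilt-proneness" — not
measurements of human populations.
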