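# meaculpa

Evolutionary dynamics of guilty apology in a noisy iterated prisoner's
dilemma.

## The problem

Guilt looks evolutionarily puzzling: it drives costly apology, reparation and
acceptance of punishment. Yet in repeated interactions where players
sometimes *err* — defecting by accident against a good partner — the behaviors
guilt produces can pay for themselves. An apologizing, forgiving grim trigger
("guilt-prone", GP) can escape the mutual-punishment spirals that ruin plain
reciprocators, provided fake apologizers can be kept at bay, either because
guilt is hard to fake or because apologizing is costly.

`meaculpa` implements this strategy ecology for theorists who want exact
numbers rather than hand-waving: it computes expected encounter payoffs
analytically, certifies evolutionary stability, locates stability boundaries,
and measures basins of attraction under replicator dynamics.

## The model

Each round of an encounter is a prisoner's dilemma with payoffs
T = 3 > R = 2 > P = 1 > S = 0; the encounter continues with probability *n*
(expected length 1/(1 − n)). Each player's realized action is flipped with
error probability *a*. Strategies: C (always cooperate), D (always defect),
GT (grim trigger), GP (grim trigger that apologizes after own defections at
cost *c* and forgives believed apologies), and F (faker: always defect,
apologize at cost *d*). GP apologies are always believed; F apologies are
believed with probability *p*.

An encounter between two strategies is a Markov chain on the players' modes
(cooperative/punishing). With per-round expected rewards *r* and transitions
*T*, expected whole-encounter payoffs solve v = r + n T v, giving the payoff
matrix on which the analysis runs:

* **ESS**: resident S resists invader T iff E(S,S) > E(T,S), or ties and
  E(S,T) > E(T,T).
* **Replicator dynamics** (discrete time): x′ᵢ = xᵢ fᵢ / f̄ with
  fᵢ = Σⱼ (Aᵢⱼ + shift) xⱼ; basins of attraction are estimated from initial
  populations drawn uniformly on the simplex.

See the vignette (`vignettes/guilty-apology.Rmd`) for the full account,
including the apology-policy conventions and numerical choices.

## Worked example

```r
library(meaculpa)
params <- model_params(n = 0.95, a = 0.01, p = 0.95, c = 0.4, d = 0.4)
pm <- build_payoff_matrix(params = params)
pm
#> Expected encounter payoffs (row player) | n=0.95 a=0.01 p=0.95 c=0.4 d=0.4
#>          C       D      GT      GP       F
#> C  39.8000  0.6000 33.5412 33.5412  0.6000
#> D  59.4000 20.2000 22.1788 22.1788 20.2000
#> GT 42.9294 19.2106 34.5575 34.5575 19.2106
#> GP 41.5976 11.6864 32.3805 39.7200  6.2197
#> F  51.4800 12.2800 14.2588 32.4810 12.2800
```

Two cooperating GPs earn 39.72 of the 40 that perfect cooperators would get
over the expected 20 rounds — noise plus occasional apology costs eat only
0.28 — while a faker meeting a GP nets 32.48 before the GP catches on, and a
GP stuck punishing a defector earns just 11.69 because it keeps paying the
0.4 apology cost. Is guilt-proneness stable here?

```r
is_ess("GP", c("C", "D", "GT", "F"), pm)
#> ESS report for GP vs {C, D, GT, F}: ESS
#>  invader margin_resident margin_tiebreak holds
#>        C        6.178824        1.797647  TRUE
#>        D       17.541201       -8.513640  TRUE
#>       GT        5.162474       -2.176990  TRUE
#>        F        7.239021       -6.060294  TRUE
```

Every resident margin E(GP,GP) − E(invader,GP) is positive: no rare mutant
can invade. How *likely* is guilt to evolve from random initial conditions?

```r
estimate_basin(params, samples = 1000, seed = 1)
#> Basin-of-attraction estimate | n=0.95 a=0.01 p=0.95 c=0.4 d=0.4 | 1000 starts, seed 1
#>  strategy fraction    ci_low   ci_high
#>         C    0.000 0.0000000 0.0000000
#>         D    0.671 0.6418784 0.7001216
#>        GP    0.329 0.2998784 0.3581216
#>         F    0.000 0.0000000 0.0000000
```

About a third of random populations evolve to all-guilt-prone, the rest to
all-defect (C and F are never end states — they are not ESSes). Sweeping the
apology cost with `optimal_cost(p = 0.95)` shows this basin is maximized at
cost 0.4: cheaper apology lets fakers thrive, dearer apology bleeds the
guilty.

`run_experiment("basin_cost")` (and presets `min_cost`, `min_n`,
`basin_faker_cost`) reproduce the full analyses as CSV tables;
`plot_results()` draws them.

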